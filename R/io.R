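## Readers and writers: UniProt-style feature tables, ortholog alignment
## FASTA (protein or codon dialect), codeml main output, and the summary TSV.
##
## Positions are 1-based in every file and report (UniProt convention).

as_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
}

## ---------------------------------------------------------------------------
## UniProt flat-file feature table

#' Parse N-glycosylation sites from UniProt-style flat-file text
#'
#' Scans \code{FT   CARBOHYD} feature lines of one or more flat-file records
#' (records separated by \code{//}) and keeps features whose description
#' carries the \code{N-linked (GlcNAc...)} term.  Features whose description
#' contains any of the non-experimental qualifiers \emph{potential},
#' \emph{by similarity}, \emph{partial} or \emph{probable}
#' (case-insensitive) are marked \code{evidence_ok = FALSE}; the screen
#' excludes them.
#'
#' @param input Path to a flat file, or the file contents as a string.
#' @return A data frame with columns \code{accession}, \code{gene},
#'   \code{position} (1-based on the canonical sequence),
#'   \code{description} and \code{evidence_ok}.  If the records carry
#'   \code{SQ} sequence blocks, the sequences are attached as a named
#'   character vector in \code{attr(, "sequences")} (named by gene).
#' @export
parse_uniprot_glycosites <- function(input) {
  lines <- as_lines(input)
  out <- list()
  seqs <- character()
  entry_name <- acc <- gene <- NA_character_
  seq_buf <- NULL
  in_sq <- FALSE
  feat <- NULL   # open CARBOHYD feature awaiting continuation lines

  flush_feat <- function() {
    if (is.null(feat)) return()
    desc <- trimws(feat$desc)
    if (grepl("N-linked \\(GlcNAc", desc, ignore.case = TRUE)) {
      out[[length(out) + 1L]] <<- data.frame(
        accession = acc, gene = gene, position = feat$pos,
        description = desc,
        evidence_ok = !grepl("potential|by similarity|partial|probable",
                             desc, ignore.case = TRUE),
        stringsAsFactors = FALSE
      )
    }
    feat <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    if (tag == "ID") {
      entry_name <- sub("^ID\\s+(\\S+).*$", "\\1", ln)
    } else if (tag == "AC" && is.na(acc)) {
      acc <- sub(";.*$", "", sub("^AC\\s+", "", ln))
    } else if (tag == "GN" && grepl("Name=", ln)) {
      gene <- sub("^.*Name=([^;,\\s]+).*$", "\\1", ln)
    } else if (tag == "SQ") {
      in_sq <- TRUE
      seq_buf <- character()
    } else if (in_sq && tag == "  ") {
      seq_buf <- c(seq_buf, gsub("[^A-Za-z]", "", ln))
    } else if (tag == "FT") {
      body <- sub("^FT", "", ln)
      if (grepl("^\\s{10,}\\S", body)) {
        ## continuation of the open feature's description
        if (!is.null(feat)) feat$desc <- paste(feat$desc, trimws(body))
        next
      }
      flush_feat()
      m <- regmatches(ln, regexec(
        "^FT\\s+(\\S+)\\s+(\\S+)(?:\\s+(\\S+))?\\s*(.*)$", ln))[[1]]
      if (length(m) && m[2] == "CARBOHYD") {
        pos <- suppressWarnings(as.integer(m[3]))
        if (is.na(pos) || pos < 1L) {
          stop("malformed FT position field at line ", i, ": ", ln)
        }
        feat <- list(pos = pos, desc = m[5])
      }
    } else if (tag == "//") {
      flush_feat()
      if (in_sq && !is.na(gene)) {
        seqs[gene] <- toupper(paste(seq_buf, collapse = ""))
      }
      entry_name <- acc <- gene <- NA_character_
      in_sq <- FALSE
      seq_buf <- NULL
    }
  }
  flush_feat()
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(accession = character(), gene = character(),
               position = integer(), description = character(),
               evidence_ok = logical(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "sequences") <- seqs
  res
}

## ---------------------------------------------------------------------------
## Ortholog alignment FASTA

#' Construct an ortholog alignment object
#'
#' @param rows Named character vector: species id -> aligned protein
#'   sequence (gap character \code{-}).
#' @param gene Gene symbol.
#' @param reference Reference species id (default \code{"human"}).
#' @param non_roster Species keys kept from the file but not resolvable in
#'   the taxonomy (excluded from clade logic, included in rendering).
#' @return An \code{ortho_alignment} object.
#' @export
ortho_alignment <- function(rows, gene = NA_character_, reference = "human",
                            non_roster = character()) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by species")
  }
  if (anyDuplicated(names(rows))) {
    stop("duplicate species in alignment: ",
         names(rows)[duplicated(names(rows))][1L])
  }
  len <- nchar(rows)
  if (length(unique(len)) > 1L) {
    ragged <- names(rows)[len != len[1L]][1L]
    stop("ragged alignment: row '", ragged, "' has length ",
         nchar(rows[ragged]), ", expected ", len[1L])
  }
  if (!reference %in% names(rows)) {
    stop("reference species '", reference, "' missing from alignment")
  }
  structure(list(gene = gene, rows = rows, reference = reference,
                 non_roster = non_roster),
            class = "ortho_alignment")
}

#' @export
print.ortho_alignment <- function(x, ...) {
  cat("ortho_alignment", if (!is.na(x$gene)) paste0("(", x$gene, ")"), ":",
      length(x$rows), "species x", nchar(x$rows[[1]]), "columns\n")
  invisible(x)
}

clean_protein_row <- function(s, row) {
  s <- chartr("UO", "XX", toupper(s))
  s <- gsub(".", "-", s, fixed = TRUE)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), SEQ_ALPHABET)
  if (length(bad)) {
    stop("row '", row, "' contains characters outside the protein alphabet: ",
         paste(bad, collapse = " "))
  }
  s
}

translate_codon_row <- function(s, row) {
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("codon row '", row, "' has length ", n, ", not divisible by 3")
  }
  codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- ifelse(codons == "---", "-",
               ifelse(grepl("-", codons, fixed = TRUE), "X",
                      unname(Biostrings::GENETIC_CODE[codons])))
  aa[is.na(aa)] <- "X"   # ambiguous nucleotides (N etc.)
  paste(aa, collapse = "")
}

#' Read an ortholog alignment from FASTA
#'
#' Headers follow the multiz-derived dialect: the first whitespace-delimited
#' token identifies the species.  The whole token is first looked up in the
#' taxonomy alias map; failing that, its prefix up to the first \code{_} or
#' \code{.} is looked up (UCSC headers embed gene ids after the assembly
#' code).  Unresolvable rows are kept under their raw token and listed in
#' \code{$non_roster}.  Without a taxonomy, raw tokens are used as ids.
#'
#' In the codon dialect every row must have length divisible by 3 with gaps
#' as \code{---} triplets; rows are translated with the standard genetic code
#' (stop \code{*}, ambiguous codon \code{X}) before storage.
#'
#' @param input Path to a FASTA file, or FASTA text.
#' @param dialect \code{"protein"} or \code{"codon"}.
#' @param taxonomy Optional \code{glygain_taxonomy} used to resolve headers.
#' @param gene Gene symbol to record on the alignment.
#' @param reference Reference species id (default \code{"human"}).
#' @return An \code{ortho_alignment}.
#' @export
read_ortholog_alignment <- function(input, dialect = c("protein", "codon"),
                                    taxonomy = NULL, gene = NA_character_,
                                    reference = "human") {
  dialect <- match.arg(dialect)
  path <- input
  if (!(length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
        file.exists(input))) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  }
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("empty FASTA")
  tokens <- vapply(strsplit(names(xs), "\\s+"), `[`, "", 1L)
  non_roster <- character()
  ids <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    id <- NA_character_
    if (!is.null(taxonomy)) {
      id <- resolve_species(taxonomy, tok, quiet = TRUE)
      if (is.na(id)) {
        pre <- sub("[_.].*$", "", tok)
        id <- resolve_species(taxonomy, pre, quiet = TRUE)
      }
      if (is.na(id)) {
        id <- tok
        non_roster <- c(non_roster, tok)
      }
    } else {
      id <- tok
    }
    ids[i] <- id
  }
  if (anyDuplicated(ids)) {
    stop("duplicate species in alignment: ", ids[duplicated(ids)][1L])
  }
  raw <- stats::setNames(as.character(xs), ids)
  rows <- if (dialect == "codon") {
    vapply(ids, function(id) translate_codon_row(raw[[id]], id), "")
  } else {
    vapply(ids, function(id) clean_protein_row(raw[[id]], id), "")
  }
  ortho_alignment(rows, gene = gene, reference = reference,
                  non_roster = non_roster)
}

#' Write an ortholog alignment as FASTA text
#'
#' @param alignment An \code{ortho_alignment}.
#' @param path Optional output file; when \code{NULL} the text is returned.
#' @param width Line width for wrapped sequences.
#' @return FASTA text, invisibly when written to a file.
#' @export
write_ortho_fasta <- function(alignment, path = NULL, width = 60L) {
  chunks <- unlist(lapply(names(alignment$rows), function(id) {
    s <- alignment$rows[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  txt <- paste(chunks, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(chunks, path)
  invisible(txt)
}

## ---------------------------------------------------------------------------
## codeml main output

#' Construct a codeml model fit from numbers
#'
#' Fits can also be parsed from codeml main output with
#' [parse_codeml_lnl()]; this package never runs codeml itself.
#'
#' @param lnL Log-likelihood.
#' @param np Number of free parameters.
#' @param model Model label, one of \code{M0}, \code{free_ratio},
#'   \code{two_ratio}, \code{model_A}, \code{null_model_A} (or \code{NA}).
#' @param omega0,omega1,omega2 dN/dS estimates where applicable.
#' @param dN,dS Per-branch rates when available.
#' @param beb Optional data frame of Bayes empirical Bayes sites
#'   (\code{position}, \code{residue}, \code{posterior}), reported verbatim.
#' @return A \code{codeml_fit} object.
#' @export
codeml_fit <- function(lnL, np = NA_integer_, model = NA_character_,
                       omega0 = NA_real_, omega1 = NA_real_,
                       omega2 = NA_real_, dN = NA_real_, dS = NA_real_,
                       beb = NULL) {
  if (!is.finite(lnL)) stop("lnL must be finite")
  for (w in c(omega0, omega1, omega2)) {
    if (!is.na(w) && w < 0) stop("omega estimates must be >= 0")
  }
  structure(list(model = model, lnL = lnL, np = np,
                 omega0 = omega0, omega1 = omega1, omega2 = omega2,
                 dN = dN, dS = dS, beb = beb),
            class = "codeml_fit")
}

#' @export
print.codeml_fit <- function(x, ...) {
  cat("codeml fit", if (!is.na(x$model)) paste0("[", x$model, "]"),
      " lnL = ", format(x$lnL), ", np = ", x$np, "\n", sep = "")
  om <- c(omega0 = x$omega0, omega1 = x$omega1, omega2 = x$omega2)
  om <- om[!is.na(om)]
  if (length(om)) {
    cat("  ", paste(names(om), "=", format(om), collapse = ", "), "\n")
  }
  if (!is.null(x$beb) && nrow(x$beb)) {
    cat("  BEB sites:", nrow(x$beb), "\n")
  }
  invisible(x)
}

#' Parse a codeml main-output file
#'
#' Extracts the log-likelihood and parameter count from the \code{lnL} line,
#' the \eqn{\omega} (dN/dS) estimates when present (single-ratio
#' \code{omega} line, branch-ratio \code{w (dN/dS) for branches} line, or
#' the branch-site \code{foreground w} row), and any Bayes empirical Bayes
#' positively-selected-sites list (captured, never recomputed).
#'
#' @param input Path to a codeml main output file, or its text.
#' @param model Optional model label to record on the fit.
#' @return A \code{codeml_fit}.
#' @export
parse_codeml_lnl <- function(input, model = NA_character_) {
  lines <- as_lines(input)
  lnl_idx <- grep("^lnL", lines)
  if (length(lnl_idx) == 0L) stop("no lnL line found in codeml output")
  if (length(lnl_idx) > 1L) {
    stop("ambiguous codeml output: ", length(lnl_idx), " lnL lines")
  }
  m <- regmatches(lines[lnl_idx], regexec(
    "^lnL\\(.*np:\\s*(\\d+)\\s*\\):\\s*(-?[0-9.]+)", lines[lnl_idx]))[[1]]
  if (length(m) < 3L) stop("unparseable lnL line: ", lines[lnl_idx])
  fit <- codeml_fit(lnL = as.numeric(m[3]), np = as.integer(m[2]),
                    model = model)

  om_line <- grep("^omega \\(dN/dS\\)", lines, value = TRUE)
  if (length(om_line)) {
    fit$omega0 <- as.numeric(sub("^omega \\(dN/dS\\)\\s*=\\s*", "",
                                 om_line[1]))
  }
  br_line <- grep("^w \\(dN/dS\\) for branches:", lines, value = TRUE)
  if (length(br_line)) {
    vals <- as.numeric(strsplit(trimws(
      sub("^w \\(dN/dS\\) for branches:", "", br_line[1])), "\\s+")[[1]])
    fit$omega0 <- vals[1]
    if (length(vals) >= 2L) fit$omega1 <- vals[2]
  }
  fg_line <- grep("^foreground w", lines, value = TRUE)
  if (length(fg_line)) {
    vals <- as.numeric(strsplit(trimws(
      sub("^foreground w", "", fg_line[1])), "\\s+")[[1]])
    fit$omega0 <- vals[1]
    if (length(vals) >= 2L) fit$omega1 <- vals[2]
    if (length(vals) >= 3L) fit$omega2 <- vals[3]
  }

  beb_idx <- grep("Bayes Empirical Bayes", lines)
  if (length(beb_idx)) {
    tail_lines <- lines[(beb_idx[1] + 1L):length(lines)]
    mm <- regmatches(tail_lines, regexec(
      "^\\s+(\\d+)\\s+([A-Z*])\\s+([0-9.]+)\\*{0,2}\\s*$", tail_lines))
    hits <- mm[vapply(mm, length, 1L) == 4L]
    if (length(hits)) {
      fit$beb <- data.frame(
        position = as.integer(vapply(hits, `[`, "", 2L)),
        residue = vapply(hits, `[`, "", 3L),
        posterior = as.numeric(vapply(hits, `[`, "", 4L)),
        stringsAsFactors = FALSE
      )
    }
  }
  fit
}

## ---------------------------------------------------------------------------
## Summary TSV

SUMMARY_COLS <- c("no", "gene", "accession", "position", "window", "timing",
                  "status", "reasons", "flags", "outgroup_fraction",
                  "n_informative")

#' Write the screening summary as TSV
#'
#' One row per screened site: running number, gene, accession, 1-based
#' position, 20-mer window, timing clade (empty when the site failed),
#' pass/fail status, reason codes, manual-review flags, the non-Euarchonta
#' motif fraction and the informative-species count.  Rows are ordered by
#' (gene, position).  Tab separators, no quoting, \code{.} decimal point.
#'
#' @param x A \code{glygain_screen} object or its \code{records} data frame.
#' @param path Optional output file; when \code{NULL} the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
write_summary_tsv <- function(x, path = NULL) {
  rec <- if (inherits(x, "glygain_screen")) x$records else x
  rec <- rec[order(rec$gene, rec$position), SUMMARY_COLS]
  fmt <- rec
  fmt$outgroup_fraction <- ifelse(is.na(rec$outgroup_fraction), "NA",
                                  format(rec$outgroup_fraction, digits = 15L))
  con <- textConnection("tsv_out", "w", local = TRUE)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  close(con)
  txt <- paste(tsv_out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a screening summary TSV back into a records data frame
#'
#' @param input Path or TSV text produced by [write_summary_tsv()].
#' @return A data frame with the summary columns.
#' @export
read_summary_tsv <- function(input) {
  lines <- as_lines(input)
  rec <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           colClasses = c(
                             no = "integer", gene = "character",
                             accession = "character", position = "integer",
                             window = "character", timing = "character",
                             status = "character", reasons = "character",
                             flags = "character",
                             outgroup_fraction = "numeric",
                             n_informative = "integer"))
  rec$reasons[is.na(rec$reasons)] <- ""
  rec$flags[is.na(rec$flags)] <- ""
  rec
}
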