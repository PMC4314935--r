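## The screen: evidence filtering, ancestral-conservation screening,
## automated curation, and timing assignment on the clade ladder.

#' Screening configuration
#'
#' @param ancestral_threshold Discard a site when \emph{more than} this
#'   fraction of informative non-Euarchonta species carry the motif
#'   (ancestrally conserved site).  Default 0.30; the boundary is strict, a
#'   fraction of exactly 0.30 is kept.
#' @param min_informative_species Minimum number of species with a
#'   determined state for the site to be evaluable (default 20 of 62).
#' @param max_uniprot_mismatch Maximum tolerated residue mismatches between
#'   the UniProt and genome-derived human sequences; more (default: 3 or
#'   more) suggests a paralogous match and fails the record.
#' @param require_chimpanzee Fail records whose alignment lacks a usable
#'   chimpanzee row (default \code{TRUE}).
#' @param max_row_gap_fraction Rows with a greater gap fraction are dropped
#'   from the alignment before state computation (default 0.5); this removes
#'   low-quality sequences, it does not fail the record.
#' @param mode Motif evaluation mode, see [species_motif_state()].
#' @param timing_loss_tolerance Fraction of informative clade members
#'   allowed to lack the motif when dating the gain (default 0: strict
#'   unanimity among sampled members).  Exposed because real data show
#'   secondary losses.
#' @param timing_unsampled How to date a gain when every species
#'   distinguishing a candidate clade from the next-inner clade is missing:
#'   \code{"skip"} (default) refuses to extend the dating to a clade with no
#'   supporting observation and falls back inwards; \code{"extend"} assigns
#'   the most inclusive clade consistent with the sampled species even when
#'   the extension rests on no data.
#' @return A \code{glygain_config} list.
#' @export
screening_config <- function(ancestral_threshold = 0.30,
                             min_informative_species = 20L,
                             max_uniprot_mismatch = 2L,
                             require_chimpanzee = TRUE,
                             max_row_gap_fraction = 0.5,
                             mode = c("columns", "species_local"),
                             timing_loss_tolerance = 0,
                             timing_unsampled = c("skip", "extend")) {
  mode <- match.arg(mode)
  timing_unsampled <- match.arg(timing_unsampled)
  for (f in c(ancestral_threshold, max_row_gap_fraction,
              timing_loss_tolerance)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      stop("fractions in the screening config must lie in [0, 1]")
    }
  }
  structure(list(ancestral_threshold = ancestral_threshold,
                 min_informative_species = as.integer(min_informative_species),
                 max_uniprot_mismatch = as.integer(max_uniprot_mismatch),
                 require_chimpanzee = require_chimpanzee,
                 max_row_gap_fraction = max_row_gap_fraction,
                 mode = mode,
                 timing_loss_tolerance = timing_loss_tolerance,
                 timing_unsampled = timing_unsampled),
            class = "glygain_config")
}

#' Fraction of non-Euarchonta species carrying the motif
#'
#' The denominator counts only informative outgroup species (state not
#' \code{missing}); undetermined rows are not evidence.  A site is discarded
#' as ancestrally conserved when the fraction \emph{exceeds} the threshold
#' (strictly): 3 sequons among 10 informative outgroups is kept.
#'
#' @param states A \code{site_states} object.
#' @param taxonomy A \code{glygain_taxonomy}.
#' @return The fraction, with attributes \code{n_informative} (outgroup
#'   species with a determined state) and \code{n_sequon}.  \code{NaN} with
#'   \code{n_informative = 0} when no outgroup species is informative.
#' @export
ancestral_conservation_fraction <- function(states, taxonomy) {
  eua <- vapply(states$species, function(s) is_euarchont(taxonomy, s), TRUE)
  out <- states[!eua, , drop = FALSE]
  informative <- out$state != "missing"
  n_inf <- sum(informative)
  n_seq <- sum(out$state == "sequon")
  frac <- if (n_inf == 0L) NaN else n_seq / n_inf
  structure(frac, n_informative = n_inf, n_sequon = n_seq)
}

## mismatches between two ungapped sequences: Hamming distance over the
## shorter overlap plus the length difference as penalty
sequence_mismatches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  sum(ca[seq_len(n)] != cb[seq_len(n)]) + abs(length(ca) - length(cb))
}

#' Automated curation filter
#'
#' Applies the curation rules that can be computed from the inputs:
#' \describe{
#'   \item{UNIPROT_MISMATCH}{the UniProt human sequence differs from the
#'     genome-derived human sequence in more than
#'     \code{max_uniprot_mismatch} residues (alignment-free Hamming count
#'     over the shorter overlap plus the length difference) — a possible
#'     paralogous match;}
#'   \item{NOT_CONSENSUS}{the annotated residue is not the Asn of an
#'     Asn-X-Ser/Thr consensus in the genome-derived human sequence;}
#'   \item{NO_CHIMP}{no usable chimpanzee row in the alignment;}
#'   \item{LOW_COVERAGE}{fewer than \code{min_informative_species} species
#'     have a determined state at the site.}
#' }
#' The rare-variant exclusion cannot be automated from these inputs and is
#' surfaced as the manual-review flag \code{RARE_VARIANT_UNCHECKED} instead.
#'
#' @param states A \code{site_states} object (or \code{NULL} when states
#'   could not be computed, e.g. a non-consensus site).
#' @param human_seq Ungapped genome-derived human sequence.
#' @param position 1-based Asn position.
#' @param config A \code{glygain_config}.
#' @param uniprot_seq Optional UniProt human sequence for the mismatch rule.
#' @return A list with \code{pass} (logical) and \code{reasons} (character
#'   vector of reason codes, empty on pass).
#' @export
curation_filter <- function(states, human_seq, position, config,
                            uniprot_seq = NULL) {
  reasons <- character()
  if (!is.null(uniprot_seq)) {
    mm <- sequence_mismatches(uniprot_seq, human_seq)
    if (mm > config$max_uniprot_mismatch) reasons <- c(reasons, "UNIPROT_MISMATCH")
  }
  chars <- strsplit(human_seq, "")[[1]]
  consensus <- position + 2L <= length(chars) &&
    is_sequon(chars[position], chars[position + 1L], chars[position + 2L])
  if (!consensus) reasons <- c(reasons, "NOT_CONSENSUS")
  if (!is.null(states)) {
    chimp_state <- states$state[states$species == "chimpanzee"]
    if (config$require_chimpanzee &&
        (length(chimp_state) == 0L || chimp_state == "missing")) {
      reasons <- c(reasons, "NO_CHIMP")
    }
    if (sum(states$state != "missing") < config$min_informative_species) {
      reasons <- c(reasons, "LOW_COVERAGE")
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Date a motif gain on the clade ladder
#'
#' Walks the ladder from Euarchonta inwards and returns the most inclusive
#' clade all of whose sampled (non-missing) members carry the sequon — the
#' branch on which the motif emerged in the clade's ancestor.  With
#' \code{timing_loss_tolerance} > 0, up to that fraction of informative
#' members may lack the motif (secondary losses).  Missing taxa are excluded
#' from the denominator: a great-ape gain with the gorilla row undetermined
#' is still dated to the clade supported by the sampled members.
#'
#' When every species distinguishing a candidate clade from the next-inner
#' clade is missing, the data cannot place the gain on that clade's branch.
#' By default (\code{timing_unsampled = "skip"}) such a clade is not
#' assigned and the dating falls back to the innermost clade with an actual
#' supporting observation, which is how a curator reading the alignment
#' would date it; \code{"extend"} instead assigns the most inclusive
#' consistent clade.
#'
#' @param states A \code{site_states} object; the human state must be
#'   \code{sequon}.
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param config A \code{glygain_config}.
#' @return A ladder clade code.
#' @export
assign_timing <- function(states, taxonomy, config = screening_config()) {
  hum <- states$state[states$species == "human"]
  if (length(hum) == 0L || hum != "sequon") {
    stop("cannot date the site: the human state is not 'sequon'")
  }
  tol <- config$timing_loss_tolerance
  lad <- ladder_clades()
  for (k in rev(seq_along(lad))) {   # eua first, hum last
    members <- intersect(clade_members(taxonomy, lad[k]), states$species)
    st <- states$state[match(members, states$species)]
    n_inf <- sum(st != "missing")
    if (n_inf == 0L) next
    if (sum(st == "sequon") / n_inf < 1 - tol) next
    if (identical(config$timing_unsampled, "skip") && k > 1L) {
      dist_sp <- setdiff(members, clade_members(taxonomy, lad[k - 1L]))
      dist_st <- states$state[match(dist_sp, states$species)]
      if (!any(dist_st != "missing")) next   # extension rests on no data
    }
    return(lad[k])
  }
  "hum"   # human itself carries the sequon
}

## drop gap-heavy rows (low-quality sequences) before state computation
drop_gappy_rows <- function(alignment, max_gap_fraction) {
  gap_frac <- vapply(alignment$rows, function(s) {
    chars <- strsplit(s, "")[[1]]
    mean(chars == "-")
  }, 1)
  keep <- gap_frac <= max_gap_fraction | names(alignment$rows) == alignment$reference
  dropped <- names(alignment$rows)[!keep]
  alignment$rows <- alignment$rows[keep]
  alignment$non_roster <- intersect(alignment$non_roster, names(alignment$rows))
  list(alignment = alignment, dropped = dropped)
}

#' Run the full screen
#'
#' Applies, per annotated site and in order: the experimental-evidence
#' filter, gap-heavy row removal, per-species motif state computation, the
#' ancestral-conservation (30\%) filter, the coverage filter, the automated
#' curation rules, and timing assignment on the clade ladder.  Every input
#' site appears exactly once in the output with its full decision trail;
#' a site whose gene has no alignment is flagged, never dropped silently.
#'
#' @param glycosites Data frame from [parse_uniprot_glycosites()] (columns
#'   \code{gene}, \code{accession}, \code{position}, \code{evidence_ok}).
#' @param alignments Named list of \code{ortho_alignment} objects, keyed by
#'   gene symbol.
#' @param taxonomy A \code{glygain_taxonomy}.
#' @param config A \code{glygain_config}.
#' @param uniprot_seqs Optional named character vector (by gene) of UniProt
#'   human sequences for the paralogy mismatch rule; defaults to the
#'   sequences attached to \code{glycosites}, if any.
#' @return A \code{glygain_screen} object: \code{$records} (one row per
#'   input site: decisions, reason codes, timing) and \code{$states} (the
#'   per-site \code{site_states}, for rendering).
#' @export
run_screen <- function(glycosites, alignments, taxonomy = default_taxonomy(),
                       config = screening_config(), uniprot_seqs = NULL) {
  if (is.null(uniprot_seqs)) {
    uniprot_seqs <- attr(glycosites, "sequences")
  }
  n <- nrow(glycosites)
  rows <- vector("list", n)
  states_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- glycosites[i, ]
    reasons <- character()
    flags <- character()
    timing <- NA_character_
    window <- NA_character_
    human_state <- NA_character_
    frac <- NA_real_
    n_inf <- NA_integer_
    states <- NULL

    if (!isTRUE(g$evidence_ok)) reasons <- c(reasons, "NO_EVIDENCE")
    aln <- alignments[[g$gene]]
    if (is.null(aln)) {
      reasons <- c(reasons, "NO_ALIGNMENT")
    } else if (length(reasons) == 0L) {
      dg <- drop_gappy_rows(aln, config$max_row_gap_fraction)
      aln <- dg$alignment
      human_seq <- strip_gaps(aln$rows[[aln$reference]])
      if (g$position + 2L > nchar(human_seq)) {
        reasons <- c(reasons, "NOT_CONSENSUS")
      } else {
        window <- site_window(human_seq, g$position)
        hchars <- strsplit(human_seq, "")[[1]]
        if (hchars[g$position] != "N") {
          reasons <- c(reasons, "NOT_CONSENSUS")
        } else {
          states <- species_motif_state(aln, g$position, mode = config$mode,
                                        taxonomy = taxonomy)
          states_list[[i]] <- states
          human_state <- states$state[states$species == "human"]
          af <- ancestral_conservation_fraction(states, taxonomy)
          frac <- as.numeric(af)
          n_inf <- sum(states$state != "missing")
          if (attr(af, "n_informative") == 0L) {
            reasons <- c(reasons, "INSUFFICIENT_OUTGROUP")
          } else if (frac > config$ancestral_threshold) {
            reasons <- c(reasons, "ANCESTRAL")
          }
          us <- if (g$gene %in% names(uniprot_seqs)) {
            uniprot_seqs[[g$gene]]
          } else {
            NULL
          }
          cf <- curation_filter(states, human_seq, g$position, config,
                                uniprot_seq = us)
          reasons <- c(reasons, cf$reasons)
          if (human_state != "sequon" &&
              !"NOT_CONSENSUS" %in% reasons) {
            reasons <- c(reasons, "NOT_CONSENSUS")
          }
        }
      }
      if (length(reasons) == 0L) {
        timing <- assign_timing(states, taxonomy, config)
        flags <- c(flags, "RARE_VARIANT_UNCHECKED")
      }
    }
    rows[[i]] <- data.frame(
      no = i, gene = g$gene, accession = g$accession, position = g$position,
      window = window, timing = timing,
      status = if (length(reasons)) "fail" else "pass",
      reasons = paste(reasons, collapse = ","),
      flags = paste(flags, collapse = ","),
      outgroup_fraction = frac, n_informative = n_inf,
      stringsAsFactors = FALSE
    )
  }
  records <- if (n) do.call(rbind, rows) else data.frame(
    no = integer(), gene = character(), accession = character(),
    position = integer(), window = character(), timing = character(),
    status = character(), reasons = character(), flags = character(),
    outgroup_fraction = numeric(), n_informative = integer(),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, states = states_list,
                 config = config),
            class = "glygain_screen")
}

#' @export
print.glygain_screen <- function(x, ...) {
  rec <- x$records
  cat("glygain screen:", nrow(rec), "sites,",
      sum(rec$status == "pass"), "passing\n")
  if (any(rec$status == "pass")) {
    print(clade_counts(x))
  }
  fails <- rec$reasons[rec$status == "fail"]
  if (length(fails)) {
    tab <- sort(table(unlist(strsplit(fails, ","))), decreasing = TRUE)
    cat("  fail reasons:",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.glygain_screen <- function(object, ...) {
  rec <- object$records
  out <- list(
    n_sites = nrow(rec),
    n_pass = sum(rec$status == "pass"),
    clade_counts = clade_counts(object),
    n_genes = length(unique(rec$gene[rec$status == "pass"]))
  )
  class(out) <- "summary.glygain_screen"
  out
}

#' @export
print.summary.glygain_screen <- function(x, ...) {
  cat("Sites screened:", x$n_sites, "\n")
  cat("Novel sites passing all filters:", x$n_pass, "in", x$n_genes,
      "proteins\n")
  print(x$clade_counts)
  invisible(x)
}
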