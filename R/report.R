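## Human-readable outputs: per-clade gain counts and text alignment panels
## with dot-encoding against the human row.

#' Per-clade counts of novel sites
#'
#' Counts passing records by the ladder clade their gain was dated to,
#' ordered humans to Euarchonta.  The counts always sum to the number of
#' passing records.
#'
#' @param x A \code{glygain_screen} object or its records data frame.
#' @return A \code{clade_count_table}: named integer vector over the nine
#'   ladder clades with a \code{total} attribute.
#' @export
clade_counts <- function(x) {
  rec <- if (inherits(x, "glygain_screen")) x$records else x
  pass <- rec[rec$status == "pass" & !is.na(rec$timing), , drop = FALSE]
  counts <- vapply(ladder_clades(), function(cl) sum(pass$timing == cl), 1L)
  structure(counts, total = sum(counts), class = "clade_count_table")
}

#' @export
print.clade_count_table <- function(x, ...) {
  cat("  novel sites per clade (hum -> eua):\n  ")
  cat(paste(sprintf("%s:%d", names(unclass(x)), unclass(x)), collapse = "  "),
      "\n")
  cat("  total:", attr(x, "total"), "\n")
  invisible(x)
}

#' Render a text alignment panel for one site
#'
#' One line per species in ladder order (humans first, then the ladder
#' outwards, then the outgroup groups): species id, clade code, and the
#' 20-residue window around the site.  Residues identical to the human row
#' are shown as dots, alignment gaps as dashes, and differing residues as
#' themselves; the human row is always spelled out.  A header line marks the
#' motif span (window offsets 11-13).
#'
#' @param alignment An \code{ortho_alignment}.
#' @param position 1-based Asn position on the ungapped human sequence.
#' @param taxonomy A \code{glygain_taxonomy}.
#' @return A \code{glygain_panel}: character vector of panel lines.
#' @export
render_alignment_panel <- function(alignment, position,
                                   taxonomy = default_taxonomy()) {
  ref <- alignment$rows[[alignment$reference]]
  ref_chars <- strsplit(ref, "")[[1]]
  res_cols <- which(ref_chars != "-")
  if (position > length(res_cols)) {
    stop("position ", position, " exceeds the ungapped reference length")
  }
  win_idx <- (position - 10L):(position + 9L)
  in_range <- win_idx >= 1L & win_idx <= length(res_cols)
  cols <- res_cols[win_idx[in_range]]

  species <- intersect(panel_species_order(taxonomy), names(alignment$rows))
  species <- c(species, setdiff(names(alignment$rows), species))
  id_w <- max(nchar(species))
  human_win <- rep("-", 20L)
  human_win[in_range] <- ref_chars[cols]

  marker <- rep(" ", 20L)
  marker[11:13] <- "*"
  lines <- sprintf("%-*s  %s  %s", id_w + 5L, "", paste(marker, collapse = ""),
                   "")
  for (id in species) {
    chars <- strsplit(alignment$rows[[id]], "")[[1]]
    win <- rep("-", 20L)
    win[in_range] <- chars[cols]
    shown <- if (id == alignment$reference) {
      win
    } else {
      ifelse(win == "-", "-", ifelse(win == human_win, ".", win))
    }
    grp <- if (id %in% taxonomy$species$id) {
      species_group(taxonomy, id)
    } else {
      "?"
    }
    lines <- c(lines, sprintf("%-*s %-3s  %s", id_w + 1L, id, grp,
                              paste(shown, collapse = "")))
  }
  structure(lines, class = "glygain_panel")
}

#' @export
print.glygain_panel <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Decode a dot-encoded panel window against the human window
#'
#' Inverse of the dot encoding used by [render_alignment_panel()]: dots
#' become the human residue, everything else stays.
#'
#' @param window Dot-encoded 20-character window.
#' @param human_window The human window string.
#' @return The decoded residue string.
#' @export
decode_panel_window <- function(window, human_window) {
  w <- strsplit(window, "")[[1]]
  h <- strsplit(human_window, "")[[1]]
  paste(ifelse(w == ".", h, w), collapse = "")
}
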