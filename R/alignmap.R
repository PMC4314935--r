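## Coordinate mapping between ungapped residue positions and alignment
## columns, and per-species sequon state at a homologous site.

#' Map an ungapped position to its alignment column
#'
#' @param aligned_seq Gapped sequence string.
#' @param position 1-based index on the ungapped sequence.
#' @return 1-based column index of the position-th non-gap character.
#' @seealso [column_to_ungapped()] for the inverse.
#' @export
ungapped_to_column <- function(aligned_seq, position) {
  chars <- strsplit(aligned_seq, "")[[1]]
  res_cols <- which(chars != "-")
  if (position < 1L || position > length(res_cols)) {
    stop("position ", position, " exceeds ungapped length ",
         length(res_cols))
  }
  res_cols[position]
}

#' Map an alignment column to its ungapped position
#'
#' @param aligned_seq Gapped sequence string.
#' @param column 1-based alignment column.
#' @return 1-based ungapped position, or \code{NA} if the column holds a gap.
#' @export
column_to_ungapped <- function(aligned_seq, column) {
  chars <- strsplit(aligned_seq, "")[[1]]
  if (column < 1L || column > length(chars)) {
    stop("column ", column, " out of range (alignment width ",
         length(chars), ")")
  }
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}

## next k non-gap characters of `chars` starting at column `col` inclusive;
## padded with '-' when the row runs out
next_residues <- function(chars, col, k) {
  res <- chars[seq(col, length(chars))]
  res <- res[res != "-"]
  out <- rep("-", k)
  n <- min(k, length(res))
  if (n > 0L) out[seq_len(n)] <- res[seq_len(n)]
  out
}

#' Per-species sequon state at a homologous site
#'
#' Locates the alignment columns of the reference (human) Asn-X-Ser/Thr
#' triplet at \code{human_position} and evaluates the motif for every
#' species.  In \code{columns} mode (default; the state one reads off a
#' printed alignment) each species is judged on the residues in those three
#' columns.  In \code{species_local} mode the species residue aligned to the
#' Asn column is taken together with its next two non-gap residues, which is
#' the biologically relevant triplet when a species has an insertion inside
#' the motif span.  The two modes agree whenever no species has an in-motif
#' insertion.
#'
#' A species is \code{missing} when it is absent from the alignment, when
#' all three evaluated positions are gaps, or when its whole 20-residue
#' window around the site is gaps (undetermined sequence); it is
#' \code{no_sequon} when residues align but fail the motif.
#'
#' @param alignment An \code{ortho_alignment} containing the reference row.
#' @param human_position 1-based Asn position on the ungapped reference
#'   sequence.  The reference residue there must be \code{N}.
#' @param mode \code{"columns"} or \code{"species_local"}.
#' @param taxonomy Optional \code{glygain_taxonomy}; when given, species are
#'   reported in ladder order and non-roster rows are skipped.
#' @param ambiguous_x Passed to [is_sequon()].
#' @return A \code{site_states} object: data frame with columns
#'   \code{species}, \code{state} (\code{sequon}/\code{no_sequon}/
#'   \code{missing}) and \code{triplet}, with the gene and position as
#'   attributes.
#' @export
species_motif_state <- function(alignment, human_position,
                                mode = c("columns", "species_local"),
                                taxonomy = NULL, ambiguous_x = "strict") {
  mode <- match.arg(mode)
  ref <- alignment$rows[[alignment$reference]]
  ref_chars <- strsplit(ref, "")[[1]]
  res_cols <- which(ref_chars != "-")
  if (human_position > length(res_cols)) {
    stop("human position ", human_position, " exceeds ungapped length ",
         length(res_cols))
  }
  if (human_position + 2L > length(res_cols)) {
    stop("site not at consensus Asn-X-Ser/Thr: motif would run past the ",
         "end of the reference sequence")
  }
  cols <- res_cols[human_position + 0:2]
  if (ref_chars[cols[1]] != "N") {
    stop("site not at consensus Asn-X-Ser/Thr: reference residue at ",
         human_position, " is '", ref_chars[cols[1]], "', not 'N'")
  }
  ## window columns for the undetermined-sequence check
  win_idx <- (human_position - 10L):(human_position + 9L)
  win_cols <- res_cols[win_idx[win_idx >= 1L & win_idx <= length(res_cols)]]

  species <- names(alignment$rows)
  species <- setdiff(species, alignment$non_roster)
  if (!is.null(taxonomy)) {
    species <- species[order(match(species, panel_species_order(taxonomy)))]
  }
  state <- character(length(species))
  triplet <- character(length(species))
  for (i in seq_along(species)) {
    chars <- strsplit(alignment$rows[[species[i]]], "")[[1]]
    trip <- if (mode == "columns") {
      chars[cols]
    } else if (chars[cols[1]] == "-") {
      chars[cols]   # nothing aligns to the Asn: judged as in columns mode
    } else {
      next_residues(chars, cols[1], 3L)
    }
    all_gap_window <- all(chars[win_cols] == "-")
    if (all(trip == "-") || all_gap_window) {
      state[i] <- "missing"
    } else {
      state[i] <- if (is_sequon(trip[1], trip[2], trip[3],
                               ambiguous_x = ambiguous_x)) {
        "sequon"
      } else {
        "no_sequon"
      }
    }
    triplet[i] <- paste(trip, collapse = "")
  }
  structure(
    data.frame(species = species, state = state, triplet = triplet,
               stringsAsFactors = FALSE),
    gene = alignment$gene,
    human_position = human_position,
    reference = alignment$reference,
    mode = mode,
    class = c("site_states", "data.frame")
  )
}

## species order used for panels and state tables: ladder groups innermost
## first, then outgroup groups
panel_species_order <- function(taxonomy) {
  sp <- taxonomy$species
  ord <- c(ladder_clades(), outgroup_clades())
  sp$id[order(match(sp$group, ord))]
}
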