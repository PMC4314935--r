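## The N-glycosylation sequon: Asn-X-Ser/Thr, X != Pro.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SEQ_ALPHABET <- c(AA20, "-", "X", "*")

check_alphabet <- function(chars) {
  bad <- setdiff(unique(chars), SEQ_ALPHABET)
  if (length(bad)) {
    stop("character(s) outside the protein alphabet: ",
         paste(bad, collapse = " "))
  }
  invisible(chars)
}

#' Test a residue triplet for the N-glycosylation sequon
#'
#' The consensus motif is Asn-X-Ser/Thr where X is any amino acid except
#' proline.  A gap or the ambiguity code \code{X} at the Asn or Ser/Thr slot
#' always fails.  At the middle slot, ambiguity is treated conservatively by
#' default: an \code{X} (or gap) fails, because "not proline" cannot be
#' certified; set \code{ambiguous_x = "permissive"} to let \code{X} pass.
#'
#' @param a,b,c Single characters (vectorised): the candidate Asn, X and
#'   Ser/Thr residues.  Allowed alphabet: the 20 amino acids, \code{-}
#'   (gap), \code{X} (ambiguous), \code{*} (stop).
#' @param ambiguous_x \code{"strict"} (default) or \code{"permissive"}:
#'   whether an ambiguous middle residue can count as "not Pro".
#' @return Logical vector.
#' @examples
#' is_sequon("N", "L", "S")  # TRUE
#' is_sequon("N", "P", "S")  # FALSE: Pro at X
#' is_sequon("N", "E", "I")  # FALSE: no Ser/Thr
#' @export
is_sequon <- function(a, b, c, ambiguous_x = c("strict", "permissive")) {
  ambiguous_x <- match.arg(ambiguous_x)
  check_alphabet(c(a, b, c))
  mid_ok <- if (ambiguous_x == "strict") {
    !(b %in% c("P", "-", "X", "*"))
  } else {
    !(b %in% c("P", "-", "*"))
  }
  a == "N" & mid_ok & c %in% c("S", "T")
}

strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

#' Scan a protein sequence for sequons
#'
#' Gaps are removed before scanning, so hits are reported 1-based on the
#' ungapped residue series.  The last two residues can never start a hit.
#'
#' @param sequence Protein sequence string (gaps allowed).
#' @param ambiguous_x Passed to [is_sequon()].
#' @return A data frame with columns \code{position} (1-based Asn index on
#'   the ungapped sequence) and \code{triplet}.
#' @examples
#' scan_sequons("DDVPEYKDRLNLSENYTLSI")$position  # 11 and 15
#' @export
scan_sequons <- function(sequence, ambiguous_x = "strict") {
  s <- strsplit(strip_gaps(sequence), "")[[1]]
  check_alphabet(s)
  n <- length(s)
  if (n < 3L) {
    return(data.frame(position = integer(), triplet = character(),
                      stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 2L)
  hit <- is_sequon(s[i], s[i + 1L], s[i + 2L], ambiguous_x = ambiguous_x)
  pos <- i[hit]
  data.frame(
    position = pos,
    triplet = paste0(s[pos], s[pos + 1L], s[pos + 2L]),
    stringsAsFactors = FALSE
  )
}

#' Extract the 20-residue window around a glycosylation site
#'
#' The window covers positions \code{position - 10} to \code{position + 9}
#' of the ungapped sequence (10 residues left of the Asn, the motif, and 7
#' residues right of it), padded with \code{-} where it overhangs either
#' sequence end.  The motif occupies window offsets 11-13.
#'
#' @param sequence Protein sequence string (gaps allowed; removed first).
#' @param position 1-based Asn index on the ungapped sequence.
#' @return A 20-character string.
#' @export
site_window <- function(sequence, position) {
  s <- strsplit(strip_gaps(sequence), "")[[1]]
  n <- length(s)
  if (position < 1L || position > n) {
    stop("position ", position, " out of range for sequence of length ", n)
  }
  idx <- (position - 10L):(position + 9L)
  chars <- ifelse(idx >= 1L & idx <= n, s[pmax(pmin(idx, n), 1L)], "-")
  paste(chars, collapse = "")
}
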