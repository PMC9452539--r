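# Composition and accumulative absolute-position vectors.

#' Frequency distribution vector (FDV)
#'
#' Raw occurrence counts of A, C, G, T. Counts sum to the sequence length.
#' A normalised variant (counts divided by length) is available for
#' visualisation-style use; the feature pipeline uses raw counts by default.
#'
#' @param seq A [nucleotide_sequence()].
#' @param normalize If `TRUE`, divide counts by the sequence length.
#' @return Named numeric vector `(A, C, G, T)`.
#' @examples
#' fdv(nucleotide_sequence("s", "AACG"))
#' @export
fdv <- function(seq, normalize = FALSE) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  chars <- seq_chars(seq)
  out <- vapply(DNA_BASES, function(b) sum(chars == b), 0)
  if (normalize) out <- out / seq$length
  out
}

#' Accumulative absolute-position incidence vector (AAPIV)
#'
#' Component i is the sum of the 1-based positions at which nucleotide i
#' occurs; components sum to n(n+1)/2 for a length-n sequence, since every
#' position is counted exactly once.
#'
#' @param seq A [nucleotide_sequence()].
#' @return Named numeric vector `(A, C, G, T)`.
#' @examples
#' aapiv(nucleotide_sequence("s", "AACG"))  # (3, 3, 4, 0)
#' @export
aapiv <- function(seq) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  chars <- seq_chars(seq)
  pos <- seq_along(chars)
  vapply(DNA_BASES, function(b) sum(pos[chars == b]), 0)
}

#' Reverse accumulative absolute-position incidence vector (RAAPIV)
#'
#' [aapiv()] applied to the reversed residue string.
#'
#' @param seq A [nucleotide_sequence()].
#' @return Named numeric vector `(A, C, G, T)`.
#' @examples
#' raapiv(nucleotide_sequence("s", "AACG"))  # (7, 2, 1, 0)
#' @export
raapiv <- function(seq) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  aapiv(nucleotide_sequence(seq$id, reverse_residues(seq$residues)))
}
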