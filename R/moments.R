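# Raw and central 2-D moments of the row-major sequence matrix.

# Fixed (j,k) order shared by all three moment kinds.
MOMENT_ORDERS <- matrix(
  c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 2L,
    2L, 0L, 1L, 2L, 2L, 1L, 3L, 0L, 0L, 3L),
  ncol = 2L, byrow = TRUE,
  dimnames = list(c("00", "01", "10", "11", "02", "20", "12", "21", "30", "03"),
                  c("j", "k")))

#' Encode a DNA sequence as an integer series
#'
#' Substitutes each residue by its numeric code. The default map is the
#' alphabetical A=1, C=2, G=3, T=4; every downstream moment value depends on
#' this choice, so it is configurable and recorded in feature-table
#' provenance.
#'
#' @param seq A [nucleotide_sequence()].
#' @param encoding Named numeric vector mapping all four bases to distinct
#'   positive integers.
#' @return Integer vector of the same length as the sequence.
#' @examples
#' encode_sequence(nucleotide_sequence("s", "ACGT"))
#' @export
encode_sequence <- function(seq, encoding = c(A = 1, C = 2, G = 3, T = 4)) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  check_encoding(encoding)
  chars <- seq_chars(seq)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  unname(encoding[chars])
}

check_encoding <- function(encoding) {
  if (!is.numeric(encoding) || !setequal(names(encoding), DNA_BASES) ||
      anyDuplicated(encoding) || any(encoding <= 0) ||
      any(encoding != as.integer(encoding))) {
    stop("encoding must map A,C,G,T to distinct positive integers", call. = FALSE)
  }
  invisible(encoding)
}

#' Reshape an integer series into a zero-padded square matrix
#'
#' The matrix dimension is d = ceiling(sqrt(z)) for a series of length z;
#' entries are filled row-major and trailing cells are zero-padded. Reading
#' the matrix back row-major and truncating at z recovers the series.
#'
#' @param series Numeric vector (e.g. from [encode_sequence()]).
#' @return A d x d numeric matrix.
#' @examples
#' reshape_to_square(c(1, 2, 3, 4, 1, 2, 3, 4, 1))
#' @export
reshape_to_square <- function(series) {
  z <- length(series)
  if (z == 0L) stop("empty series", call. = FALSE)
  d <- ceiling(sqrt(z))
  matrix(c(series, numeric(d * d - z)), nrow = d, ncol = d, byrow = TRUE)
}

moment_vector <- function(values, kind) {
  structure(stats::setNames(values, rownames(MOMENT_ORDERS)), kind = kind)
}

#' Raw moments up to degree 3
#'
#' Computes the ten raw moments A_jk = sum_a sum_b a^j b^k f(a,b) with
#' 1-based row index a and column index b, for all j,k >= 0 with j+k <= 3, in
#' the fixed order (00, 01, 10, 11, 02, 20, 12, 21, 30, 03).
#'
#' @param matrix Square numeric matrix.
#' @return Named numeric vector of 10 moments (attribute `kind = "raw"`).
#' @export
raw_moments <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  a <- seq_len(nrow(matrix))
  vals <- apply(MOMENT_ORDERS, 1L, function(o) {
    drop(crossprod(a^o[["j"]], matrix %*% a^o[["k"]]))
  })
  moment_vector(vals, "raw")
}

#' Central moments up to degree 3
#'
#' Same sums as [raw_moments()] but referenced to the centroid
#' (abar, bbar) = (M10/M00, M01/M00). By construction mu00 = M00 and
#' mu10 = mu01 = 0. For an all-zero matrix the centroid is undefined; a zero
#' vector is returned with a warning rather than failing the pipeline.
#'
#' @param matrix Square numeric matrix.
#' @return Named numeric vector of 10 moments (attribute `kind = "central"`).
#' @export
central_moments <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  a <- seq_len(nrow(matrix))
  m00 <- sum(matrix)
  if (m00 == 0) {
    warning("all-zero matrix: centroid undefined, returning zero central moments",
            call. = FALSE)
    return(moment_vector(numeric(10L), "central"))
  }
  abar <- drop(crossprod(a, rowSums(matrix))) / m00
  bbar <- drop(crossprod(a, colSums(matrix))) / m00
  da <- a - abar
  db <- a - bbar
  vals <- apply(MOMENT_ORDERS, 1L, function(o) {
    drop(crossprod(da^o[["j"]], matrix %*% db^o[["k"]]))
  })
  moment_vector(vals, "central")
}

#' Concatenated 30-moment block of one matrix
#'
#' Raw (10), central (10) and Hahn (10) moments of a square matrix, in that
#' fixed order. The Hahn basis is built (and cached) at the matrix dimension;
#' for matrices smaller than 4 x 4 the Hahn degrees beyond N-1 do not exist
#' and those entries are zero.
#'
#' @param matrix Square numeric matrix.
#' @param hahn_x,hahn_y Non-negative Hahn shape parameters (default 0).
#' @return Named numeric vector of 30 values
#'   (`raw_00` ... `central_00` ... `hahn_03`).
#' @export
moment_block <- function(matrix, hahn_x = 0, hahn_y = 0) {
  n <- nrow(matrix)
  basis <- cached_hahn_basis(n, hahn_x, hahn_y, min(3L, n - 1L))
  vals <- c(raw_moments(matrix), central_moments(matrix),
            hahn_moments(matrix, basis))
  stats::setNames(vals, paste(rep(c("raw", "central", "hahn"), each = 10L),
                              rownames(MOMENT_ORDERS), sep = "_"))
}
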