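# Discrete orthogonal Hahn basis and Hahn moments.
#
# Polynomials are the classical Hahn family Q_m(i; alpha = y, beta = x, N-1)
# evaluated by a stable term-ratio recurrence of the terminating 3F2 series,
# weighted by the textbook orthogonality weight
#   rho(i) proportional to Gamma(y+i+1) Gamma(x+N-i) / (Gamma(i+1) Gamma(N-i)),
# computed in log-Gamma space so large N and shape parameters cannot
# overflow. The square norm k2_m is evaluated numerically as sum_i Q_m^2 rho,
# which makes the weighted rows orthonormal under plain summation by
# construction. At x = y = 0 the family reduces to the discrete Chebyshev
# polynomials (uniform weight).

.basis_cache <- new.env(parent = emptyenv())

#' Build a weighted discrete Hahn basis
#'
#' Returns the (max_degree+1) x N table of weighted polynomial values
#' \eqn{\tilde h_m(i) = Q_m(i) \sqrt{\rho(i)/k^2_m}}, whose rows are
#' orthonormal under the summation inner product.
#'
#' @param N Number of sample points (the matrix dimension), N >= 1.
#' @param x,y Non-negative shape parameters (default 0).
#' @param max_degree Highest polynomial degree, must be < N (default
#'   `min(3, N - 1)`).
#' @return Object of class `hahn_basis` with fields `params` (x, y, N),
#'   `max_degree`, `table` (weighted values), `norms` (numeric square norms
#'   k2_m, up to one overall weight scaling) and `weight` (rho, scaled to
#'   max 1).
#' @examples
#' b <- hahn_basis(15)
#' max(abs(b$table %*% t(b$table) - diag(4)))  # orthonormal rows
#' @export
hahn_basis <- function(N, x = 0, y = 0, max_degree = min(3L, N - 1L)) {
  stopifnot(is_count(N), is.numeric(x), is.numeric(y), x >= 0, y >= 0)
  if (!(is.numeric(max_degree) && max_degree >= 0 && max_degree == as.integer(max_degree))) {
    stop("max_degree must be a non-negative integer", call. = FALSE)
  }
  if (max_degree >= N) {
    stop("max_degree (", max_degree, ") must be smaller than N (", N, ")",
         call. = FALSE)
  }
  i <- 0:(N - 1L)
  log_rho <- lgamma(x + N - i) + lgamma(y + i + 1) - lgamma(i + 1) - lgamma(N - i)
  rho <- exp(log_rho - max(log_rho))
  Q <- matrix(0, nrow = max_degree + 1L, ncol = N)
  for (m in 0:max_degree) {
    term <- rep(1, N)
    acc <- rep(1, N)
    if (m > 0) {
      for (k in seq_len(m)) {
        term <- term * ((-m + k - 1) * (m + x + y + k) * (-i + k - 1)) /
          ((y + k) * (-(N - 1) + k - 1) * k)
        acc <- acc + term
      }
    }
    if (any(!is.finite(acc))) {
      bad <- i[which(!is.finite(acc))[1L]]
      stop("non-finite Hahn polynomial value at degree m = ", m, ", i = ", bad,
           call. = FALSE)
    }
    Q[m + 1L, ] <- acc
  }
  rho_mat <- matrix(rho, nrow = max_degree + 1L, ncol = N, byrow = TRUE)
  norms <- rowSums(Q^2 * rho_mat)
  W <- Q * sqrt(rho_mat / norms)
  structure(list(params = list(x = x, y = y, N = as.integer(N)),
                 max_degree = as.integer(max_degree),
                 table = W, norms = norms, weight = rho),
            class = "hahn_basis")
}

#' @export
print.hahn_basis <- function(x, ...) {
  cat("<hahn_basis> N =", x$params$N, " x =", x$params$x, " y =", x$params$y,
      " degrees 0..", x$max_degree, "\n", sep = "")
  invisible(x)
}

cached_hahn_basis <- function(N, x = 0, y = 0, max_degree = min(3L, N - 1L)) {
  key <- sprintf("N%d_x%.17g_y%.17g_d%d", N, x, y, max_degree)
  b <- .basis_cache[[key]]
  if (is.null(b)) {
    b <- hahn_basis(N, x, y, max_degree)
    .basis_cache[[key]] <- b
  }
  b
}

#' Hahn moments up to degree 3
#'
#' Projects a square matrix onto the weighted Hahn basis:
#' H_uv = sum_b sum_a beta_ab htilde_u(b) htilde_v(a), with 0-based sample
#' index. All ten (u,v) with u+v <= 3 are returned in the fixed order
#' (00, 01, 10, 11, 02, 20, 12, 21, 30, 03). Degrees that do not exist for a
#' small basis (N - 1 < 3) yield zeros.
#'
#' @param matrix Square numeric matrix with dimension equal to the basis N.
#' @param basis A [hahn_basis()].
#' @return Named numeric vector of 10 moments (attribute `kind = "hahn"`).
#' @export
hahn_moments <- function(matrix, basis) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            inherits(basis, "hahn_basis"))
  if (nrow(matrix) != basis$params$N) {
    stop("matrix dimension (", nrow(matrix), ") does not match basis N (",
         basis$params$N, ")", call. = FALSE)
  }
  W <- basis$table
  H <- W %*% t(matrix) %*% t(W)   # H[u+1, v+1]
  vals <- apply(MOMENT_ORDERS, 1L, function(o) {
    u <- o[["j"]]
    v <- o[["k"]]
    if (u > basis$max_degree || v > basis$max_degree) 0 else H[u + 1L, v + 1L]
  })
  moment_vector(vals, "hahn")
}

#' Full Hahn transform and its inverse
#'
#' With a complete basis (max_degree = N - 1) the weighted Hahn transform is
#' an isometry; `hahn_reconstruct` inverts it exactly.
#'
#' @param matrix Square numeric matrix (for `hahn_transform`).
#' @param H Full N x N Hahn coefficient matrix (for `hahn_reconstruct`).
#' @param basis A complete [hahn_basis()] with `max_degree = N - 1`.
#' @return `hahn_transform`: the N x N coefficient matrix H with
#'   H[u+1, v+1] = H_uv; `hahn_reconstruct`: the reconstructed matrix.
#' @export
hahn_transform <- function(matrix, basis) {
  stopifnot(inherits(basis, "hahn_basis"),
            basis$max_degree == basis$params$N - 1L,
            nrow(matrix) == basis$params$N)
  W <- basis$table
  W %*% t(matrix) %*% t(W)
}

#' @rdname hahn_transform
#' @export
hahn_reconstruct <- function(H, basis) {
  stopifnot(inherits(basis, "hahn_basis"),
            basis$max_degree == basis$params$N - 1L,
            nrow(H) == basis$params$N)
  W <- basis$table
  t(W) %*% t(H) %*% W
}
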