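# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm rgamma rpois rnbinom runif median sd setNames
#' @importFrom stats coef logLik pchisq p.adjust var qlogis optimize
NULL

#' Evaluate an expression under a local RNG seed
#'
#' Wrapper around [withr::with_seed()] so that every generator in the package
#' is a pure function of its seed and parameters.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Rodrigues rotation vector to matrix
#'
#' @param rvec numeric length-3 axis-angle vector (radians).
#' @return 3x3 rotation matrix.
#' @keywords internal
rodrigues_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  k <- rvec / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation matrix to Rodrigues vector
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 axis-angle vector.
#' @keywords internal
matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near 180 degrees: extract axis from R + I
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs using off-diagonal terms
    i <- which.max(axis)
    if (i == 1) axis <- c(axis[1], A[1, 2] / axis[1], A[1, 3] / axis[1])
    if (i == 2) axis <- c(A[1, 2] / axis[2], axis[2], A[2, 3] / axis[2])
    if (i == 3) axis <- c(A[1, 3] / axis[3], A[2, 3] / axis[3], axis[3])
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(theta)) * theta
}

#' Project a matrix onto the nearest rotation (SVD polar decomposition)
#' @keywords internal
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    s$v[, 3] <- -s$v[, 3]
    R <- s$u %*% t(s$v)
  }
  R
}

#' Row-wise medians of a numeric matrix
#'
#' Vectorised (single `order()` pass) so per-pixel temporal medians over a
#' frame stack stay cheap without a dedicated matrix-statistics dependency.
#'
#' @param m numeric matrix.
#' @return numeric vector of length `nrow(m)`.
#' @keywords internal
row_medians <- function(m) {
  n <- ncol(m)
  srt <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  if (n %% 2 == 1) srt[, (n + 1) / 2] else (srt[, n / 2] + srt[, n / 2 + 1]) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
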