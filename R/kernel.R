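#' Heavy-tailed radial basis kernel
#'
#' The kernel family
#' `k(x, y) = exp( -(1/sigma) * sum_d | x_d^a - y_d^a |^b )`
#' generalizes the Gaussian RBF (`a = 1, b = 2`) and the Laplacian kernel
#' (`a = 1, b = 1`); sub-Gaussian exponents give heavier tails, which is
#' the default used by the identification pipeline. Powers of negative
#' coordinates use the signed convention `sign(v) |v|^a` so the kernel is
#' well defined for any real feature (generalized Hurst exponents can be
#' negative).
#'
#' @param sigma bandwidth `sigma > 0`, or `NA` to have the cross-validation
#'   routines set it per training fold by the median pairwise-distance
#'   heuristic.
#' @param a,b positive exponents of the kernel family (defaults `a = 1`,
#'   `b = 1`, the heavy-tailed Laplacian-like case).
#' @param cost soft-margin cost `C` of the support vector machine (used by
#'   the classification routines, not by the kernel itself).
#' @return Object of class `htrbf_spec`.
#' @export
htrbf_spec <- function(sigma = NA_real_, a = 1, b = 1, cost = 1) {
  if (!is.na(sigma) && sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (a <= 0 || b <= 0) stop("exponents a and b must be > 0", call. = FALSE)
  structure(list(kind = "htrbf", sigma = sigma, a = a, b = b, cost = cost),
            class = "htrbf_spec")
}

signed_power <- function(v, a) sign(v) * abs(v)^a

#' @rdname htrbf_spec
#' @param x,y numeric feature vectors of equal length.
#' @param spec an `htrbf_spec`; its `sigma` must be set.
#' @return `htrbf_kernel()`: the kernel value in `(0, 1]`; `k(x, x) = 1`.
#' @export
htrbf_kernel <- function(x, y, spec = htrbf_spec(sigma = 1)) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("kernel inputs must be finite", call. = FALSE)
  if (is.na(spec$sigma))
    stop("spec$sigma is unset; supply a bandwidth", call. = FALSE)
  exp(-sum(abs(signed_power(x, spec$a) - signed_power(y, spec$a))^spec$b) / spec$sigma)
}

# kernlab-compatible kernel closure for a fully specified htrbf_spec.
as_kernlab_kernel <- function(spec) {
  force(spec)
  k <- function(x, y = NULL) {
    if (is.null(y)) return(1)
    htrbf_kernel(x, y, spec)
  }
  class(k) <- "kernel"
  k
}

# Pairwise htrbf distance sum_d |x^a - y^a|^b between rows of X (and rows of
# Y if given); used for Gram matrices and the median heuristic.
htrbf_distances <- function(X, Y = NULL, a = 1, b = 1) {
  Xa <- signed_power(as.matrix(X), a)
  Ya <- if (is.null(Y)) Xa else signed_power(as.matrix(Y), a)
  n <- nrow(Xa); m <- nrow(Ya)
  D <- matrix(0, n, m)
  for (d in seq_len(ncol(Xa)))
    D <- D + abs(outer(Xa[, d], Ya[, d], `-`))^b
  D
}

# Median-heuristic bandwidth: median of the pairwise htrbf distances over
# the (training) rows of X; falls back to 1 when the median is 0.
median_heuristic_sigma <- function(X, a = 1, b = 1) {
  D <- htrbf_distances(X, a = a, b = b)
  m <- stats::median(D[upper.tri(D)])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Gram matrix of the heavy-tailed RBF kernel
#'
#' @param X numeric matrix, one sample per row.
#' @param spec an `htrbf_spec` with `sigma` set.
#' @return Symmetric positive matrix of kernel evaluations with unit
#'   diagonal.
#' @export
htrbf_gram <- function(X, spec) {
  if (is.na(spec$sigma))
    stop("spec$sigma is unset; supply a bandwidth", call. = FALSE)
  exp(-htrbf_distances(X, a = spec$a, b = spec$b) / spec$sigma)
}
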