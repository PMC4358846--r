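#' Segment origins for one partition corner
#'
#' Partitions an `M x N` surface into `floor(M/s) x floor(N/s)` non-overlapping
#' `s x s` segments. Because `M` and `N` need not be multiples of `s`, a margin
#' is left untiled; starting the tiling from each of the four corners moves
#' that margin to the opposite side, and the full analysis pools the segments
#' of all four tilings.
#'
#' @param M,N surface dimensions.
#' @param s integer window size, `6 <= s <= floor(min(M, N)/4)`.
#' @param corner one of `"TL"`, `"TR"`, `"BL"`, `"BR"` (top-left, top-right,
#'   bottom-left, bottom-right).
#' @return Integer matrix with columns `r`, `t`: 0-based offsets so that a
#'   segment occupies rows `r + 1 ... r + s` and columns `t + 1 ... t + s`.
#' @export
partition_indices <- function(M, N, s, corner = c("TL", "TR", "BL", "BR")) {
  corner <- match.arg(corner)
  s <- as.integer(s)
  Ms <- M %/% s
  Ns <- N %/% s
  # the full analysis restricts s to 6 ... min(M, N)/4 via scale_grid(); at
  # the partition level we only require a workable tiling
  if (s < 6L || Ms < 2L || Ns < 2L)
    stop(sprintf("window size s = %d outside the valid range (s >= 6 with at least 2 segments per direction; surface is %d x %d)",
                 s, M, N), call. = FALSE)
  r0 <- if (corner %in% c("BL", "BR")) M - Ms * s else 0L
  t0 <- if (corner %in% c("TR", "BR")) N - Ns * s else 0L
  r <- r0 + (seq_len(Ms) - 1L) * s
  t <- t0 + (seq_len(Ns) - 1L) * s
  cbind(r = rep(r, times = Ns), t = rep(t, each = Ms))
}

#' Two-dimensional cumulative sum of a segment
#'
#' `G(i, j) = sum_{k1 <= i} sum_{k2 <= j} X(k1, k2)` over the raw segment
#' values (no mean subtraction).
#'
#' @param segment square numeric matrix.
#' @return Matrix of the same size holding the double partial sums.
#' @export
cumulative_sum <- function(segment) {
  segment <- as.matrix(segment)
  stopifnot_finite(segment, "segment")
  t(apply(apply(segment, 2L, cumsum), 1L, cumsum))
}

#' Least-squares plane detrending of a profile
#'
#' Fits the local trend `a*i + b*j + c` to an `s x s` profile by ordinary
#' least squares over the grid points (i = row, j = column, 1-based) and
#' returns the residual surface. The grid design is orthogonal after
#' centering, so the coefficients have a closed form.
#'
#' @param profile square numeric matrix (the cumulative-sum surface).
#' @return A list with `coefficients` (named `a`, `b`, `c`) and `residuals`
#'   (matrix of the same size; they sum to zero and are orthogonal to both
#'   index coordinates).
#' @export
detrend_plane <- function(profile) {
  profile <- as.matrix(profile)
  s <- nrow(profile)
  if (s < 2L || ncol(profile) != s)
    stop("profile must be a square matrix with side >= 2", call. = FALSE)
  ic <- seq_len(s) - (s + 1) / 2
  sic2 <- sum(ic^2)
  gbar <- mean(profile)
  a <- sum(ic * rowSums(profile)) / (s * sic2)
  b <- sum(ic * colSums(profile)) / (s * sic2)
  cc <- gbar - (a + b) * (s + 1) / 2
  trend <- outer(a * seq_len(s), b * seq_len(s), `+`) + cc
  list(coefficients = c(a = a, b = b, c = cc),
       residuals = profile - trend)
}

#' Root-mean-square local fluctuation of a detrended segment
#'
#' @param residuals square numeric matrix of detrending residuals.
#' @return `sqrt(mean(residuals^2))`.
#' @export
local_fluctuation <- function(residuals) {
  stopifnot_finite(residuals, "residuals")
  sqrt(mean(residuals^2))
}

# Blockwise cumulative sum down the rows, restarting every `s` rows.
blockwise_cumsum <- function(Z, s) {
  C1 <- apply(Z, 2L, cumsum)
  if (!is.matrix(C1)) C1 <- matrix(C1, nrow = nrow(Z))
  nb <- nrow(Z) %/% s
  if (nb > 1L) {
    prev <- C1[s * seq_len(nb - 1L), , drop = FALSE]
    prev <- rbind(0, prev)[rep(seq_len(nb), each = s), , drop = FALSE]
    C1 <- C1 - prev
  }
  C1
}

# All local fluctuations F(m, n, s) at one scale for one corner, computed
# without materializing per-segment matrices: within-block double cumulative
# sums followed by closed-form plane regression via per-block sums.
corner_fluctuations <- function(X, s, corner) {
  M <- nrow(X); N <- ncol(X)
  Ms <- M %/% s; Ns <- N %/% s
  r0 <- if (corner %in% c("BL", "BR")) M - Ms * s else 0L
  t0 <- if (corner %in% c("TR", "BR")) N - Ns * s else 0L
  Z <- X[r0 + seq_len(Ms * s), t0 + seq_len(Ns * s), drop = FALSE]
  G <- t(blockwise_cumsum(t(blockwise_cumsum(Z, s)), s))
  ic <- seq_len(s) - (s + 1) / 2
  sic2 <- sum(ic^2)
  S1 <- block_sums(G, s)
  S2 <- block_sums(G * G, s)
  Si <- block_sums(G * rep(ic, Ms), s)              # row weights recycle down columns
  Sj <- t(block_sums(t(G) * rep(ic, Ns), s))
  ss_res <- S2 - S1^2 / s^2 - (Si^2 + Sj^2) / (s * sic2)
  ss_res[ss_res < 0] <- 0                           # guard rounding in exact-plane segments
  sqrt(ss_res / s^2)
}

# Generalized mean of order q of the pooled segment fluctuations, computed in
# log space so |q| = 15 does not overflow.
generalized_mean <- function(f, q, q0_tol = 1e-9) {
  if (abs(q) < q0_tol) {
    if (any(f == 0))
      stop("degenerate surface: a segment has zero fluctuation, so the q = 0 (log) average is undefined; add a small dither or crop the flat region",
           call. = FALSE)
    return(exp(mean(log(f))))
  }
  if (q < 0 && any(f == 0))
    stop(sprintf("degenerate surface: segment %d has zero fluctuation, so negative moment orders are undefined; add a small dither or crop the flat region",
                 which(f == 0)[1L]), call. = FALSE)
  lf <- log(f)
  z <- q * lf
  m <- max(z)
  exp((m + log(mean(exp(z - m)))) / q)
}

#' q-th order fluctuation function at one scale
#'
#' Pools the local fluctuations of every segment from the requested partition
#' corners and forms their generalized mean of order `q` for each entry of
#' the `q` grid (geometric mean for `|q|` below `q0_tol`). The result is
#' non-decreasing in `q` by the generalized-mean inequality.
#'
#' @param surface a [gray_surface] or numeric matrix.
#' @param s window size.
#' @param q_grid numeric vector of moment orders (see [q_grid()]).
#' @param corners character subset of `c("TL", "TR", "BL", "BR")`.
#' @param q0_tol moment orders with `|q| < q0_tol` use the q = 0 geometric-
#'   mean form.
#' @return Named numeric vector of `F_q(s)`, one entry per moment order.
#' @export
fluctuation_function <- function(surface, s, q_grid = default_q_grid(),
                                 corners = c("TL", "TR", "BL", "BR"),
                                 q0_tol = 1e-9) {
  X <- unclass(as.matrix(surface))
  f <- unlist(lapply(corners, function(cn) corner_fluctuations(X, s, cn)),
              use.names = FALSE)
  out <- vapply(q_grid, function(q) generalized_mean(f, q, q0_tol), numeric(1))
  names(out) <- vapply(as.numeric(q_grid), as.character, character(1))
  out
}

#' Fluctuation table over the full scale and moment grids
#'
#' Runs the complete partition / cumulative-sum / plane-detrend / fluctuation
#' pipeline at every scale of the grid, pooling segments across the requested
#' corners, and assembles the `F_q(s)` matrix used for the scaling
#' regressions.
#'
#' @inheritParams fluctuation_function
#' @param scale_grid increasing integer window sizes (see [scale_grid()]);
#'   `NULL` uses [default_scales()] for the surface dimensions.
#' @return An object of class `fluctuation_table`: list with `F` (matrix,
#'   rows = moment orders, columns = scales), `scales`, `q`, and
#'   `n_segments` (pooled segment count per scale).
#' @export
compute_fluctuation_table <- function(surface, scale_grid = NULL,
                                      q_grid = default_q_grid(),
                                      corners = c("TL", "TR", "BL", "BR"),
                                      q0_tol = 1e-9) {
  X <- unclass(as.matrix(surface))
  if (is.null(scale_grid))
    scale_grid <- default_scales(nrow(X), ncol(X))
  corners <- match.arg(corners, c("TL", "TR", "BL", "BR"), several.ok = TRUE)
  Fm <- matrix(NA_real_, length(q_grid), length(scale_grid),
               dimnames = list(vapply(as.numeric(q_grid), as.character, character(1)),
                               as.character(as.integer(scale_grid))))
  n_seg <- integer(length(scale_grid))
  for (k in seq_along(scale_grid)) {
    s <- scale_grid[k]
    f <- unlist(lapply(corners, function(cn) corner_fluctuations(X, s, cn)),
                use.names = FALSE)
    n_seg[k] <- length(f)
    Fm[, k] <- tryCatch(
      vapply(q_grid, function(q) generalized_mean(f, q, q0_tol), numeric(1)),
      error = function(e) stop(sprintf("at scale s = %d: %s", s, conditionMessage(e)),
                               call. = FALSE))
  }
  structure(list(F = Fm, scales = as.integer(scale_grid),
                 q = as.numeric(q_grid), n_segments = n_seg),
            class = "fluctuation_table")
}

#' @export
print.fluctuation_table <- function(x, ...) {
  cat(sprintf("<fluctuation_table> %d moment orders x %d scales (s = %d ... %d), %d-%d segments per scale\n",
              length(x$q), length(x$scales), min(x$scales), max(x$scales),
              min(x$n_segments), max(x$n_segments)))
  invisible(x)
}
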