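#' Generalized Hurst exponents from a fluctuation table
#'
#' For each moment order `q`, fits `ln F_q(s) = h(q) ln s + const` by
#' ordinary least squares over the full scale grid. The slope is the
#' generalized Hurst exponent `h(q)`; `h(2)` is the classical Hurst index of
#' the surface. No scale subrange is selected; the per-q coefficient of
#' determination is reported so scaling breaks can be detected.
#'
#' @param table a `fluctuation_table` from [compute_fluctuation_table()].
#' @return Object of class `hurst_spectrum`: data frame with columns `q`,
#'   `h`, `intercept`, `r_squared`.
#' @export
estimate_hq <- function(table) {
  stopifnot(inherits(table, "fluctuation_table"))
  if (length(table$scales) < 4L)
    stop("at least 4 scales are required to estimate h(q)", call. = FALSE)
  x <- log(table$scales)
  xc <- x - mean(x)
  fit <- t(apply(table$F, 1L, function(Fq) {
    y <- log(Fq)
    slope <- sum(xc * y) / sum(xc^2)
    intercept <- mean(y) - slope * mean(x)
    ssr <- sum((y - intercept - slope * x)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    c(slope, intercept, r2)
  }))
  out <- data.frame(q = table$q, h = fit[, 1L], intercept = fit[, 2L],
                    r_squared = pmin(pmax(fit[, 3L], 0), 1))
  class(out) <- c("hurst_spectrum", "data.frame")
  out
}

#' Mass exponent tau(q) from the Hurst spectrum
#'
#' `tau(q) = q h(q) - D_f` with support dimension `D_f = 2` for surfaces, so
#' `tau(0) = -2` identically.
#'
#' @param h_spec a `hurst_spectrum` (or a list/data frame with `q` and `h`).
#' @return Data frame with columns `q` and `tau`.
#' @export
tau_from_h <- function(h_spec) {
  data.frame(q = h_spec$q, tau = h_spec$q * h_spec$h - 2)
}

#' Generalized dimensions D_q from tau(q)
#'
#' `D_q = tau(q) / (q - 1)` for `q != 1`; the information dimension `D_1`
#' must instead be estimated from the box-entropy regression
#' ([estimate_D1()]). The correlation dimension `D_2` is returned as an
#' attribute when `q = 2` is on the grid.
#'
#' @param tau data frame with columns `q`, `tau` (from [tau_from_h()]).
#' @param q1_tol grid entries with `|q - 1| < q1_tol` are excluded.
#' @return Data frame with columns `q`, `Dq` (rows with `q = 1` removed) and
#'   attribute `D2`.
#' @export
dq_from_tau <- function(tau, q1_tol = 1e-9) {
  keep <- abs(tau$q - 1) >= q1_tol
  out <- data.frame(q = tau$q[keep], Dq = tau$tau[keep] / (tau$q[keep] - 1))
  i2 <- which(abs(out$q - 2) < 1e-9)
  attr(out, "D2") <- if (length(i2)) out$Dq[i2[1L]] else NA_real_
  out
}

#' Information dimension D1 by box-entropy regression
#'
#' Normalizes the surface to a probability measure, computes the box masses
#' `P(m, n) = (segment sum) / (total sum)` on the top-left tiling at each
#' scale, and regresses the entropy sum `sum P log P` on `log s`; the slope
#' is `D_1`. Empty boxes contribute 0 (the `p log p -> 0` limit).
#'
#' @param surface a [gray_surface] or numeric matrix with non-negative
#'   values and positive total sum.
#' @param scale_grid integer scales (`NULL`: [default_scales()]).
#' @return The slope `D_1` (numeric scalar) with attribute `entropy`
#'   (the per-scale entropy sums).
#' @export
estimate_D1 <- function(surface, scale_grid = NULL) {
  X <- unclass(as.matrix(surface))
  if (min(X) < 0)
    stop("D1 requires non-negative surface values; shift the surface first",
         call. = FALSE)
  total <- sum(X)
  if (total <= 0)
    stop("D1 requires a surface with positive total mass", call. = FALSE)
  if (is.null(scale_grid))
    scale_grid <- default_scales(nrow(X), ncol(X))
  ent <- vapply(scale_grid, function(s) {
    Ms <- nrow(X) %/% s; Ns <- ncol(X) %/% s
    P <- block_sums(X[seq_len(Ms * s), seq_len(Ns * s), drop = FALSE], s) / total
    sum(ifelse(P > 0, P * log(P), 0))
  }, numeric(1))
  x <- log(as.numeric(scale_grid))
  xc <- x - mean(x)
  slope <- sum(xc * ent) / sum(xc^2)
  structure(slope, entropy = ent)
}

#' Hoelder exponents and singularity spectrum by Legendre transform
#'
#' `alpha(q) = tau'(q)` is computed by central finite differences of `tau`
#' on the (possibly non-uniform) `q` grid; the endpoints, where only
#' one-sided differences exist, are discarded. The singularity spectrum is
#' `f(alpha) = q alpha(q) - tau(q)` on the same interior support.
#'
#' @param tau data frame with columns `q`, `tau`.
#' @return Data frame with columns `q`, `alpha`, `f` (interior grid points
#'   only). A warning is recorded if `alpha` is not non-increasing in `q`
#'   (spectrum folding from estimation noise); values are kept.
#' @export
legendre_spectrum <- function(tau) {
  q <- tau$q; tv <- tau$tau
  n <- length(q)
  if (n < 3L)
    stop("at least 3 moment orders are required for the Legendre transform",
         call. = FALSE)
  i <- 2:(n - 1L)
  alpha <- (tv[i + 1L] - tv[i - 1L]) / (q[i + 1L] - q[i - 1L])
  f <- q[i] * alpha - tv[i]
  if (any(diff(alpha) > 1e-8))
    warning("alpha(q) is not non-increasing: the singularity spectrum folds, likely from estimation noise",
            call. = FALSE)
  data.frame(q = q[i], alpha = alpha, f = f)
}

#' Width summaries of the singularity spectrum
#'
#' `delta_alpha = alpha_max - alpha_min` measures the width of the spectrum
#' (texture heterogeneity); `delta_f = f(alpha_max) - f(alpha_min)` its
#' asymmetry, evaluated at the moment orders attaining the extrema (ties
#' broken toward the smallest `|q|`, the best-estimated part of the
#' spectrum).
#'
#' @param spectrum data frame with columns `q`, `alpha`, `f` from
#'   [legendre_spectrum()].
#' @return Named numeric vector `alpha_max`, `alpha_min`, `delta_alpha`,
#'   `delta_f`.
#' @export
spectrum_widths <- function(spectrum) {
  pick <- function(target) {
    idx <- which(abs(spectrum$alpha - target) < 1e-12)
    idx[which.min(abs(spectrum$q[idx]))]
  }
  i_max <- pick(max(spectrum$alpha))
  i_min <- pick(min(spectrum$alpha))
  c(alpha_max = spectrum$alpha[i_max],
    alpha_min = spectrum$alpha[i_min],
    delta_alpha = spectrum$alpha[i_max] - spectrum$alpha[i_min],
    delta_f = spectrum$f[i_max] - spectrum$f[i_min])
}

#' Full multifractal analysis of one surface
#'
#' Composes the fluctuation table, the `h(q)` regression, `tau(q)`, the
#' generalized dimensions, the box-entropy `D_1` and the Legendre spectrum
#' into one result object.
#'
#' @inheritParams compute_fluctuation_table
#' @return Object of class `mfdfa_result`: list with elements `table`,
#'   `hurst` (h(q) fits), `tau`, `dims` (D_q), `D1`, `D2`, `spectrum`
#'   (alpha, f) and `widths`.
#' @export
mfdfa_spectrum <- function(surface, scale_grid = NULL,
                           q_grid = default_q_grid(),
                           corners = c("TL", "TR", "BL", "BR")) {
  X <- unclass(as.matrix(surface))
  if (is.null(scale_grid))
    scale_grid <- default_scales(nrow(X), ncol(X))
  tab <- compute_fluctuation_table(surface, scale_grid, q_grid, corners)
  hs <- estimate_hq(tab)
  tau <- tau_from_h(hs)
  dims <- dq_from_tau(tau)
  # D1 needs a non-negative measure; gray images already are, synthetic
  # zero-mean surfaces are shifted to their minimum first.
  Xpos <- if (min(X) < 0) X - min(X) else X
  D1 <- as.numeric(estimate_D1(Xpos, scale_grid))
  spec <- legendre_spectrum(tau)
  structure(list(table = tab, hurst = hs, tau = tau, dims = dims,
                 D1 = D1, D2 = attr(dims, "D2"),
                 spectrum = spec, widths = spectrum_widths(spec)),
            class = "mfdfa_result")
}

#' @export
print.mfdfa_result <- function(x, ...) {
  h2 <- x$hurst$h[which.min(abs(x$hurst$q - 2))]
  cat(sprintf("<mfdfa_result> h(2) = %.3f, delta_alpha = %.3f, delta_f = %.3f, D1 = %.3f, D2 = %.3f\n",
              h2, x$widths[["delta_alpha"]], x$widths[["delta_f"]], x$D1, x$D2))
  invisible(x)
}

#' Feature vector names used throughout the package
#' @return Character vector of the 12 descriptor names.
#' @export
feature_names <- function() {
  c("h_m3", "h_m2", "h_m1", "h_p1", "h_p2", "h_p3",
    "alpha_max", "alpha_min", "delta_alpha", "delta_f", "D1", "D2")
}

#' Extract the 12-descriptor multifractal feature vector
#'
#' Runs the full pipeline and reads off the texture descriptors used for
#' identification: `h(q)` at `q = -3, -2, -1, 1, 2, 3`, the spectrum
#' summaries `alpha_max`, `alpha_min`, `delta_alpha`, `delta_f`, and the
#' information and correlation dimensions `D1`, `D2`.
#'
#' @inheritParams mfdfa_spectrum
#' @return Named numeric vector of length 12 (names [feature_names()]).
#' @export
extract_features <- function(surface, scale_grid = NULL,
                             q_grid = default_q_grid(),
                             corners = c("TL", "TR", "BL", "BR")) {
  res <- mfdfa_spectrum(surface, scale_grid, q_grid, corners)
  hq <- function(qv) res$hurst$h[which(abs(res$hurst$q - qv) < 1e-9)[1L]]
  out <- c(hq(-3), hq(-2), hq(-1), hq(1), hq(2), hq(3),
           res$widths[["alpha_max"]], res$widths[["alpha_min"]],
           res$widths[["delta_alpha"]], res$widths[["delta_f"]],
           res$D1, res$D2)
  names(out) <- feature_names()
  if (!all(is.finite(out)))
    stop("non-finite feature extracted; the surface may be degenerate", call. = FALSE)
  out
}
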