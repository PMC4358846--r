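#' Scale and moment-order grids
#'
#' The fluctuation function is evaluated on a grid of integer window sizes
#' `s` with `6 <= s <= floor(min(M, N) / 4)` and on a grid of moment orders
#' `q` spanning `[-15, 15]`. `default_scales()` places about `n_scales`
#' approximately geometrically spaced integers in the valid range so the
#' log-log regression has uniform leverage in `log s`; `default_q_grid()`
#' uses the integers -15...15 plus -0.5 and 0.5 for resolution of the
#' finite-difference derivative near q = 0.
#'
#' @param M,N surface dimensions.
#' @param n_scales target number of scales (duplicates after rounding are
#'   dropped).
#' @name grids
NULL

#' @rdname grids
#' @return `default_scales()`: an increasing integer vector of window sizes.
#' @export
default_scales <- function(M, N, n_scales = 20L) {
  s_max <- floor(min(M, N) / 4)
  scale_grid(unique(round(exp(seq(log(6), log(s_max), length.out = n_scales)))),
             M = M, N = N)
}

#' @rdname grids
#' @param scales increasing integer window sizes to validate against the
#'   surface dimensions.
#' @export
scale_grid <- function(scales, M, N) {
  scales <- as.integer(scales)
  s_max <- floor(min(M, N) / 4)
  if (any(scales < 6L) || any(scales > s_max))
    stop(sprintf("scales must satisfy 6 <= s <= floor(min(M, N)/4) = %d", s_max),
         call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing", call. = FALSE)
  if (length(scales) < 4L)
    stop("at least 4 scales are required for the log-log regression; the surface is too small for this grid",
         call. = FALSE)
  structure(scales, class = c("scale_grid", "integer"))
}

#' @rdname grids
#' @param q_values increasing numeric moment orders; must contain -3, -2,
#'   -1, 1, 2, 3 (the h(q) feature orders) and reach -15 and 15.
#' @return `default_q_grid()` / `q_grid()`: a validated numeric vector of
#'   moment orders.
#' @export
q_grid <- function(q_values) {
  q_values <- as.numeric(q_values)
  if (is.unsorted(q_values, strictly = TRUE))
    stop("q values must be strictly increasing", call. = FALSE)
  need <- c(-15, -3, -2, -1, 1, 2, 3, 15)
  if (!all(vapply(need, function(q) any(abs(q_values - q) < 1e-12), logical(1))))
    stop("q grid must contain -15, -3, -2, -1, 1, 2, 3 and 15", call. = FALSE)
  if (!any(abs(q_values) < 1e-9))
    stop("q grid must contain a value treated as q = 0", call. = FALSE)
  structure(q_values, class = c("q_grid", "numeric"))
}

#' @rdname grids
#' @export
default_q_grid <- function() {
  q_grid(sort(c(-15:15, -0.5, 0.5)))
}
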