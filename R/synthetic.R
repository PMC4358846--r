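#' Fractional-Brownian-type test surface
#'
#' Spectrally synthesizes an isotropic fractional Brownian sheet with power
#' spectrum proportional to `|f|^-(2H + 2)` and returns its mixed
#' (rectangular) increments as a stationary, zero-mean texture. The analysis
#' pipeline's cumulative-sum step integrates these increments back into the
#' sheet, so the estimated generalized Hurst exponent satisfies
#' `h(q) ~ H` for all `q` (a monofractal surface); this is the exact
#' two-dimensional analog of applying detrended fluctuation analysis to
#' fractional Gaussian noise.
#'
#' The increments are synthesized on a lattice `oversample` times finer and
#' block-summed down to the requested size. Block-summing rectangular
#' increments is the exact decimation of the underlying sheet, so this
#' removes the near-Nyquist deficiency of plain spectral synthesis while
#' preserving the scaling law (verified by the increment-variance
#' self-check in the test suite).
#'
#' @param H Hurst exponent in `(0, 1)`.
#' @param size integer `(rows, cols)` of the returned matrix.
#' @param seed integer seed; fixed seeds give identical surfaces.
#' @param oversample integer synthesis refinement factor (>= 1).
#' @return Numeric `rows x cols` matrix, zero mean, unit variance scale.
#' @export
fbm_surface <- function(H, size = c(256L, 256L), seed = 1L, oversample = 4L) {
  if (H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)", call. = FALSE)
  rows <- as.integer(size[1L]); cols <- as.integer(size[2L])
  ov <- as.integer(oversample)
  if (ov < 1L) stop("oversample must be >= 1", call. = FALSE)
  ro <- rows * ov; co <- cols * ov
  # synthesize on a 2x grid to suppress periodic wrap-around, then crop
  L <- 2L * (max(ro, co) + 1L)
  fr <- c(0:(L %/% 2), -((L - L %/% 2 - 1L):1)) / L
  f2 <- outer(fr^2, fr^2, `+`)
  amp <- f2^(-(H + 1) / 2)
  amp[1L, 1L] <- 0                       # no DC component
  B <- with_seed(seed, {
    noise <- matrix(stats::rnorm(L * L), L, L) +
      1i * matrix(stats::rnorm(L * L), L, L)
    Re(stats::fft(amp * noise, inverse = TRUE)) / L
  })
  B <- B[seq_len(ro + 1L), seq_len(co + 1L)]
  X <- B[-1L, -1L] - B[-(ro + 1L), -1L] - B[-1L, -(co + 1L)] +
    B[-(ro + 1L), -(co + 1L)]
  if (ov > 1L) {
    gr <- rep(seq_len(rows), each = ov)
    gc <- rep(seq_len(cols), each = ov)
    X <- t(rowsum(t(rowsum(X, gr, reorder = FALSE)), gc, reorder = FALSE))
  }
  X <- X - mean(X)
  X / stats::sd(X)
}

#' Multiplicative-cascade multifractal measure
#'
#' Recursive 2x2 subdivision: starting from unit mass on one cell, every
#' cell splits into four children whose masses are the parent mass times the
#' weights `p1..p4`. With `shuffle = TRUE` the placement of the four weights
#' is randomized independently per cell (a randomized cascade); otherwise
#' the placement is fixed (top-left, top-right, bottom-left, bottom-right).
#' The result is an exactly multifractal measure with the closed-form mass
#' exponent of [cascade_tau_analytic()].
#'
#' @param weights four non-negative weights summing to 1.
#' @param depth recursion depth; the output is a `2^depth x 2^depth` matrix.
#' @param shuffle randomize weight placement per subdivision.
#' @param seed integer seed (only used when `shuffle = TRUE`).
#' @return Non-negative matrix with total mass 1.
#' @export
cascade_surface <- function(weights, depth, shuffle = FALSE, seed = 1L) {
  weights <- as.numeric(weights)
  if (length(weights) != 4L || any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be 4 non-negative values summing to 1", call. = FALSE)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  build <- function() {
    m <- matrix(1, 1L, 1L)
    for (lev in seq_len(depth)) {
      Lc <- nrow(m)
      n_cells <- Lc * Lc
      if (shuffle) {
        keys <- matrix(stats::runif(4L * n_cells), 4L, n_cells)
        ord <- apply(keys, 2L, order)
        W <- array(weights[ord], dim = c(4L, Lc, Lc))
      } else {
        W <- array(rep(weights, n_cells), dim = c(4L, Lc, Lc))
      }
      oi <- seq(1L, 2L * Lc, by = 2L); ei <- oi + 1L
      new <- matrix(0, 2L * Lc, 2L * Lc)
      new[oi, oi] <- m * matrix(W[1L, , ], Lc, Lc)
      new[oi, ei] <- m * matrix(W[2L, , ], Lc, Lc)
      new[ei, oi] <- m * matrix(W[3L, , ], Lc, Lc)
      new[ei, ei] <- m * matrix(W[4L, , ], Lc, Lc)
      m <- new
    }
    m
  }
  if (shuffle) with_seed(seed, build()) else build()
}

#' Closed-form scaling exponents of a multiplicative cascade
#'
#' For a 2x2 cascade with weights `p1..p4`, the partition-function exponent
#' is `tau(q) = -log2(sum_i p_i^q)`; its exact derivative gives the Hoelder
#' exponent `alpha(q) = -sum p_i^q log2 p_i / sum p_i^q` and the spectrum
#' `f(alpha) = q alpha(q) - tau(q)`. These serve as the analytic oracle for
#' the estimators.
#'
#' @param weights four non-negative weights summing to 1.
#' @param q numeric vector of moment orders; zero weights are only allowed
#'   for `q > 0`.
#' @return Data frame with columns `q`, `tau`, `alpha`, `f`.
#' @export
cascade_tau_analytic <- function(weights, q) {
  weights <- as.numeric(weights)
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0))
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (any(weights == 0) && any(q <= 0))
    stop("zero weights make tau(q) undefined for q <= 0", call. = FALSE)
  out <- lapply(q, function(qq) {
    pq <- weights^qq
    s <- sum(pq)
    alpha <- -sum(pq * log2(weights)) / s
    tau <- -log2(s)
    data.frame(q = qq, tau = tau, alpha = alpha, f = qq * alpha - tau)
  })
  do.call(rbind, out)
}

#' Box-counting estimate of the mass exponent tau(q)
#'
#' Independent estimator used to validate the cascade generator and
#' cross-check multifractality diagnostics: for dyadic box sizes, the
#' partition function `Z(q, l) = sum_boxes P_box^q` is regressed as
#' `log Z` against `log(l / L)`; the slope is `tau(q)`. Empty boxes are
#' excluded for `q <= 0` with a warning.
#'
#' @param measure non-negative matrix with dyadic (power-of-two) square side.
#' @param q numeric vector of moment orders.
#' @return Data frame with columns `q`, `tau`.
#' @export
box_counting_tau <- function(measure, q) {
  measure <- as.matrix(measure)
  L <- nrow(measure)
  if (ncol(measure) != L || bitwAnd(L, L - 1L) != 0L)
    stop("measure must be square with power-of-two side", call. = FALSE)
  if (min(measure) < 0) stop("measure must be non-negative", call. = FALSE)
  total <- sum(measure)
  depth <- as.integer(round(log2(L)))
  sizes <- 2^(0:(depth - 1L))
  P_list <- lapply(sizes, function(s) as.numeric(block_sums(measure, s)) / total)
  has_zero <- any(vapply(P_list, function(p) any(p == 0), logical(1)))
  if (has_zero && any(q <= 0))
    warning("empty boxes excluded from the partition sum for q <= 0", call. = FALSE)
  x <- log(sizes / L)
  xc <- x - mean(x)
  tau <- vapply(q, function(qq) {
    z <- vapply(P_list, function(p) {
      if (qq <= 0) p <- p[p > 0]
      # log-space accumulation so |q| = 15 does not overflow
      lp <- qq * log(p)
      m <- max(lp)
      m + log(sum(exp(lp - m)))
    }, numeric(1))
    sum(xc * z) / sum(xc^2)
  }, numeric(1))
  data.frame(q = q, tau = tau)
}

#' Map a cascade measure to a gray-level surface
#'
#' Raw cascade mass is extremely spiky; the default `"power"` transform
#' compresses it as `m^gamma` before scaling to 0..255. Because
#' `m^gamma` of a cascade is (up to a global factor) again a cascade with
#' weights proportional to `w^gamma`, the compressed surface is still
#' exactly multifractal, with a known transformed weight vector — so the
#' gray image keeps the class-specific scaling structure at an image-like
#' dynamic range. A `"log"` transform (min-max scaled log-mass) and a raw
#' `"linear"` scaling are also available; note the log of a cascade is no
#' longer a multifractal measure and carries far weaker class contrast. A
#' tiny positive dither is always added so no analysis segment is exactly
#' flat.
#'
#' @param measure positive matrix (e.g. from [cascade_surface()]).
#' @param transform `"power"` (default), `"log"` or `"linear"`.
#' @param gamma compression exponent of the power transform.
#' @param dither amplitude of the uniform dither (gray levels).
#' @param seed seed for the dither.
#' @return Numeric matrix of gray levels in approximately `[0, 255]`.
#' @export
cascade_to_gray <- function(measure, transform = c("power", "log", "linear"),
                            gamma = 0.25, dither = 1e-6, seed = 1L) {
  transform <- match.arg(transform)
  if (min(measure) <= 0)
    stop("gray mapping requires strictly positive mass (use positive weights)",
         call. = FALSE)
  g <- switch(transform,
    power = {
      p <- measure^gamma
      p / max(p) * 255
    },
    log = {
      lg <- log(measure)
      rng <- max(lg) - min(lg)
      if (rng > 0) (lg - min(lg)) / rng * 255 else
        matrix(127.5, nrow(measure), ncol(measure))
    },
    linear = measure / max(measure) * 255)
  g + with_seed(seed, matrix(stats::runif(length(g), 0, dither),
                             nrow(g), ncol(g)))
}

# Graded family of cascade weight vectors: weight spread delta controls the
# strength of multifractality, giving species with well-separated textures.
species_weight_vectors <- function(n_species, delta_range = c(0.01, 0.08)) {
  deltas <- seq(delta_range[1L], delta_range[2L], length.out = n_species)
  lapply(deltas, function(d) 0.25 + d * c(3, 1, -1, -3))
}

#' Synthetic labelled multi-species dataset
#'
#' Emulates a leaf-scan study design with known ground truth. In
#' `"surfaces"` mode, each species is a randomized multiplicative cascade
#' with its own weight vector (default: a graded family from near-uniform to
#' strongly heterogeneous, i.e. well-separated textures); each sample uses a
#' fresh cascade randomization, is mapped to gray levels by
#' [cascade_to_gray()], and receives additive Gaussian gray-level noise. In
#' `"features"` mode a Gaussian 12-descriptor table is drawn directly
#' (fast path for classifier tests): all descriptors share one within-species
#' distribution, and the descriptors named in `shift_features` receive
#' species-specific mean offsets with between-species standard deviation
#' `feature_shift` times the within-species standard deviation.
#'
#' @param n_species number of species (>= 2).
#' @param n_per_species samples per species.
#' @param output `"surfaces"` (list of [gray_surface]) or `"features"`
#'   (a `feature_table`).
#' @param base_weights optional list of `n_species` cascade weight vectors.
#' @param depth cascade depth in `"surfaces"` mode (surface side `2^depth`).
#' @param noise_sd additive gray-level noise standard deviation.
#' @param feature_shift between/within SD ratio of the injected species
#'   separation in `"features"` mode (0 = identical species distributions).
#' @param shift_features descriptors carrying the separation in
#'   `"features"` mode.
#' @param species_offsets optional numeric vector of length `n_species`
#'   fixing each species' mean offset on the shifted descriptors, in units
#'   of the within-species SD (instead of random offsets); use this to plant
#'   a known similarity structure, e.g. `c(0, 0.15, 3, 3.15, 6)` for two
#'   close pairs plus one outlier.
#' @param seed integer master seed; everything downstream is derived from it.
#' @return List with `surfaces` (list of [gray_surface]) and `labels`, or a
#'   `feature_table`, according to `output`.
#' @export
make_species_dataset <- function(n_species = 5L, n_per_species = 30L,
                                 output = c("surfaces", "features"),
                                 base_weights = NULL, depth = 7L,
                                 noise_sd = 2,
                                 feature_shift = 2,
                                 shift_features = c("h_m3", "alpha_min", "delta_alpha"),
                                 species_offsets = NULL,
                                 seed = 1L) {
  output <- match.arg(output)
  if (n_species < 2L) stop("at least 2 species are required", call. = FALSE)
  species <- sprintf("S%02d", seq_len(n_species))
  if (output == "features")
    return(synthetic_feature_table(species, n_per_species, feature_shift,
                                   shift_features, species_offsets, seed))
  if (is.null(base_weights))
    base_weights <- species_weight_vectors(n_species)
  if (length(base_weights) != n_species)
    stop("need one weight vector per species", call. = FALSE)
  surfaces <- list()
  labels <- character(0)
  idx <- 0L
  for (si in seq_len(n_species)) {
    for (r in seq_len(n_per_species)) {
      idx <- idx + 1L
      s_seed <- derive_seed(seed, idx)
      m <- cascade_surface(base_weights[[si]], depth, shuffle = TRUE,
                           seed = s_seed)
      g <- cascade_to_gray(m, seed = derive_seed(s_seed, 1L))
      g <- g + with_seed(derive_seed(s_seed, 2L),
                         matrix(stats::rnorm(length(g), 0, noise_sd),
                                nrow(g), ncol(g)))
      surfaces[[idx]] <- gray_surface(g,
                                      source_id = sprintf("%s_%03d", species[si], r),
                                      species = species[si])
      labels[idx] <- species[si]
    }
  }
  list(surfaces = surfaces, labels = labels)
}

# Gaussian 12-descriptor table with controllable species separation.
# Baseline means/SDs are plausible values for leaf-like textures.
synthetic_feature_table <- function(species, n_per_species, feature_shift,
                                    shift_features, species_offsets, seed) {
  base_mean <- c(h_m3 = 2.4, h_m2 = 2.3, h_m1 = 2.2, h_p1 = 2.0, h_p2 = 1.9,
                 h_p3 = 1.85, alpha_max = 2.8, alpha_min = 1.5,
                 delta_alpha = 1.3, delta_f = -0.5, D1 = 1.95, D2 = 1.9)
  base_sd <- c(h_m3 = 0.05, h_m2 = 0.045, h_m1 = 0.04, h_p1 = 0.06,
               h_p2 = 0.05, h_p3 = 0.04, alpha_max = 0.07, alpha_min = 0.02,
               delta_alpha = 0.07, delta_f = 0.25, D1 = 0.03, D2 = 0.025)
  bad <- setdiff(shift_features, feature_names())
  if (length(bad))
    stop(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  with_seed(seed, {
    rows <- list()
    # species-level mean offsets (the between-species signal)
    offsets <- matrix(0, length(species), length(base_mean),
                      dimnames = list(species, names(base_mean)))
    for (f in shift_features)
      offsets[, f] <- if (is.null(species_offsets))
        stats::rnorm(length(species), 0, feature_shift * base_sd[[f]])
      else as.numeric(species_offsets) * base_sd[[f]]
    for (si in seq_along(species)) {
      vals <- sapply(names(base_mean), function(f)
        stats::rnorm(n_per_species, base_mean[[f]] + offsets[si, f],
                     base_sd[[f]]))
      df <- data.frame(sample_id = sprintf("%s_%03d", species[si],
                                           seq_len(n_per_species)),
                       species = species[si], stringsAsFactors = FALSE)
      rows[[si]] <- cbind(df, as.data.frame(vals))
    }
    feature_table(do.call(rbind, rows))
  })
}
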