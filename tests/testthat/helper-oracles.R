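# Independent brute-force oracles used across the test files. These are
# deliberately literal transcriptions of the defining formulas, kept free of
# any code shared with the package internals.

# Literal segment-by-segment fluctuation pipeline: double-sum cumulative
# profile, least-squares plane via explicit normal equations, RMS residual,
# then the plain generalized mean over pooled segments.
naive_fluctuation_function <- function(X, s, qs, corners = c("TL", "TR", "BL", "BR")) {
  fl <- numeric(0)
  for (cn in corners) {
    org <- partition_indices(nrow(X), ncol(X), s, cn)
    for (k in seq_len(nrow(org))) {
      seg <- X[org[k, 1] + 1:s, org[k, 2] + 1:s]
      G <- matrix(0, s, s)
      for (i in 1:s) for (j in 1:s) G[i, j] <- sum(seg[1:i, 1:j])
      ij <- expand.grid(i = 1:s, j = 1:s)
      A <- cbind(ij$i, ij$j, 1)
      coef <- solve(t(A) %*% A, t(A) %*% as.vector(G))
      y <- matrix(as.vector(G) - A %*% coef, s, s)
      fl <- c(fl, sqrt(mean(y^2)))
    }
  }
  vapply(qs, function(q) {
    if (abs(q) < 1e-9) exp(mean(log(fl))) else mean(fl^q)^(1 / q)
  }, numeric(1))
}

# Plane fit by generic least squares (QR), for checking the closed form.
naive_plane_fit <- function(G) {
  s <- nrow(G)
  ij <- expand.grid(i = 1:s, j = 1:s)
  fit <- stats::lm.fit(cbind(ij$i, ij$j, 1), as.vector(G))
  list(coefficients = unname(fit$coefficients),
       residuals = matrix(fit$residuals, s, s))
}

# Sample standard deviation written out longhand.
naive_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# Feature table with every descriptor drawn from one normal distribution,
# optionally with per-species mean offsets on selected descriptors.
flat_feature_table <- function(n_species, n_per, seed, offsets = NULL) {
  set.seed(seed)
  species <- sprintf("S%02d", seq_len(n_species))
  rows <- lapply(seq_along(species), function(si) {
    vals <- sapply(feature_names(), function(f) {
      off <- if (!is.null(offsets) && f %in% rownames(offsets))
        offsets[f, si] else 0
      rnorm(n_per, 1 + off, 0.1)
    })
    cbind(data.frame(sample_id = sprintf("%s_%02d", species[si], seq_len(n_per)),
                     species = species[si], stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
  feature_table(do.call(rbind, rows))
}

# Well-separated three-class table in the three named descriptors: class
# centers 10 within-class SDs apart.
separated_feature_table <- function(n_per = 12, seed = 1,
                                    feats = c("h_m3", "alpha_min", "delta_alpha"),
                                    gap = 10) {
  off <- matrix(0, length(feats), 3, dimnames = list(feats, NULL))
  for (i in seq_along(feats)) off[i, ] <- gap * 0.1 * (0:2)
  flat_feature_table(3, n_per, seed, offsets = off)
}
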