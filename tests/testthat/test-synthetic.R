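test_that("cascade generator conserves mass and handles the uniform case", {
  expect_equal(cascade_surface(rep(0.25, 4), 5),
               matrix(4^-5, 32, 32))
  for (sh in c(FALSE, TRUE)) {
    m <- cascade_surface(c(0.4, 0.3, 0.2, 0.1), 6, shuffle = sh, seed = 2)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_equal(dim(m), c(64L, 64L))
    expect_true(min(m) > 0)
  }
  # determinism and seed sensitivity
  m1 <- cascade_surface(c(0.4, 0.3, 0.2, 0.1), 5, shuffle = TRUE, seed = 3)
  expect_identical(m1, cascade_surface(c(0.4, 0.3, 0.2, 0.1), 5,
                                       shuffle = TRUE, seed = 3))
  expect_false(identical(m1, cascade_surface(c(0.4, 0.3, 0.2, 0.1), 5,
                                             shuffle = TRUE, seed = 4)))
  expect_error(cascade_surface(c(0.5, 0.3, 0.1, 0.2), 4), "summing to 1")
})

test_that("analytic cascade exponents match their closed forms", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  an <- cascade_tau_analytic(w, c(-3, 0, 2))
  expect_equal(an$tau[an$q == 0], -2)             # support dimension
  expect_equal(an$tau[an$q == 2], -log2(sum(w^2)))
  expect_equal(an$tau[an$q == 2], 1.737, tolerance = 1e-3)
  eq <- cascade_tau_analytic(rep(0.25, 4), -5:5)
  expect_equal(eq$tau, 2 * (-5:5 - 1), tolerance = 1e-12)
  expect_error(cascade_tau_analytic(c(0.5, 0.5, 0, 0), 0), "q <= 0")
})

test_that("box counting recovers tau exactly for cascades and point masses", {
  # uniform measure: tau(q) = 2(q-1) on dyadic boxes, D_q = 2
  u <- matrix(1, 64, 64)
  bt <- box_counting_tau(u, c(-3, -1, 0.5, 2, 3))
  expect_equal(bt$tau, 2 * (bt$q - 1), tolerance = 1e-10)

  # the partition sums of a cascade are exact at every dyadic scale,
  # shuffled or not, so box counting matches the analytic tau to rounding
  w <- c(0.4, 0.3, 0.2, 0.1)
  m <- cascade_surface(w, 7, shuffle = TRUE, seed = 5)
  bt2 <- box_counting_tau(m, -3:3)
  expect_equal(bt2$tau, cascade_tau_analytic(w, -3:3)$tau, tolerance = 1e-8)

  pm <- matrix(0, 32, 32); pm[5, 9] <- 1
  bt3 <- suppressWarnings(box_counting_tau(pm, c(1, 2, 3)))
  expect_equal(bt3$tau, rep(0, 3), tolerance = 1e-12)
  expect_error(box_counting_tau(matrix(1, 48, 48), 2), "power-of-two")
})

test_that("fBm generator is seeded and its increments scale as s^(2H)", {
  X1 <- fbm_surface(0.5, c(64, 64), seed = 9, oversample = 2)
  expect_identical(X1, fbm_surface(0.5, c(64, 64), seed = 9, oversample = 2))
  expect_false(identical(X1, fbm_surface(0.5, c(64, 64), seed = 10,
                                         oversample = 2)))
  expect_equal(mean(X1), 0, tolerance = 1e-12)
  expect_error(fbm_surface(1.2), "strictly in")

  # generator self-check: variance of the rectangular increments of the
  # implied sheet (cumulative sum) grows as s^(2H)
  for (H in c(0.3, 0.7)) {
    slopes <- vapply(1:3, function(sd_) {
      X <- fbm_surface(H, c(128, 128), seed = sd_, oversample = 4)
      B <- apply(apply(X, 2, cumsum), 1, cumsum)
      ss <- c(4, 8, 16, 32)
      v <- vapply(ss, function(s) {
        i <- seq(1, 128 - s, by = s)
        inc <- B[i + s, i + s] - B[i, i + s] - B[i + s, i] + B[i, i]
        mean(inc^2)
      }, numeric(1))
      unname(coef(lm(log(v) ~ log(ss)))[2]) / 2
    }, numeric(1))
    expect_lt(abs(mean(slopes) - H), 0.1)
  }
})

test_that("gray mapping keeps cascades positive, dithered, and seeded", {
  m <- cascade_surface(c(0.4, 0.3, 0.2, 0.1), 6, shuffle = TRUE, seed = 1)
  g <- cascade_to_gray(m, seed = 2)
  expect_true(all(g > 0) && max(g) <= 255 + 1e-6)
  expect_identical(g, cascade_to_gray(m, seed = 2))
  # power compression preserves mass ordering (up to dither on exact ties)
  expect_gt(cor(as.vector(m), as.vector(g), method = "spearman"), 0.99)
  glog <- cascade_to_gray(m, transform = "log", seed = 2)
  expect_equal(max(glog), 255, tolerance = 1e-5)
  expect_error(cascade_to_gray(matrix(0, 4, 4)), "positive")
})

test_that("species dataset generator is deterministic and labelled", {
  ds <- make_species_dataset(2, 2, depth = 6, seed = 77)
  expect_length(ds$surfaces, 4)
  expect_equal(ds$labels, c("S01", "S01", "S02", "S02"))
  expect_identical(unclass(ds$surfaces[[1]]),
                   unclass(make_species_dataset(2, 2, depth = 6,
                                                seed = 77)$surfaces[[1]]))
  expect_equal(dim(ds$surfaces[[1]]), c(64L, 64L))

  tab <- make_species_dataset(3, 5, output = "features", seed = 8)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 15)
  # zero shift makes species indistinguishable: pairwise accuracy near chance
  tab0 <- make_species_dataset(2, 20, output = "features",
                               feature_shift = 0, seed = 6)
  pw <- pairwise_accuracy_matrix(tab0, c("h_m3", "alpha_min", "delta_alpha"),
                                 K = 4, repeats = 2, seed = 3)
  expect_lt(abs(pw["S01", "S02"] - 0.5), 0.2)
})

test_that("uniform cascade yields D_q = 2 through both estimation routes", {
  # box counting on the exact uniform measure
  bt <- box_counting_tau(matrix(1 / 64^2, 64, 64), c(-3, -1, 0.5, 2, 3))
  expect_equal(bt$tau / (bt$q - 1), rep(2, 5), tolerance = 0.05)
  # MF-DFA pipeline on the dithered uniform gray surface
  g <- cascade_to_gray(cascade_surface(rep(0.25, 4), 7), seed = 4)
  res <- suppressWarnings(mfdfa_spectrum(gray_surface(g)))
  dq <- res$dims$Dq[res$dims$q %in% c(-3:-1, 2, 3)]
  expect_equal(dq, rep(2, 5), tolerance = 0.05)
})
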