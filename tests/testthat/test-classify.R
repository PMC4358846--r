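test_that("htrbf kernel satisfies its algebraic identities", {
  sp <- htrbf_spec(sigma = 1.7, a = 0.8, b = 1.3)
  set.seed(2)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(htrbf_kernel(x, x, sp), 1)
  expect_equal(htrbf_kernel(x, y, sp), htrbf_kernel(y, x, sp))
  expect_gt(htrbf_kernel(x, y, sp), 0)
  expect_lte(htrbf_kernel(x, y, sp), 1)
  # a = 1, b = 1 point evaluation
  expect_equal(htrbf_kernel(0, 1, htrbf_spec(sigma = 1, a = 1, b = 1)),
               exp(-1))
  # a = 1, b = 2 reduces exactly to the Gaussian RBF
  spg <- htrbf_spec(sigma = 2.3, a = 1, b = 2)
  expect_equal(htrbf_kernel(x, y, spg), exp(-sum((x - y)^2) / 2.3),
               tolerance = 1e-15)
  expect_error(htrbf_kernel(c(x, 1), y, sp), "same length")
  expect_error(htrbf_kernel(c(NA, x[-1]), y, sp), "finite")
})

test_that("htrbf Gram matrix is symmetric, unit-diagonal, and Gaussian at a=1,b=2", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  sp <- htrbf_spec(sigma = 1.4, a = 1, b = 2)
  G <- htrbf_gram(X, sp)
  expect_equal(G, t(G))
  expect_equal(diag(G), rep(1, 10))
  Ggauss <- exp(-as.matrix(dist(X))^2 / 1.4)
  expect_equal(max(abs(G - unname(Ggauss))), 0, tolerance = 1e-12)
  # heavy-tailed case matches the scalar kernel entrywise
  sph <- htrbf_spec(sigma = 0.9, a = 0.7, b = 1)
  Gh <- htrbf_gram(X, sph)
  expect_equal(Gh[3, 7], htrbf_kernel(X[3, ], X[7, ], sph), tolerance = 1e-14)
})

test_that("cross-validation separates well-separated classes and is seeded", {
  tab <- separated_feature_table(n_per = 12, seed = 5)
  cv <- kfold_cv(tab, c("h_m3", "alpha_min", "delta_alpha"), K = 4,
                 repeats = 2, seed = 11)
  expect_gte(cv$mean_accuracy, 0.99)
  expect_equal(cv$mean_accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  expect_equal(rowSums(cv$confusion), c(S01 = 24, S02 = 24, S03 = 24))
  expect_identical(cv, kfold_cv(tab, c("h_m3", "alpha_min", "delta_alpha"),
                                K = 4, repeats = 2, seed = 11))
  expect_error(kfold_cv(tab, c("h_m3", "nope"), K = 4), "unknown feature")
  expect_error(kfold_cv(tab, "h_m3", K = 13), "at least K")
})

test_that("label permutation drops accuracy to chance", {
  tab <- flat_feature_table(5, 12, seed = 31)   # 5 identical class distributions
  cv <- kfold_cv(tab, c("h_m3", "alpha_min", "delta_alpha"), K = 4,
                 repeats = 3, seed = 2)
  se <- sd(cv$fold_accuracies) / sqrt(length(cv$fold_accuracies))
  expect_lt(abs(cv$mean_accuracy - 0.2), max(3 * se, 0.1))
})

test_that("pairwise accuracy matrix reflects constructed geometry", {
  # classes 1 and 2 overlap; class 3 far away
  off <- matrix(c(0, 0.02, 10) * 0.1, 1, 3,
                dimnames = list("delta_alpha", NULL))
  tab <- flat_feature_table(3, 10, seed = 13, offsets = off)
  pw <- pairwise_accuracy_matrix(tab, "delta_alpha", K = 5, repeats = 2,
                                 seed = 3)
  expect_equal(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(1, 3))
  expect_gte(pw["S01", "S03"], 0.95)
  expect_gte(pw["S02", "S03"], 0.95)
  expect_lt(pw["S01", "S02"], 0.8)     # near-chance for overlapping pair
})

test_that("multiclass experiment reports per-class recall from the confusion", {
  tab <- separated_feature_table(n_per = 10, seed = 8)
  mc <- multiclass_experiment(tab, c("h_m3", "alpha_min", "delta_alpha"),
                              K = 5, repeats = 2, seed = 4)
  expect_equal(unname(mc$per_class_accuracy), rep(1, 3))
  expect_equal(mc$overall_accuracy,
               sum(diag(mc$confusion)) / sum(mc$confusion))
})

test_that("subsampling at full size equals the full experiment", {
  tab <- separated_feature_table(n_per = 10, seed = 16)
  feats <- c("h_m3", "alpha_min", "delta_alpha")
  sub <- subsample_experiment(tab, feats, K = 5, n_values = c(6, 10),
                              repeats = 2, seed = 9)
  full <- kfold_cv(tab, feats, K = 5, repeats = 2, seed = 9)
  expect_equal(sub$mean_accuracy[sub$n == 10], full$mean_accuracy)
  expect_error(subsample_experiment(tab, feats, K = 5, n_values = 11,
                                    repeats = 1, seed = 1), "smallest species")
})

test_that("combination comparison favors informative descriptors", {
  tab <- separated_feature_table(n_per = 10, seed = 23)
  res <- combination_comparison(
    tab, combos = list(signal = c("h_m3", "alpha_min", "delta_alpha"),
                       noise = c("h_p1", "D1", "D2")),
    K_values = c(3, 5), repeats = 2, seed = 6)
  expect_equal(nrow(res), 4L)
  for (K in c(3, 5)) {
    acc <- res$mean_accuracy[res$K == K]
    names(acc) <- res$combo[res$K == K]
    expect_gt(acc[["signal"]], acc[["noise"]])
  }
  # single combo reduces to kfold_cv on the same seed path
  one <- combination_comparison(tab, list(s = c("h_m3")), K_values = 5,
                                repeats = 2, seed = 6)
  expect_equal(one$mean_accuracy,
               kfold_cv(tab, "h_m3", K = 5, repeats = 2, seed = 6)$mean_accuracy)
})

test_that("accuracy clustering merges the most-confusable species first", {
  acc <- matrix(c(1, 0.5, 0.99,
                  0.5, 1, 0.99,
                  0.99, 0.99, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- accuracy_clustering(acc)
  expect_equal(cl$hclust$height[1], 0.5)
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_identical(first, c("A", "B"))
  expect_match(cl$newick, "\\(")
  g <- accuracy_clustering(acc, g = 2)$groups
  expect_equal(g[["A"]], g[["B"]])
  expect_false(g[["A"]] == g[["C"]])
  # 1-accuracy variant reverses the geometry
  cl2 <- accuracy_clustering(acc, transform = "one_minus")
  first2 <- sort(cl2$hclust$labels[-cl2$hclust$merge[1, ]])
  expect_false(identical(first2, c("A", "B")))
  expect_error(accuracy_clustering(acc * 2), "\\[0, 1\\]")
})
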