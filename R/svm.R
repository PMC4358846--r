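#' Stratified K-fold cross-validated SVM identification
#'
#' Trains a soft-margin support vector machine with the heavy-tailed RBF
#' kernel on `100(K-1)/K`% of the samples and tests on the held-out fold,
#' cycling through all `K` folds; the whole procedure is repeated `repeats`
#' times with fresh stratified splits to average out the randomness of the
#' partition. Features are z-scored per fold using training-fold statistics
#' only, and an unset kernel bandwidth is filled per fold by the median
#' pairwise-distance heuristic on the (standardized) training samples, so no
#' information leaks from the test fold. Multi-class problems use
#' one-vs-one voting (the `kernlab` default).
#'
#' @param table a `feature_table`.
#' @param features character vector of descriptor names to use (e.g. the
#'   top-3 by separability).
#' @param K number of folds (`K >= 2`; every species needs at least `K`
#'   samples).
#' @param spec an [htrbf_spec()].
#' @param repeats number of independent repetitions of the K-fold procedure.
#' @param seed integer seed; fixed seeds give bit-identical results.
#' @param fold_seeds optional integer vector of length `repeats` overriding
#'   the per-repeat split seeds (used internally to align experiments).
#' @return Object of class `cv_result`: list with `K`, `fold_accuracies`
#'   (length `K * repeats`), `mean_accuracy` (= trace of the pooled
#'   confusion matrix over its total), `confusion` (species x species counts
#'   pooled over folds and repeats), `seed`.
#' @export
kfold_cv <- function(table, features, K = 10L, spec = htrbf_spec(),
                     repeats = 10L, seed = 1L, fold_seeds = NULL) {
  table <- feature_table(table)
  bad <- setdiff(features, feature_names())
  if (length(bad))
    stop(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  y <- factor(table$species)
  X <- as.matrix(table[, features, drop = FALSE])
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (min(table(y)) < K)
    stop(sprintf("every species needs at least K = %d samples (smallest has %d)",
                 K, min(table(y))), call. = FALSE)
  if (is.null(fold_seeds)) fold_seeds <- derive_seed(seed, seq_len(repeats))
  lev <- levels(y)
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  fold_acc <- numeric(0)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, K, fold_seeds[r])
    for (k in seq_len(K)) {
      te <- which(folds == k)
      tr <- which(folds != k)
      pred <- svm_train_predict(X[tr, , drop = FALSE], y[tr],
                                X[te, , drop = FALSE], spec)
      confusion <- confusion + unclass(table(factor(y[te], lev), factor(pred, lev)))
      fold_acc <- c(fold_acc, mean(pred == y[te]))
    }
  }
  structure(list(K = K, fold_accuracies = fold_acc,
                 mean_accuracy = sum(diag(confusion)) / sum(confusion),
                 confusion = confusion, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d runs: mean accuracy %.4f (fold sd %.4f)\n",
              x$K, length(x$fold_accuracies) / x$K, x$mean_accuracy,
              stats::sd(x$fold_accuracies)))
  invisible(x)
}

# Stratified fold labels: within each class, shuffled indices are dealt to
# folds 1..K round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(y, K, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(K), length.out = length(idx))
    }
  })
  folds
}

# Train an htrbf SVM on (Xtr, ytr) and predict Xte. Standardization and the
# bandwidth heuristic use the training rows only. The Gram matrix route is
# used so kernel evaluation stays vectorized.
svm_train_predict <- function(Xtr, ytr, Xte, spec) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
  Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
  sp <- spec
  if (is.na(sp$sigma))
    sp$sigma <- median_heuristic_sigma(Xtr, a = sp$a, b = sp$b)
  Ktr <- htrbf_gram(Xtr, sp)
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(Ktr), factor(ytr),
                         type = "C-svc", C = sp$cost)
  Kte <- exp(-htrbf_distances(Xte, Xtr, a = sp$a, b = sp$b) / sp$sigma)
  pred <- kernlab::predict(model,
                           kernlab::as.kernelMatrix(Kte[, kernlab::SVindex(model),
                                                        drop = FALSE]))
  factor(as.character(pred), levels = levels(factor(ytr)))
}

#' Pairwise identification accuracy between every two species
#'
#' Runs the K-fold SVM experiment on every binary subproblem and returns the
#' mean accuracies as a symmetric matrix (diagonal fixed at 1). Low pairwise
#' accuracy means the two species' textures are hard to tell apart.
#'
#' @inheritParams kfold_cv
#' @return Symmetric numeric matrix with species names on both dimensions.
#' @export
pairwise_accuracy_matrix <- function(table, features, K = 10L,
                                     spec = htrbf_spec(), repeats = 10L,
                                     seed = 1L) {
  table <- feature_table(table)
  lev <- sort(unique(table$species))
  if (length(lev) < 2L) stop("at least 2 species required", call. = FALSE)
  acc <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  pair_id <- 0L
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in seq((i + 1L), length(lev))) {
      pair_id <- pair_id + 1L
      sub <- table[table$species %in% c(lev[i], lev[j]), ]
      res <- kfold_cv(sub, features, K, spec, repeats,
                      seed = derive_seed(seed, pair_id))
      acc[i, j] <- acc[j, i] <- res$mean_accuracy
    }
  }
  acc
}

#' Multi-species identification experiment
#'
#' K-fold cross-validated identification over all species at once, with
#' per-species recall read off the pooled confusion matrix.
#'
#' @inheritParams kfold_cv
#' @return List with `overall_accuracy`, `per_class_accuracy` (named),
#'   `confusion`, and the underlying `cv` result.
#' @export
multiclass_experiment <- function(table, features, K = 10L,
                                  spec = htrbf_spec(), repeats = 10L,
                                  seed = 1L) {
  cv <- kfold_cv(table, features, K, spec, repeats, seed)
  per_class <- diag(cv$confusion) / rowSums(cv$confusion)
  list(overall_accuracy = cv$mean_accuracy,
       per_class_accuracy = per_class,
       confusion = cv$confusion,
       cv = cv)
}

#' Effect of per-species sample size on identification accuracy
#'
#' For each requested `n`, draws `n` samples per species without
#' replacement, runs the K-fold experiment, and averages over `repeats`
#' independent draws.
#'
#' @inheritParams kfold_cv
#' @param n_values integer vector of per-species sample sizes
#'   (`max(n_values)` at most the smallest species size).
#' @return Data frame with columns `n`, `mean_accuracy`, `sd_accuracy`.
#' @export
subsample_experiment <- function(table, features, K = 10L,
                                 spec = htrbf_spec(), n_values,
                                 repeats = 10L, seed = 1L) {
  table <- feature_table(table)
  sizes <- table(table$species)
  if (max(n_values) > min(sizes))
    stop(sprintf("n must not exceed the smallest species size (%d)", min(sizes)),
         call. = FALSE)
  rows <- lapply(as.integer(n_values), function(n) {
    accs <- vapply(seq_len(repeats), function(r) {
      idx <- subsample_per_class(table$species, n, derive_seed(seed, 5000L + r))
      kfold_cv(table[idx, ], features, K, spec, repeats = 1L,
               fold_seeds = derive_seed(seed, r))$mean_accuracy
    }, numeric(1))
    data.frame(n = n, mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs))
  })
  do.call(rbind, rows)
}

# Indices of n samples per class, sorted so that drawing the full class
# returns the table unchanged.
subsample_per_class <- function(species, n, seed) {
  with_seed(seed, {
    idx <- lapply(split(seq_along(species), species), function(ii)
      sort(ii[sample.int(length(ii), n)]))
  })
  sort(unlist(idx, use.names = FALSE))
}

#' Compare descriptor combinations across K
#'
#' Runs the K-fold experiment for each feature combination and each fold
#' count on identical splits (same seed path), so differences reflect the
#' descriptors, not the partition.
#'
#' @inheritParams kfold_cv
#' @param combos named list of character vectors of descriptor names.
#' @param K_values integer vector of fold counts.
#' @return Data frame with columns `combo`, `K`, `mean_accuracy`.
#' @export
combination_comparison <- function(table, combos, K_values = 10L,
                                   spec = htrbf_spec(), repeats = 10L,
                                   seed = 1L) {
  if (is.null(names(combos)))
    names(combos) <- vapply(combos, paste, character(1), collapse = "+")
  rows <- list()
  for (cn in names(combos)) {
    for (K in as.integer(K_values)) {
      res <- kfold_cv(table, combos[[cn]], K, spec, repeats, seed)
      rows[[length(rows) + 1L]] <-
        data.frame(combo = cn, K = K, mean_accuracy = res$mean_accuracy,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
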