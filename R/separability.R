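#' Variance-ratio separability of each descriptor
#'
#' For each of the 12 descriptors, `sigma_in(i)` is the standard deviation
#' over the samples of species `i`; `sigma_in` is their unweighted mean over
#' species (the intra-species variability), `sigma_bet` is the standard
#' deviation of the per-species mean values (the inter-species variability),
#' and the separability index is their ratio `I0 = sigma_bet / sigma_in`.
#' Descriptors with larger `I0` discriminate species better.
#'
#' @param table a `feature_table` with at least 2 species and at least 2
#'   samples per species.
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`
#'   (n denominator) for both standard deviations.
#' @return Object of class `separability_report`: data frame with one row
#'   per descriptor and columns `feature`, `sigma_bet`, `sigma_in`, `I0`,
#'   ordered as [feature_names()], plus attribute `ranking` (features by
#'   decreasing `I0`).
#' @export
compute_separability <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  table <- feature_table(table)
  sp <- split(seq_len(nrow(table)), table$species)
  if (length(sp) < 2L)
    stop("separability requires at least 2 species", call. = FALSE)
  if (any(lengths(sp) < 2L))
    stop("separability requires at least 2 samples per species", call. = FALSE)
  sdev <- function(x) {
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  rows <- lapply(feature_names(), function(f) {
    v <- table[[f]]
    s_in_i <- vapply(sp, function(idx) sdev(v[idx]), numeric(1))
    means <- vapply(sp, function(idx) mean(v[idx]), numeric(1))
    s_in <- mean(s_in_i)
    s_bet <- sdev(means)
    if (s_in == 0)
      warning(sprintf("feature %s has zero within-species variability; I0 reported as Inf", f),
              call. = FALSE)
    data.frame(feature = f, sigma_bet = s_bet, sigma_in = s_in,
               I0 = if (s_in == 0) Inf else s_bet / s_in,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ranking") <- out$feature[order(-out$I0, match(out$feature, feature_names()))]
  class(out) <- c("separability_report", "data.frame")
  out
}

#' Select the top-k descriptors by separability
#'
#' Features are ranked by decreasing `I0`; ties are broken by the fixed
#' descriptor order of [feature_names()] (h(q) orders first, then the
#' spectrum summaries, then the dimensions).
#'
#' @param report a `separability_report` from [compute_separability()].
#' @param k number of descriptors to select (default 3, the identification
#'   pipeline's working dimension).
#' @return Character vector of `k` descriptor names, best first.
#' @export
select_top_features <- function(report, k = 3L) {
  if (k < 1L || k > nrow(report))
    stop(sprintf("k must be between 1 and %d", nrow(report)), call. = FALSE)
  attr(report, "ranking")[seq_len(k)]
}

#' Write a separability report as delimited text
#'
#' Transposed layout mirroring a summary table: rows `sigma_bet`,
#' `sigma_in`, `I0`; one column per descriptor.
#'
#' @param report a `separability_report`.
#' @param path file path.
#' @export
write_separability <- function(report, path) {
  m <- t(as.matrix(report[, c("sigma_bet", "sigma_in", "I0")]))
  colnames(m) <- report$feature
  utils::write.csv(data.frame(quantity = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
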