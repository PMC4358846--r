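#' Hierarchical clustering of species from pairwise accuracies
#'
#' Uses the pairwise identification accuracy as the inter-species distance:
#' two species whose binary classifier performs poorly are hard to
#' distinguish, sit at a small "distance", and merge early. Agglomerative
#' clustering with average linkage is applied to this distance; set
#' `transform = "one_minus"` to cluster on `1 - accuracy` instead (then
#' similar species are the ones merging late).
#'
#' @param acc_matrix symmetric matrix of pairwise accuracies in `[0, 1]`
#'   (e.g. from [pairwise_accuracy_matrix()]).
#' @param transform `"identity"` (default; accuracy is the distance) or
#'   `"one_minus"`.
#' @param g optional number of flat groups to cut the dendrogram into.
#' @return Object of class `accuracy_clustering`: list with `hclust` (the
#'   merge tree), `newick` (bracketed tree text), and `groups` (named
#'   integer membership when `g` is given).
#' @export
accuracy_clustering <- function(acc_matrix, transform = c("identity", "one_minus"),
                                g = NULL) {
  transform <- match.arg(transform)
  if (!isSymmetric(unname(acc_matrix)))
    stop("accuracy matrix must be symmetric", call. = FALSE)
  if (any(acc_matrix < 0 | acc_matrix > 1))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  d <- if (transform == "one_minus") 1 - acc_matrix else acc_matrix
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  groups <- if (!is.null(g)) stats::cutree(hc, k = g) else NULL
  structure(list(hclust = hc, newick = newick, groups = groups,
                 transform = transform),
            class = "accuracy_clustering")
}

#' @export
print.accuracy_clustering <- function(x, ...) {
  cat(sprintf("<accuracy_clustering> %d species, distance = %s accuracy\n",
              length(x$hclust$labels),
              if (x$transform == "one_minus") "1 -" else "raw"))
  cat(" ", x$newick, "\n")
  if (!is.null(x$groups)) {
    cat("  groups:\n")
    for (gi in sort(unique(x$groups)))
      cat(sprintf("    %d: %s\n", gi,
                  paste(names(x$groups)[x$groups == gi], collapse = ", ")))
  }
  invisible(x)
}
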