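#' Feature tables
#'
#' A `feature_table` is a data frame with columns `sample_id`, `species` and
#' the 12 multifractal descriptors ([feature_names()]), one row per sample.
#'
#' @param df data frame with the required columns.
#' @return A validated `feature_table`.
#' @export
feature_table <- function(df) {
  cols <- c("sample_id", "species", feature_names())
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("feature table is missing columns: %s; expected header %s",
                 paste(missing, collapse = ", "), paste(cols, collapse = ",")),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("feature table must contain at least one sample", call. = FALSE)
  df <- df[, cols]
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  for (f in feature_names()) df[[f]] <- as.numeric(df[[f]])
  bad <- !stats::complete.cases(df[, feature_names()]) |
    !apply(as.matrix(df[, feature_names()]), 1L, function(r) all(is.finite(r)))
  if (any(bad))
    stop(sprintf("non-finite feature value for sample(s): %s",
                 paste(df$sample_id[bad], collapse = ", ")), call. = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Build a feature table from surfaces
#'
#' @param surfaces list of [gray_surface] objects (their `source_id` and
#'   `species` attributes become the table labels).
#' @param ... passed to [extract_features()] (scale/q grids, corners).
#' @return A `feature_table` with one row per surface.
#' @export
extract_feature_table <- function(surfaces, ...) {
  rows <- lapply(surfaces, function(s) {
    fv <- extract_features(s, ...)
    cbind(data.frame(sample_id = attr(s, "source_id"),
                     species = attr(s, "species"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  feature_table(do.call(rbind, rows))
}

#' Write / read a feature table as delimited text
#'
#' Comma-separated with the documented header
#' `sample_id,species,h_m3,...,D2`; the round trip is lossless (values are
#' written with full double precision).
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `read_feature_table()` returns the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  df <- as.data.frame(table)
  for (f in feature_names())
    df[[f]] <- sprintf("%.17g", df[[f]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       species = "character"))
  feature_table(df)
}
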