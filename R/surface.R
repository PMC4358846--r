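#' Grayscale surface objects
#'
#' A `gray_surface` represents an image as a real-valued `M x N` matrix
#' `X(i, j)` whose entries are gray levels (nominally 0--255). It is the
#' canonical input of the multifractal analysis pipeline: row index `i` runs
#' top to bottom over image rows, column index `j` over image columns.
#'
#' Surfaces must be at least 24 x 24 so that the default dyadic-free scale
#' range `6 ... floor(min(M, N) / 4)` is non-empty.
#'
#' @param values numeric matrix of gray levels; all entries must be finite.
#' @param source_id character label identifying the sample.
#' @param species optional character species/class label.
#'
#' @return An object of class `gray_surface`: the value matrix with
#'   attributes `source_id` and `species`.
#' @examples
#' s <- gray_surface(matrix(runif(32 * 32, 0, 255), 32, 32), "demo")
#' dim(s)
#' @export
gray_surface <- function(values, source_id = "surface", species = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("surface values must be numeric", call. = FALSE)
  storage.mode(values) <- "double"
  stopifnot_finite(values, "surface")
  if (nrow(values) < 24L || ncol(values) < 24L)
    stop(sprintf(
      "surface is %d x %d; at least 24 x 24 is required so the scale range 6 ... min(M, N)/4 is non-empty",
      nrow(values), ncol(values)), call. = FALSE)
  structure(values,
            source_id = as.character(source_id),
            species = as.character(species),
            class = c("gray_surface", "matrix", "array"))
}

#' @export
print.gray_surface <- function(x, ...) {
  cat(sprintf("<gray_surface> %s: %d x %d, range [%.3g, %.3g]",
              attr(x, "source_id"), nrow(x), ncol(x), min(x), max(x)))
  sp <- attr(x, "species")
  if (length(sp) && !is.na(sp)) cat(sprintf(", species %s", sp))
  cat("\n")
  invisible(x)
}

#' Load an image or matrix file as a gray surface
#'
#' Reads a PNG or TIFF image (JPEG where the `EBImage` package is available)
#' or a dense numeric CSV matrix. Color images are reduced to gray according
#' to `gray_method`; single-channel inputs are used as-is. Pixel intensities
#' read from image files are rescaled from the decoder's 0--1 convention to
#' 0--255 gray levels.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` or `.csv`
#'   file.
#' @param gray_method `"luma601"` (default) uses the ITU-R BT.601 weights
#'   0.299 R + 0.587 G + 0.114 B; `"mean"` averages the channels. The choice
#'   only matters for color inputs.
#' @param source_id,species labels attached to the result; `source_id`
#'   defaults to the file name.
#' @return A [gray_surface].
#' @export
load_surface <- function(path, gray_method = c("luma601", "mean"),
                         source_id = NULL, species = NA_character_) {
  gray_method <- match.arg(gray_method)
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package; convert to PNG/TIFF or CSV",
             call. = FALSE)
      a <- EBImage::imageData(EBImage::readImage(path)) * 255
      # EBImage stores x (column) as the first dimension; transpose to rows.
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop(sprintf("unsupported file type '.%s' (PNG, TIFF, JPEG, CSV)", ext),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      img <- switch(gray_method,
        luma601 = 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L],
        mean    = (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3)
    } else {
      img <- img[, , 1L]          # gray(+alpha): keep the gray channel
    }
  }
  if (is.null(source_id)) source_id <- basename(path)
  gray_surface(img, source_id = source_id, species = species)
}

#' Write a numeric matrix as a dense CSV readable by [load_surface()]
#'
#' @param values numeric matrix (or `gray_surface`).
#' @param path output file path.
#' @export
write_surface_csv <- function(values, path) {
  m <- unclass(as.matrix(values))
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  utils::write.table(chr, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
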