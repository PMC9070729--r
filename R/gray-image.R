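#' Grayscale section image
#'
#' A `gray_image` is a 2D raster of 8-bit intensities (stored as numeric,
#' range \[0, 255\]) with a physical resolution in mm per pixel. The
#' convention throughout is dark signal on a light background, as produced
#' by DAB immunostaining on brightfield scans.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\]; rows are image
#'   rows, columns image columns.
#' @param resolution_mm_per_px physical pixel size in mm (default 0.000908,
#'   the scanner resolution the pipeline was designed around).
#' @param origin integer pair `(row, col)` (0-based) locating this crop in
#'   its parent image, for traceability; default `c(0, 0)`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, resolution_mm_per_px = 0.000908,
                       origin = c(0L, 0L)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image raster must be non-empty")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie within [0, 255] and contain no NA")
  if (!is.numeric(resolution_mm_per_px) || length(resolution_mm_per_px) != 1L ||
      resolution_mm_per_px <= 0)
    stop("`resolution_mm_per_px` must be a positive scalar")
  structure(
    list(pixels = unname(pixels),
         resolution_mm_per_px = as.numeric(resolution_mm_per_px),
         origin = as.integer(origin)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> %d x %d px, %.6f mm/px, intensities [%.1f, %.1f]\n",
              d[1], d[2], x$resolution_mm_per_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(img) {
  if (!is_gray_image(img)) stop("expected a `gray_image` object")
  invisible(img)
}

#' Read a section image from PNG or TIFF
#'
#' RGB (or RGBA) input is converted to grayscale with the Rec. 601 luma
#' weights (0.299 R + 0.587 G + 0.114 B). Intensities are rescaled from the
#' file's \[0, 1\] range to \[0, 255\].
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param resolution_mm_per_px physical pixel size in mm.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, resolution_mm_per_px = 0.000908) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  px <- rgb_to_gray(arr) * 255
  gray_image(pmin(pmax(px, 0), 255), resolution_mm_per_px)
}

#' Write a section image to PNG or TIFF
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  m <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(m, path),
    tif  = ,
    tiff = tiff::writeTIFF(m, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

# Collapse an image array read by png/tiff to a single grayscale channel.
rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch == 1L) return(arr[, , 1])
  # Rec. 601 luma; alpha channel ignored
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
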