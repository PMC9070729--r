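#' Rolling-ball background subtraction
#'
#' Estimates the smooth light background of a section image as the
#' grayscale closing of the image by a flat disk of the given radius, and
#' removes it under the light-background convention: the output is
#' `img - background + 255`, clipped to \[0, 255\]. Background pixels map
#' to (approximately) 255 while dark blobs keep their depth below the
#' local background.
#'
#' @param img a [gray_image()].
#' @param radius_px disk radius in px (default 50).
#' @return A [gray_image()] of identical shape and resolution.
#' @export
rolling_ball_subtract <- function(img, radius_px = 50L) {
  assert_gray_image(img)
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("`radius_px` must be >= 1")
  if (radius_px >= min(dim(img$pixels)))
    stop("rolling-ball radius (", radius_px,
         ") is as large as the image extent; crop is degenerate")
  bg <- morph_disk(morph_disk(img$pixels, radius_px, TRUE),
                   radius_px, FALSE)  # grayscale closing
  out <- clamp255(img$pixels - bg + 255)
  gray_image(out, img$resolution_mm_per_px, img$origin)
}

#' Mean filter
#'
#' Each pixel is replaced by the mean of its `kernel_px` x `kernel_px`
#' neighborhood; borders are edge-replicated.
#'
#' @param img a [gray_image()].
#' @param kernel_px odd kernel width (default 5).
#' @return A filtered [gray_image()].
#' @export
mean_filter <- function(img, kernel_px = 5L) {
  assert_gray_image(img)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L || kernel_px %% 2L == 0L)
    stop("`kernel_px` must be odd and >= 1")
  k <- matrix(1 / kernel_px^2, kernel_px, kernel_px)
  out <- clamp255(conv2_replicate(img$pixels, k))
  gray_image(out, img$resolution_mm_per_px, img$origin)
}

#' Gaussian filter
#'
#' Convolution with a truncated, renormalized 2D Gaussian kernel; borders
#' are edge-replicated. The renormalization makes constant images exact
#' fixed points.
#'
#' @param img a [gray_image()].
#' @param sigma Gaussian standard deviation in px (default 1.3).
#' @param kernel_px odd kernel width (default 5).
#' @return A filtered [gray_image()].
#' @export
gaussian_filter <- function(img, sigma = 1.3, kernel_px = 5L) {
  assert_gray_image(img)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L || kernel_px %% 2L == 0L)
    stop("`kernel_px` must be odd and >= 1")
  k <- gaussian_kernel(sigma, kernel_px)
  out <- clamp255(conv2_replicate(img$pixels, k))
  gray_image(out, img$resolution_mm_per_px, img$origin)
}

#' Truncated normalized 2D Gaussian kernel
#'
#' @param sigma standard deviation in px.
#' @param kernel_px odd kernel width.
#' @return A `kernel_px` x `kernel_px` matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, kernel_px) {
  h <- (kernel_px - 1L) / 2L
  d <- seq.int(-h, h)
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Morphological opening (dark-signal polarity)
#'
#' Suppresses small dark specks while preserving larger dark blobs. Because
#' the signal is dark on a light background, the opening is applied in the
#' inverted (signal-bright) representation, which equals a grayscale
#' closing (dilation then erosion) in the original polarity, with a square
#' `kernel_px` x `kernel_px` structuring element. The operation is
#' idempotent.
#'
#' @param img a [gray_image()].
#' @param kernel_px structuring-element width (default 5).
#' @return A filtered [gray_image()].
#' @export
morphological_open <- function(img, kernel_px = 5L) {
  assert_gray_image(img)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L) stop("`kernel_px` must be >= 1")
  out <- if (kernel_px %% 2L == 1L) {
    morph_square(morph_square(img$pixels, kernel_px, TRUE),
                 kernel_px, FALSE)
  } else {
    se <- matrix(TRUE, kernel_px, kernel_px)
    morph_op(morph_op(img$pixels, se, TRUE), se, FALSE)
  }
  gray_image(clamp255(out), img$resolution_mm_per_px, img$origin)
}
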