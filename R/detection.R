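#' Candidate signal
#'
#' One connected dark component extracted from a filtered section image.
#' Centroids are the unweighted means of the mask coordinates, reported
#' 0-based in (row, col) order to match the package's file formats.
#'
#' @param mask integer matrix with columns `row`, `col` (1-based R indices
#'   into the image raster).
#' @param min_intensity minimum intensity over the mask on the designated
#'   intensity image.
#' @return An object of class `candidate_signal` with fields `mask`,
#'   `area_px`, `min_intensity` and `centroid` (0-based `(row, col)`).
#' @export
candidate_signal <- function(mask, min_intensity) {
  if (!is.matrix(mask) || ncol(mask) != 2L || nrow(mask) < 1L)
    stop("`mask` must be a non-empty 2-column (row, col) matrix")
  structure(
    list(mask = mask,
         area_px = nrow(mask),
         min_intensity = as.numeric(min_intensity),
         centroid = c(row = mean(mask[, 1]) - 1, col = mean(mask[, 2]) - 1)),
    class = "candidate_signal")
}

#' Extract candidate signals from a filtered image
#'
#' Binarizes the fully filtered image at intensity strictly below
#' `params$candidate_threshold`, labels connected components under the
#' configured connectivity, and measures each component's area, centroid
#' and minimum intensity.
#'
#' @param img the fully filtered [gray_image()] (rolling-ball, mean,
#'   Gaussian, opening applied in that order).
#' @param params a [detection_params()] object.
#' @param intensity_image optional [gray_image()] on which each candidate's
#'   minimum intensity is measured (e.g. the background-subtracted image);
#'   defaults to `img` itself.
#' @return A list of [candidate_signal()] objects (possibly empty).
#' @export
extract_candidates <- function(img, params = detection_params(),
                               intensity_image = NULL) {
  assert_gray_image(img)
  validate_detection_params(params)
  if (is.null(intensity_image)) intensity_image <- img
  assert_gray_image(intensity_image)
  if (!identical(dim(intensity_image$pixels), dim(img$pixels)))
    stop("`intensity_image` must have the same shape as `img`")
  fg <- img$pixels < params$candidate_threshold
  if (!any(fg)) return(list())
  lab <- label_components(fg, params$connectivity)
  idx <- which(lab > 0L)
  ord <- split(idx, lab[idx])
  nr <- nrow(img$pixels)
  lapply(ord, function(ii) {
    mask <- cbind(row = (ii - 1L) %% nr + 1L, col = (ii - 1L) %/% nr + 1L)
    candidate_signal(mask, min(intensity_image$pixels[ii]))
  })
}

#' Classify a candidate as c-Fos signal or not
#'
#' A candidate is a c-Fos signal iff its area lies in the closed interval
#' `[area_min_px, area_max_px]` and its minimum intensity is strictly less
#' than `min_intensity_threshold`.
#'
#' @param candidate a [candidate_signal()].
#' @param params a [detection_params()] object.
#' @return `TRUE` if accepted as a c-Fos signal.
#' @export
classify_signal <- function(candidate, params = detection_params()) {
  if (!inherits(candidate, "candidate_signal"))
    stop("expected a `candidate_signal`")
  candidate$area_px >= params$area_min_px &&
    candidate$area_px <= params$area_max_px &&
    candidate$min_intensity < params$min_intensity_threshold
}

#' Detect c-Fos signals on a cropped section image
#'
#' Runs the full filter chain — rolling-ball background subtraction, mean
#' filter, Gaussian filter, morphological opening, in that order — then
#' extracts connected candidates and classifies each by the area and
#' minimum-intensity gates. Deterministic for fixed input and parameters.
#'
#' @param img a [gray_image()] crop of one region of interest.
#' @param params a [detection_params()] object.
#' @param image_id identifier carried into the result (default `"image"`).
#' @return A `signal_set`: list with `signals` (data frame with columns
#'   `id`, `centroid_row`, `centroid_col` (0-based), `area_px`,
#'   `min_intensity`, `accepted`), `masks` (list of (row, col) index
#'   matrices), `image_id` and `params`.
#' @export
detect_cfos <- function(img, params = detection_params(),
                        image_id = "image") {
  assert_gray_image(img)
  validate_detection_params(params)
  sub <- rolling_ball_subtract(img, params$ball_radius_px)
  flt <- mean_filter(sub, params$mean_kernel_px)
  flt <- gaussian_filter(flt, params$gaussian_sigma, params$gaussian_kernel_px)
  flt <- morphological_open(flt, params$opening_kernel_px)
  intens <- if (params$intensity_source == "subtracted") sub else flt
  cands <- extract_candidates(flt, params, intensity_image = intens)
  signal_set(cands, params, image_id)
}

#' Assemble classified candidates into a signal set
#'
#' @param candidates list of [candidate_signal()] objects.
#' @param params the [detection_params()] used.
#' @param image_id source-image identifier.
#' @return A `signal_set` (see [detect_cfos()]).
#' @export
signal_set <- function(candidates, params = detection_params(),
                       image_id = "image") {
  n <- length(candidates)
  if (n == 0L) {
    df <- data.frame(id = integer(), centroid_row = numeric(),
                     centroid_col = numeric(), area_px = integer(),
                     min_intensity = numeric(), accepted = logical())
  } else {
    df <- data.frame(
      id = seq_len(n),
      centroid_row = vapply(candidates, function(c) c$centroid[["row"]], 0),
      centroid_col = vapply(candidates, function(c) c$centroid[["col"]], 0),
      area_px = vapply(candidates, function(c) c$area_px, 0L),
      min_intensity = vapply(candidates, function(c) c$min_intensity, 0),
      accepted = vapply(candidates, classify_signal, TRUE, params = params))
  }
  rownames(df) <- NULL
  structure(list(signals = df,
                 masks = lapply(candidates, function(c) c$mask),
                 image_id = image_id,
                 params = params),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> '%s': %d candidate(s), %d accepted as c-Fos\n",
              x$image_id, nrow(x$signals), sum(x$signals$accepted)))
  invisible(x)
}

#' Accepted-signal centroids of a signal set
#'
#' @param signals a `signal_set` (from [detect_cfos()]), or a data frame
#'   with columns `centroid_row`, `centroid_col` and optionally `accepted`.
#' @return Two-column matrix `(x, y)` = `(col, row)`, 0-based, one row per
#'   accepted signal.
#' @export
accepted_centroids <- function(signals) {
  df <- if (inherits(signals, "signal_set")) signals$signals else signals
  if (!is.null(df$accepted)) df <- df[df$accepted, , drop = FALSE]
  cbind(x = df$centroid_col, y = df$centroid_row)
}

#' Write / read a signal table as CSV
#'
#' Columns: `id, centroid_row, centroid_col, area_px, min_intensity,
#' accepted`. Coordinates are 0-based pixel indices in (row, col) order;
#' a comment line in the header states the convention.
#'
#' @param signals a `signal_set` or its `signals` data frame.
#' @param path output CSV path.
#' @return `path` invisibly (writer); the signals data frame (reader).
#' @export
write_signals_csv <- function(signals, path) {
  df <- if (inherits(signals, "signal_set")) signals$signals else signals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based pixel indices, row/col order", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("centroid_row", "centroid_col", "area_px", "min_intensity")
  if (!all(need %in% names(df)))
    stop("signal CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(df$accepted)) df$accepted <- TRUE
  df$accepted <- as.logical(df$accepted)
  df
}
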