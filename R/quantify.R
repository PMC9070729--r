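#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Tests each point against a simple polygon with the even-odd (ray
#' crossing) rule; points lying on an edge or vertex count as inside.
#'
#' @param pts two-column `(x, y)` matrix of query points.
#' @param vertices two-column `(x, y)` polygon vertex matrix, or a
#'   [region_outline()].
#' @param eps absolute tolerance for the boundary test.
#' @return Logical vector, one entry per point.
#' @export
point_in_polygon <- function(pts, vertices, eps = 1e-9) {
  if (inherits(vertices, "region_outline")) vertices <- vertices$vertices
  pts <- matrix(as.numeric(pts), ncol = 2)
  v <- as.matrix(vertices)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  on_boundary <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]
    x2 <- v[nxt[i], 1]; y2 <- v[nxt[i], 2]
    # distance to the edge segment (boundary counts as inside)
    dx <- x2 - x1; dy <- y2 - y1; l2 <- dx * dx + dy * dy
    if (l2 == 0) {
      dseg <- sqrt((px - x1)^2 + (py - y1)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
      dseg <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
    }
    on_boundary <- on_boundary | dseg <= eps
    # even-odd rule with a horizontal ray towards +x
    cross <- (y1 > py) != (y2 > py)
    if (any(cross)) {
      k <- which(cross)
      xint <- x1 + (py[k] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[k] < xint
      inside[k] <- xor(inside[k], flip)
    }
  }
  inside | on_boundary
}

#' Count accepted signals inside a region outline
#'
#' Membership is decided by the signal centroid under the even-odd rule,
#' with the polygon boundary counting as inside.
#'
#' @param signals a `signal_set` (see [detect_cfos()]), a signals data
#'   frame, or a two-column `(x, y)` centroid matrix.
#' @param r a [region_outline()] in the section frame.
#' @return Integer count of accepted signals inside `r`.
#' @export
assign_signals <- function(signals, r) {
  stopifnot(inherits(r, "region_outline"))
  if (r$frame != "section")
    stop("`assign_signals()` expects a section-frame outline")
  pts <- if (is.matrix(signals)) signals else accepted_centroids(signals)
  if (nrow(pts) == 0L) return(0L)
  sum(point_in_polygon(pts, r$vertices))
}

#' Per-region c-Fos signal density
#'
#' Counts the accepted signals whose centroid lies in the region outline
#' and divides by the region's physical area: the outline area in px^2
#' (shoelace formula) times the squared resolution gives mm^2, and
#' density = count / area in signals/mm^2.
#'
#' @param signals as in [assign_signals()].
#' @param r a [region_outline()] in the section frame.
#' @param resolution_mm_per_px physical pixel size (default 0.000908).
#' @return One-row data frame with columns `region, count, area_px2,
#'   area_mm2, density_per_mm2`.
#' @export
quantify_region <- function(signals, r, resolution_mm_per_px = 0.000908) {
  stopifnot(inherits(r, "region_outline"))
  if (!is.numeric(resolution_mm_per_px) || resolution_mm_per_px <= 0)
    stop("`resolution_mm_per_px` must be positive")
  area_px2 <- polygon_area(r$vertices)
  if (area_px2 <= 0) stop("region '", r$name, "' has zero area")
  count <- assign_signals(signals, r)
  area_mm2 <- area_px2 * resolution_mm_per_px^2
  data.frame(region = r$name,
             count = count,
             area_px2 = area_px2,
             area_mm2 = area_mm2,
             density_per_mm2 = count / area_mm2,
             stringsAsFactors = FALSE)
}

#' Quantify several regions at once
#'
#' @param signals as in [assign_signals()].
#' @param outlines list of section-frame [region_outline()] objects.
#' @inheritParams quantify_region
#' @return Data frame with one row per region (see [quantify_region()]).
#' @export
quantify_regions <- function(signals, outlines,
                             resolution_mm_per_px = 0.000908) {
  do.call(rbind, lapply(outlines, quantify_region, signals = signals,
                        resolution_mm_per_px = resolution_mm_per_px))
}
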