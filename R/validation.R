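#' Sensitivity / precision match result
#'
#' Container for the validation metrics comparing the semi-automatic
#' system with manual annotation:
#' sensitivity (%) = 100 TP / (TP + FN), precision (%) = 100 TP / (TP + FP),
#' where TP/FP/FN are counts of matched signals (`mode = "counts"`) or
#' overlap areas (`mode = "area"`).
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative count or
#'   area.
#' @param mode `"counts"` or `"area"`.
#' @return An object of class `match_result`.
#' @export
match_result <- function(tp, fp, fn, mode = c("counts", "area")) {
  mode <- match.arg(mode)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NaN
  if (is.nan(sens) || is.nan(prec))
    warning("metrics undefined: no ", mode, " to match")
  structure(list(true_positive = tp, false_positive = fp,
                 false_negative = fn,
                 sensitivity_pct = sens, precision_pct = prec,
                 mode = mode),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> (%s) TP=%g FP=%g FN=%g | sensitivity %.1f%%, precision %.1f%%\n",
    x$mode, x$true_positive, x$false_positive, x$false_negative,
    x$sensitivity_pct, x$precision_pct))
  invisible(x)
}

#' Count-level validation against manual clicks
#'
#' Matches automatically detected signal centroids to manually clicked
#' positions by one-to-one mutual nearest neighbors within `max_dist_px`:
#' a pair matches iff each is the other's nearest neighbor and their
#' distance is at most `max_dist_px`. Matched pairs are TP, unmatched
#' manual clicks FN, unmatched automatic signals FP. Ties are broken by
#' lowest index. `max_dist_px = Inf` emulates a totals-only comparison.
#'
#' @param auto two-column `(x, y)` matrix of detected centroids (or a
#'   `signal_set`).
#' @param manual two-column `(x, y)` matrix of manual click positions.
#' @param max_dist_px maximum matching distance in px (default 10,
#'   roughly a blob radius at the upper area gate).
#' @return A [match_result()] with `mode = "counts"`.
#' @export
match_counts <- function(auto, manual, max_dist_px = 10) {
  if (inherits(auto, "signal_set")) auto <- accepted_centroids(auto)
  auto <- as.matrix(auto); manual <- as.matrix(manual)
  if (!is.numeric(max_dist_px) || max_dist_px <= 0)
    stop("`max_dist_px` must be positive")
  na <- nrow(auto); nm <- nrow(manual)
  if (na == 0L || nm == 0L)
    return(match_result(0, na, nm, mode = "counts"))
  d <- outer(seq_len(na), seq_len(nm), function(i, j)
    sqrt((auto[i, 1] - manual[j, 1])^2 + (auto[i, 2] - manual[j, 2])^2))
  nn_of_auto <- apply(d, 1, which.min)
  nn_of_manual <- apply(d, 2, which.min)
  tp <- 0L
  for (i in seq_len(na)) {
    j <- nn_of_auto[i]
    if (nn_of_manual[j] == i && d[i, j] <= max_dist_px) tp <- tp + 1L
  }
  match_result(tp, na - tp, nm - tp, mode = "counts")
}

#' Area-level validation of a region outline
#'
#' Compares the automatically outlined region with a manually outlined
#' reference: TP is the intersection area, FN the manual-only area, FP the
#' auto-only area. The exact path clips one polygon by the other
#' (Sutherland-Hodgman) and requires the clip polygon to be convex; for
#' two non-convex polygons, `method = "grid"` estimates the overlap on a
#' dense point grid.
#'
#' @param auto,manual [region_outline()] objects in the same frame.
#' @param method `"exact"` (default; at least one polygon must be convex)
#'   or `"grid"`.
#' @param grid_n grid points per axis for `method = "grid"` (default 1000).
#' @return A [match_result()] with `mode = "area"`.
#' @export
match_areas <- function(auto, manual, method = c("exact", "grid"),
                        grid_n = 1000L) {
  stopifnot(inherits(auto, "region_outline"),
            inherits(manual, "region_outline"))
  if (auto$frame != manual$frame)
    stop("outlines must be in the same coordinate frame")
  method <- match.arg(method)
  a_area <- polygon_area(auto$vertices)
  m_area <- polygon_area(manual$vertices)
  inter <- if (method == "exact") {
    polygon_intersection_area(auto$vertices, manual$vertices)
  } else {
    polygon_overlap_grid(auto$vertices, manual$vertices, grid_n)
  }
  match_result(inter, a_area - inter, m_area - inter, mode = "area")
}

#' Intersection area of two simple polygons
#'
#' Sutherland-Hodgman clipping of the subject polygon by each edge of the
#' clip polygon; exact when the clip polygon is convex. If only the first
#' polygon is convex the roles are swapped automatically.
#'
#' @param subject,clip two-column `(x, y)` vertex matrices.
#' @return Intersection area (0 for disjoint polygons).
#' @export
polygon_intersection_area <- function(subject, clip) {
  subject <- as.matrix(subject); clip <- as.matrix(clip)
  if (!is_convex_polygon(clip)) {
    if (is_convex_polygon(subject)) {
      tmp <- subject; subject <- clip; clip <- tmp
    } else {
      stop("exact intersection needs at least one convex polygon; ",
           "use method = \"grid\"")
    }
  }
  out <- clip_by_convex(subject, clip)
  if (is.null(out) || nrow(out) < 3L) return(0)
  polygon_area(out)
}

is_convex_polygon <- function(v, eps = 1e-12) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[i %% n + 1L, ]; c <- v[(i + 1L) %% n + 1L, ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cr) > eps) {
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman: clip `subject` by convex polygon `clip`.
clip_by_convex <- function(subject, clip) {
  if (shoelace_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[e, ]; b <- clip[e %% nc + 1L, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    isect <- function(p, q) {
      # intersection of segment p-q with the infinite line a-b
      d1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      d2 <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
      t <- d1 / (d1 - d2)
      p + t * (q - p)
    }
    n <- nrow(out)
    res <- list()
    for (i in seq_len(n)) {
      p <- out[i, ]; q <- out[i %% n + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin && qin) res[[length(res) + 1L]] <- q
      else if (pin && !qin) res[[length(res) + 1L]] <- isect(p, q)
      else if (!pin && qin) {
        res[[length(res) + 1L]] <- isect(p, q)
        res[[length(res) + 1L]] <- q
      }
    }
    out <- if (length(res)) do.call(rbind, res) else NULL
  }
  out
}

# Grid estimate of intersection area over the union bounding box.
polygon_overlap_grid <- function(a, b, grid_n = 1000L) {
  xr <- range(c(a[, 1], b[, 1])); yr <- range(c(a[, 2], b[, 2]))
  xs <- seq(xr[1], xr[2], length.out = grid_n)
  ys <- seq(yr[1], yr[2], length.out = grid_n)
  pts <- cbind(rep(xs, times = grid_n), rep(ys, each = grid_n))
  hit <- point_in_polygon(pts, a, eps = 0) & point_in_polygon(pts, b, eps = 0)
  cell <- diff(xr) * diff(yr) / grid_n^2
  sum(hit) * cell
}
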