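#' Named brain-region outline
#'
#' A simple (non-self-intersecting) polygon with positive area delimiting
#' one brain region, either in atlas coordinates or in section (image)
#' coordinates. Vertices are `(x, y)` = `(col, row)` pairs, 0-based pixel
#' units in the section frame.
#'
#' @param name region label (e.g. `"PAG"`, `"LHb"`).
#' @param vertices numeric matrix with >= 3 rows and columns `(x, y)`.
#' @param frame `"atlas"` or `"section"`.
#' @return An object of class `region_outline`.
#' @export
region_outline <- function(name, vertices, frame = c("atlas", "section")) {
  frame <- match.arg(frame)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("`vertices` must be a numeric matrix with >= 3 rows and 2 columns")
  colnames(vertices) <- c("x", "y")
  if (abs(shoelace_signed(vertices)) <= 0)
    stop("outline '", name, "' has zero enclosed area")
  if (!is_simple_polygon(vertices))
    stop("outline '", name, "' is self-intersecting")
  structure(list(name = as.character(name), vertices = unname(vertices),
                 frame = frame),
            class = "region_outline")
}

#' @export
print.region_outline <- function(x, ...) {
  cat(sprintf("<region_outline> '%s' (%s frame): %d vertices, area %.2f\n",
              x$name, x$frame, nrow(x$vertices), polygon_area(x$vertices)))
  invisible(x)
}

# Signed shoelace area (positive = counter-clockwise in (x, y)).
shoelace_signed <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Polygon area by the shoelace formula
#'
#' @param vertices two-column `(x, y)` matrix of polygon vertices, or a
#'   [region_outline()].
#' @return Absolute enclosed area, in squared vertex units.
#' @export
polygon_area <- function(vertices) {
  if (inherits(vertices, "region_outline")) vertices <- vertices$vertices
  abs(shoelace_signed(as.matrix(vertices)))
}

# Proper-crossing test for two closed segments p1-p2 and p3-p4, excluding
# shared endpoints; used to verify polygon simplicity.
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  FALSE
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Projective map from atlas to section coordinates
#'
#' @param matrix invertible 3x3 matrix; normalized so the bottom-right
#'   entry is 1.
#' @return An object of class `homography`.
#' @export
homography <- function(matrix) {
  m <- unname(as.matrix(matrix))
  if (!all(dim(m) == c(3L, 3L))) stop("homography matrix must be 3x3")
  if (abs(det(m)) < .Machine$double.eps^0.75)
    stop("homography matrix is singular")
  if (abs(m[3, 3]) < .Machine$double.eps^0.5)
    stop("cannot normalize: bottom-right entry is ~0")
  structure(list(matrix = m / m[3, 3]), class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography>\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Invert a homography
#'
#' @param H a [homography()].
#' @return The inverse [homography()].
#' @export
invert_homography <- function(H) {
  stopifnot(inherits(H, "homography"))
  homography(solve(H$matrix))
}

#' Apply a homography to 2D points
#'
#' @param H a [homography()].
#' @param pts two-column `(x, y)` matrix.
#' @return Transformed two-column matrix after perspective division.
#' @export
apply_homography <- function(H, pts) {
  stopifnot(inherits(H, "homography"))
  pts <- as.matrix(pts)
  ph <- cbind(pts[, 1], pts[, 2], 1) %*% t(H$matrix)
  w <- ph[, 3]
  if (any(abs(w) < .Machine$double.eps^0.5 * max(1, max(abs(ph)))))
    stop("a point maps to infinity (w ~ 0) under this homography")
  cbind(x = ph[, 1] / w, y = ph[, 2] / w)
}

#' Least-squares homography from point correspondences
#'
#' Normalized direct linear transform (DLT): both point sets are centered
#' and isotropically scaled to mean distance sqrt(2) from the origin, the
#' 2n x 9 design matrix is solved by SVD, and the result is denormalized.
#' Exact (to machine precision) when the correspondences are consistent
#' with a projective map.
#'
#' @param src,dst two-column `(x, y)` matrices of >= 4 corresponding
#'   points; no 3 source points may be collinear.
#' @return A [homography()] with `dst ~ H src`.
#' @export
estimate_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("`src` and `dst` must pair up")
  n <- nrow(src)
  if (n < 4L) stop("need >= 4 point correspondences")
  mc <- max_collinear(src)
  if ((n == 4L && mc >= 3L) || mc >= n - 1L)
    stop("degenerate configuration: too many collinear source points")
  Ts <- normalizing_transform(src)
  Td <- normalizing_transform(dst)
  s <- apply_affine3(Ts, src)
  d <- apply_affine3(Td, dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  homography(solve(Td) %*% Hn %*% Ts)
}

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2).
normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  rbind(c(s, 0, -s * ctr[1]),
        c(0, s, -s * ctr[2]),
        c(0, 0, 1))
}

apply_affine3 <- function(Tm, pts) {
  ph <- cbind(pts[, 1], pts[, 2], 1) %*% t(Tm)
  ph[, 1:2, drop = FALSE]
}

# largest number of mutually collinear points (exact test, small n)
max_collinear <- function(pts, eps = 1e-9) {
  n <- nrow(pts)
  if (n < 3L) return(n)
  best <- 2L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    v <- pts[j, ] - pts[i, ]
    cnt <- 2L
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      w <- pts[k, ] - pts[i, ]
      if (abs(v[1] * w[2] - v[2] * w[1]) <
          eps * max(1, sum(abs(v)) * sum(abs(w))))
        cnt <- cnt + 1L
    }
    best <- max(best, cnt)
  }
  best
}

#' Map a region outline through a homography
#'
#' Each vertex is transformed with perspective division; the frame flips
#' from atlas to section. Simplicity of the transformed polygon is
#' re-checked (a projective map can fold a polygon across the horizon).
#'
#' @param r a [region_outline()] in the atlas frame.
#' @param H a [homography()].
#' @return A [region_outline()] in the section frame.
#' @export
transform_outline <- function(r, H) {
  stopifnot(inherits(r, "region_outline"))
  if (r$frame != "atlas")
    stop("`transform_outline()` expects an atlas-frame outline")
  v <- apply_homography(H, r$vertices)
  region_outline(r$name, v, frame = "section")
}

#' Read / write region outlines as CSV
#'
#' Format: columns `region, vertex_index, x, y` with one row per vertex,
#' vertex order preserved; coordinates are 0-based pixel units,
#' `(x, y)` = `(col, row)`. Read and write round-trip bit-exactly.
#'
#' @param path CSV path.
#' @param frame coordinate frame of the stored outlines.
#' @return A named list of [region_outline()] objects (reader); `path`
#'   invisibly (writer).
#' @export
read_outlines_csv <- function(path, frame = c("atlas", "section")) {
  frame <- match.arg(frame)
  df <- read.csv(path, comment.char = "#")
  need <- c("region", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("outline CSV must contain columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$vertex_index), ]
    region_outline(d$region[1], cbind(d$x, d$y), frame = frame)
  })
  out[unique(df$region)]
}

#' @rdname read_outlines_csv
#' @param outlines a [region_outline()] or list of them.
#' @export
write_outlines_csv <- function(outlines, path) {
  if (inherits(outlines, "region_outline")) outlines <- list(outlines)
  rows <- lapply(outlines, function(r)
    data.frame(region = r$name,
               vertex_index = seq_len(nrow(r$vertices)) - 1L,
               # %.17g keeps the doubles bit-exact across the round trip
               x = sprintf("%.17g", r$vertices[, 1]),
               y = sprintf("%.17g", r$vertices[, 2])))
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based pixel units, x = col, y = row", con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read atlas-to-section point correspondences from CSV
#'
#' Format: columns `src_x, src_y, dst_x, dst_y`, one correspondence per
#' row.
#'
#' @param path CSV path.
#' @return List with `src` and `dst` two-column matrices.
#' @export
read_correspondences_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(df)))
    stop("correspondence CSV must contain columns: ",
         paste(need, collapse = ", "))
  list(src = cbind(x = df$src_x, y = df$src_y),
       dst = cbind(x = df$dst_x, y = df$dst_y))
}
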