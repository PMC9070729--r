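#' Specification of a synthetic section image
#'
#' Describes a light-background micrograph emulating a DAB-stained
#' brightfield crop: a smooth illumination gradient, dark elliptical
#' nuclear blobs of controlled size and depth, and additive speckle
#' noise. Blobs are rendered as hard-edged filled ellipses so their pixel
#' masks are exact ground truth; the detection pipeline's own smoothing
#' softens them.
#'
#' @param shape integer pair `(rows, cols)` (default `c(220, 220)`).
#' @param background background gray level (default 200).
#' @param gradient_amplitude amplitude of a tilted-plane illumination
#'   gradient (default 20; background +/- amplitude must stay in
#'   \[0, 255\]).
#' @param blobs data frame with columns `row, col` (0-based centers),
#'   `r_row, r_col` (ellipse semi-axes in px) and `depth` (gray levels
#'   below the local background); may have zero rows.
#' @param noise_sd SD of additive Gaussian speckle noise (default 3).
#' @param seed integer RNG seed; every generated section is deterministic
#'   per seed.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(shape = c(220L, 220L), background = 200,
                         gradient_amplitude = 20,
                         blobs = data.frame(row = numeric(), col = numeric(),
                                            r_row = numeric(),
                                            r_col = numeric(),
                                            depth = numeric()),
                         noise_sd = 3, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (background - gradient_amplitude < 0 ||
      background + gradient_amplitude > 255)
    stop("background +/- gradient must stay within [0, 255]")
  need <- c("row", "col", "r_row", "r_col", "depth")
  if (!all(need %in% names(blobs)))
    stop("`blobs` must have columns: ", paste(need, collapse = ", "))
  if (nrow(blobs) && (any(blobs$r_row <= 0) || any(blobs$r_col <= 0)))
    stop("blob radii must be positive")
  if (any(blobs$depth < 0)) stop("blob depth must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(shape = as.integer(shape), background = background,
                 gradient_amplitude = gradient_amplitude, blobs = blobs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "section_spec")
}

#' Random non-overlapping blob layout
#'
#' Places `n` elliptical blobs on a jittered grid so that centers are at
#' least `min_sep` apart (guaranteeing separation of several blob
#' diameters for default radii), with semi-axes and depths drawn uniformly
#' from the given ranges. Defaults put blob areas well inside the
#' \[10, 550\] px gate and depths deep enough (>  85 gray levels) that the
#' minimum-intensity cut accepts them.
#'
#' @param n number of blobs.
#' @param shape image shape `(rows, cols)`.
#' @param radius_range semi-axis range in px (default `c(3, 6)`).
#' @param depth_range depth range in gray levels (default `c(110, 150)`).
#' @param min_sep minimum center separation in px (default 36, i.e. >= 3
#'   maximal blob diameters).
#' @param margin margin to the image border in px (default 15).
#' @param seed integer RNG seed.
#' @return Blob data frame suitable for [section_spec()].
#' @export
random_blob_layout <- function(n, shape = c(220L, 220L),
                               radius_range = c(3, 6),
                               depth_range = c(110, 150),
                               min_sep = 36, margin = 15, seed = 1L) {
  grid_r <- seq(margin, shape[1] - 1 - margin, by = min_sep)
  grid_c <- seq(margin, shape[2] - 1 - margin, by = min_sep)
  cells <- expand.grid(row = grid_r, col = grid_c)
  if (nrow(cells) < n)
    stop("image too small for ", n, " blobs at separation ", min_sep)
  withr::with_seed(seed, {
    pick <- sample.int(nrow(cells), n)
    jit <- (min_sep - 2 * max(radius_range)) / 2.5
    data.frame(
      row = cells$row[pick] + runif(n, -jit, jit),
      col = cells$col[pick] + runif(n, -jit, jit),
      r_row = runif(n, radius_range[1], radius_range[2]),
      r_col = runif(n, radius_range[1], radius_range[2]),
      depth = runif(n, depth_range[1], depth_range[2]))
  })
}

#' Render a synthetic section with ground truth
#'
#' Builds the image `background + gradient - depth * blob_mask + noise`
#' (rounded and clipped to \[0, 255\]) and returns it together with the
#' exact per-blob pixel masks and centroids. Overlapping blob masks are
#' permitted but flagged, since they complicate count-level ground truth.
#'
#' @param spec a [section_spec()].
#' @param resolution_mm_per_px carried into the image (default 0.000908).
#' @return List with `image` (a [gray_image()]) and `truth`: a list with
#'   `centroids` (data frame `centroid_row, centroid_col, area_px`,
#'   0-based), `masks` (list of (row, col) index matrices) and
#'   `overlapping` (logical flag).
#' @export
make_section <- function(spec, resolution_mm_per_px = 0.000908) {
  stopifnot(inherits(spec, "section_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  # tilted-plane gradient in a seed-deterministic direction
  img <- withr::with_seed(spec$seed, {
    theta <- runif(1, 0, 2 * pi)
    u <- if (nc > 1) (col(matrix(0, nr, nc)) - 1) / (nc - 1) * 2 - 1 else 0
    v <- if (nr > 1) (row(matrix(0, nr, nc)) - 1) / (nr - 1) * 2 - 1 else 0
    base <- spec$background +
      spec$gradient_amplitude * (cos(theta) * u + sin(theta) * v) / sqrt(2)
    if (spec$noise_sd > 0)
      base <- base + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    base
  })
  masks <- vector("list", nrow(spec$blobs))
  covered <- matrix(0L, nr, nc)
  for (b in seq_len(nrow(spec$blobs))) {
    bl <- spec$blobs[b, ]
    rr <- seq.int(max(0, floor(bl$row - bl$r_row)),
                  min(nr - 1, ceiling(bl$row + bl$r_row)))
    cc <- seq.int(max(0, floor(bl$col - bl$r_col)),
                  min(nc - 1, ceiling(bl$col + bl$r_col)))
    inside <- outer(((rr - bl$row) / bl$r_row)^2,
                    ((cc - bl$col) / bl$r_col)^2, `+`) <= 1
    w <- which(inside, arr.ind = TRUE)
    mask <- cbind(row = rr[w[, 1]] + 1L, col = cc[w[, 2]] + 1L)  # 1-based
    masks[[b]] <- mask
    idx <- mask[, 1] + (mask[, 2] - 1L) * nr
    img[idx] <- img[idx] - bl$depth
    covered[idx] <- covered[idx] + 1L
  }
  img <- round(clamp255(img))
  centroids <- if (length(masks)) {
    data.frame(
      centroid_row = vapply(masks, function(m) mean(m[, 1]) - 1, 0),
      centroid_col = vapply(masks, function(m) mean(m[, 2]) - 1, 0),
      area_px = vapply(masks, nrow, 0L))
  } else {
    data.frame(centroid_row = numeric(), centroid_col = numeric(),
               area_px = integer())
  }
  list(image = gray_image(img, resolution_mm_per_px),
       truth = list(centroids = centroids, masks = masks,
                    overlapping = any(covered > 1L)))
}

#' Random atlas outline, planted homography, and its section image
#'
#' Generates a random simple (convex) polygon in the atlas frame, a
#' well-conditioned random projective map, and the transformed polygon in
#' the section frame — the fixture for registration round-trip tests.
#'
#' @param seed integer RNG seed.
#' @param n_vertices number of polygon vertices (default 6).
#' @param H optional [homography()] to plant; default: a random map close
#'   to a similarity with mild projective distortion.
#' @return List with `atlas` ([region_outline()]), `H` ([homography()])
#'   and `section` ([region_outline()]).
#' @export
make_outline_pair <- function(seed = 1L, n_vertices = 6L, H = NULL) {
  withr::with_seed(seed, {
    # star-shaped (hence simple) polygon: jittered equally spaced angles
    # winding once around the center, jitter < the angular spacing
    step <- 2 * pi / n_vertices
    ang <- (seq_len(n_vertices) - 1) * step + runif(n_vertices, 0, 0.8 * step)
    rad <- runif(n_vertices, 60, 100)
    v <- cbind(x = 150 + rad * cos(ang), y = 150 + rad * sin(ang))
    if (is.null(H)) {
      A <- diag(c(runif(1, 0.8, 1.25), runif(1, 0.8, 1.25)))
      rot <- runif(1, -0.3, 0.3)
      R <- rbind(c(cos(rot), -sin(rot)), c(sin(rot), cos(rot)))
      M <- rbind(cbind(R %*% A, c(runif(1, -30, 30), runif(1, -30, 30))),
                 c(runif(2, -1e-4, 1e-4), 1))
      H <- homography(M)
    }
    atlas <- region_outline("synthetic", v, frame = "atlas")
    list(atlas = atlas, H = H, section = transform_outline(atlas, H))
  })
}

#' Specification of a synthetic density table
#'
#' Multivariate-normal c-Fos densities per experimental group with a
#' target inter-region correlation structure, truncated at 0 (densities
#' are non-negative; with the default means/SDs the truncation is
#' essentially never active).
#'
#' @param n_per_group named integer vector: subjects per group; names are
#'   the group (subpopulation) labels.
#' @param regions character vector of region names.
#' @param group_means groups x regions matrix of mean densities
#'   (signals/mm^2).
#' @param sds per-region SD vector (recycled), default 10.
#' @param correlation regions x regions target correlation matrix
#'   (symmetric positive semidefinite), default identity.
#' @param seed integer RNG seed.
#' @return An object of class `table_spec`.
#' @export
table_spec <- function(n_per_group, regions, group_means, sds = 10,
                       correlation = diag(length(regions)), seed = 1L) {
  if (is.null(names(n_per_group)))
    stop("`n_per_group` must be a named vector of group sizes")
  k <- length(regions)
  group_means <- matrix(group_means, nrow = length(n_per_group), ncol = k)
  sds <- rep_len(sds, k)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))))
    stop("correlation matrix must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semidefinite")
  structure(list(n_per_group = n_per_group, regions = regions,
                 group_means = group_means, sds = sds,
                 correlation = correlation, seed = as.integer(seed)),
            class = "table_spec")
}

#' Draw a synthetic density table
#'
#' @param spec a [table_spec()].
#' @return A [density_table()] with `group` and `subpopulation` both set
#'   to the group label.
#' @export
make_density_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  k <- length(spec$regions)
  Sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
  withr::with_seed(spec$seed, {
    rows <- lapply(seq_along(spec$n_per_group), function(g) {
      n <- spec$n_per_group[g]
      x <- MASS::mvrnorm(n, mu = spec$group_means[g, ], Sigma = Sigma)
      x <- matrix(pmax(x, 0), nrow = n)  # truncate at 0
      colnames(x) <- spec$regions
      data.frame(group = names(spec$n_per_group)[g],
                 subpopulation = names(spec$n_per_group)[g],
                 x, check.names = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- cbind(subject = sprintf("m%02d", seq_len(nrow(df))), df)
    rownames(df) <- NULL
    density_table(df)
  })
}

#' Build a trajectory spending scheduled times in each zone
#'
#' Produces a piecewise-constant path that sits at a representative point
#' of each scheduled zone (`"interaction"`, `"avoidance"` or `"none"`)
#' for exactly the scheduled duration, sampled every `dt` seconds.
#' Occupancy computed by [zone_occupancy()] reproduces the schedule to
#' within one sampling interval per segment (exactly, when segment
#' durations are multiples of `dt`).
#'
#' @param schedule data frame with columns `zone` and `duration`
#'   (seconds); durations must sum to the session length.
#' @param arena an [arena_geometry()].
#' @param duration session length in seconds (default 150).
#' @param dt sampling interval in seconds (default 0.1).
#' @return A [sit_trajectory()].
#' @export
make_trajectory <- function(schedule, arena, duration = 150, dt = 0.1) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (!all(c("zone", "duration") %in% names(schedule)))
    stop("`schedule` needs columns `zone` and `duration`")
  if (!all(schedule$zone %in% c("interaction", "avoidance", "none")))
    stop("zones must be 'interaction', 'avoidance' or 'none'")
  if (any(schedule$duration < 0) ||
      abs(sum(schedule$duration) - duration) > 1e-9)
    stop("schedule durations must be non-negative and sum to `duration`")
  anchors <- zone_anchor_points(arena)
  t <- seq(0, duration - dt / 2, by = dt)
  edges <- cumsum(schedule$duration)
  seg <- findInterval(t, edges) + 1L  # sample at an edge starts the next segment
  zones <- schedule$zone[seg]
  xy <- anchors[zones, , drop = FALSE]
  sit_trajectory(t, xy[, 1], xy[, 2], duration)
}

# Representative interior point of each zone (and of the neutral strip).
zone_anchor_points <- function(arena) {
  along <- function(frac) {
    switch(arena$target_side,
           left   = c(frac * arena$width, arena$height / 2),
           right  = c((1 - frac) * arena$width, arena$height / 2),
           bottom = c(arena$width / 2, frac * arena$height),
           top    = c(arena$width / 2, (1 - frac) * arena$height))
  }
  m <- rbind(interaction = along(1 / 6),
             avoidance = along(7 / 8),
             none = along(0.55))
  colnames(m) <- c("x", "y")
  m
}
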