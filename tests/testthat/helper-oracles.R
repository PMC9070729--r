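# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package:
# explicit neighborhood loops, naive textbook formulas, and a direct
# Lance-Williams agglomeration.

# -- image oracles -------------------------------------------------------

# 2D convolution, replicate border, computed patch-by-patch.
oracle_conv2 <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax(i + (-hr:hr), 1), nr)
      ci <- pmin(pmax(j + (-hc:hc), 1), nc)
      out[i, j] <- sum(m[ri, ci] * kernel)
    }
  }
  out
}

# grayscale erosion/dilation by an explicit structuring element, with the
# neighborhood clipped at the borders
oracle_morph <- function(m, se, dilate) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- (nrow(se) - 1) %/% 2; hc <- (ncol(se) - 1) %/% 2
  off <- which(se, arr.ind = TRUE)
  dr <- off[, 1] - 1 - hr; dc <- off[, 2] - 1 - hc
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- i + dr; ci <- j + dc
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
      vals <- m[cbind(ri[ok], ci[ok])]
      out[i, j] <- if (dilate) max(vals) else min(vals)
    }
  }
  out
}

oracle_disk <- function(r) {
  d <- seq.int(-r, r)
  outer(d^2, d^2, `+`) <= r^2
}

# rolling-ball background subtraction: explicit closing then subtraction
oracle_rolling_ball <- function(m, r) {
  se <- oracle_disk(r)
  bg <- oracle_morph(oracle_morph(m, se, TRUE), se, FALSE)
  pmin(pmax(m - bg + 255, 0), 255)
}

# opening in dark-signal polarity = closing in original polarity
oracle_opening <- function(m, k) {
  se <- matrix(TRUE, k, k)
  oracle_morph(oracle_morph(m, se, TRUE), se, FALSE)
}

# -- geometry oracles ----------------------------------------------------

# scalar even-odd ray casting (ray towards -x, the opposite convention of
# the implementation) with explicit boundary handling
oracle_point_in_polygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) {
    ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[nxt[i], 1]; by <- v[nxt[i], 2]
    l2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (l2 == 0) 0 else
      min(1, max(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / l2))
    qx <- ax + t * (bx - ax); qy <- ay + t * (by - ay)
    if (sqrt((px - qx)^2 + (py - qy)^2) <= eps) return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    ay <- v[i, 2]; by <- v[nxt[i], 2]
    if ((ay > py) != (by > py)) {
      xint <- v[i, 1] + (py - ay) / (by - ay) * (v[nxt[i], 1] - v[i, 1])
      if (px > xint) inside <- !inside   # ray towards -x
    }
  }
  inside
}

# random convex polygon: convex hull of random points
rand_convex_polygon <- function(seed, n = 12, center = c(0, 0), rad = c(3, 8)) {
  withr::with_seed(seed, {
    pts <- cbind(center[1] + runif(n, -rad[2], rad[2]),
                 center[2] + runif(n, -rad[2], rad[2]))
    pts[grDevices::chull(pts), ]
  })
}

# random star-shaped (simple, generally non-convex) polygon: jittered
# equally spaced angles winding once around the center
rand_star_polygon <- function(seed, n = 9, center = c(0, 0), rad = c(2, 9)) {
  withr::with_seed(seed, {
    step <- 2 * pi / n
    ang <- (seq_len(n) - 1) * step + runif(n, 0, 0.8 * step)
    r <- runif(n, rad[1], rad[2])
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  })
}

# -- statistics oracles --------------------------------------------------

# naive-loop Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  unname(sxy / sqrt(sxx * syy))
}

# Lance-Williams agglomeration for Ward's method on squared Euclidean
# distances; ties broken by the lexicographically smallest active pair.
# Returns merges in order: list(height, members) with sorted leaf sets.
oracle_ward <- function(x) {
  n <- nrow(x)
  tot <- 2L * n - 1L
  d <- matrix(NA_real_, tot, tot)
  d[1:n, 1:n] <- as.matrix(dist(x))^2
  sizes <- c(rep(1, n), rep(NA, n - 1L))
  members <- c(lapply(seq_len(n), identity), vector("list", n - 1L))
  active <- seq_len(n)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestd <- Inf
    k <- length(active)
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        i <- active[a]; j <- active[b]
        if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    new <- n + step
    members[[new]] <- sort(c(members[[i]], members[[j]]))
    sizes[new] <- sizes[i] + sizes[j]
    merges[[step]] <- list(height = d[i, j], members = members[[new]])
    rest <- active[!active %in% c(i, j)]
    for (b in rest) {
      d[new, b] <- d[b, new] <-
        ((sizes[i] + sizes[b]) * d[i, b] +
         (sizes[j] + sizes[b]) * d[j, b] -
         sizes[b] * d[i, j]) / (sizes[i] + sizes[j] + sizes[b])
    }
    active <- c(rest, new)
  }
  merges
}

# merge history of an hclust object in the same canonical form
hclust_merge_sets <- function(hc) {
  n <- length(hc$height) + 1L
  members <- vector("list", n - 1L)
  res <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    get <- function(k) if (k < 0) -k else members[[k]]
    m <- sort(c(get(hc$merge[step, 1]), get(hc$merge[step, 2])))
    members[[step]] <- m
    res[[step]] <- list(height = hc$height[step], members = m)
  }
  res
}

# -- misc ----------------------------------------------------------------

rand_image <- function(seed, nr = 24, nc = 24) {
  withr::with_seed(seed, matrix(as.numeric(sample(0:255, nr * nc, TRUE)),
                                nr, nc))
}

truth_centroids_xy <- function(truth)
  cbind(x = truth$centroids$centroid_col, y = truth$centroids$centroid_row)
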