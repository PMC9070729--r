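#' Density table: subjects x regions c-Fos densities
#'
#' The substrate of the downstream statistics is a data frame with the
#' metadata columns `subject`, `group` and `subpopulation` followed by one
#' numeric column per brain region (c-Fos signals/mm^2). Missing entries
#' are permitted (`NA`); non-missing densities must be non-negative, and
#' subject and region labels must be unique.
#'
#' @param df data frame in the layout above.
#' @return The validated data frame, classed `density_table`.
#' @export
density_table <- function(df) {
  meta <- c("subject", "group", "subpopulation")
  if (!all(meta %in% names(df)))
    stop("density table needs columns: ", paste(meta, collapse = ", "))
  regions <- setdiff(names(df), meta)
  if (length(regions) == 0L) stop("density table has no region columns")
  if (anyDuplicated(df$subject)) stop("duplicate subject labels")
  if (anyDuplicated(regions)) stop("duplicate region labels")
  vals <- as.matrix(df[regions])
  if (!is.numeric(vals)) stop("region columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) stop("densities must be non-negative")
  class(df) <- unique(c("density_table", class(df)))
  df
}

#' Region columns of a density table
#'
#' @param t a [density_table()].
#' @return Character vector of region names.
#' @export
table_regions <- function(t)
  setdiff(names(t), c("subject", "group", "subpopulation"))

#' Numeric matrix view of a density table
#'
#' @param t a [density_table()].
#' @return Subjects x regions numeric matrix with subject rownames.
#' @export
density_matrix <- function(t) {
  m <- as.matrix(as.data.frame(t)[table_regions(t)])
  rownames(m) <- t$subject
  m
}

#' Read / write density tables as CSV
#'
#' First columns `subject, group, subpopulation`, then one column per
#' region.
#'
#' @param path CSV path.
#' @return A [density_table()] (reader); `path` invisibly (writer).
#' @export
read_density_table <- function(path) {
  density_table(read.csv(path, check.names = FALSE, comment.char = "#"))
}

#' @rdname read_density_table
#' @param t a [density_table()].
#' @export
write_density_table <- function(t, path) {
  write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' Autoscale a density table
#'
#' Standardizes each region column to mean 0 and sample SD 1 (n - 1
#' denominator), the normalization applied before hierarchical
#' clustering. Scaled values may be negative, so the result is a plain
#' data frame in the same layout.
#'
#' @param t a [density_table()] (or data frame in the same layout).
#' @return Data frame with autoscaled region columns.
#' @export
autoscale <- function(t) {
  regions <- table_regions(t)
  out <- as.data.frame(t)
  for (rg in regions) {
    x <- out[[rg]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop("region '", rg, "' has zero variance; cannot autoscale")
    out[[rg]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  out
}

#' Per-group mean densities
#'
#' Collapses a density table to one row per grouping label, averaging the
#' member rows region-wise (missing-aware). This is the group-averaging
#' step preceding the clustering heatmap.
#'
#' @param t a [density_table()] or autoscaled data frame in that layout.
#' @param by metadata column holding the grouping labels (default
#'   `"subpopulation"`).
#' @return Data frame with columns `group` and one column per region.
#' @export
group_means <- function(t, by = "subpopulation") {
  if (!by %in% names(t)) stop("no such grouping column: ", by)
  g <- t[[by]]
  if (anyNA(g) || any(!nzchar(as.character(g))))
    stop("every subject must carry a non-empty '", by, "' label")
  regions <- table_regions(t)
  agg <- aggregate(as.data.frame(t)[regions], by = list(group = g),
                   FUN = function(x) mean(x, na.rm = TRUE))
  if (any(!is.finite(as.matrix(agg[regions]))))
    stop("a group has no observations for some region")
  agg
}

#' Pairwise Pearson correlation matrices across regions
#'
#' Computes the region x region Pearson correlation matrix over subjects
#' (pairwise-complete observations), together with two-sided p values from
#' the t transform `t = r sqrt((n-2)/(1-r^2))` on n - 2 degrees of
#' freedom, and the pairwise sample sizes. No multiple-testing correction
#' is applied (raw Pearson p values, as in the source analyses).
#'
#' @param t a [density_table()].
#' @param subset optional logical or integer vector selecting subjects
#'   (e.g. `t$group == "defeat"`).
#' @return List of class `correlation_matrices` with elements `r`, `p`,
#'   `n_used` (all regions x regions matrices).
#' @export
correlation_matrices <- function(t, subset = NULL) {
  m <- density_matrix(t)
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  k <- ncol(m)
  regions <- colnames(m)
  r <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  p <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  n_used <- matrix(0L, k, k, dimnames = list(regions, regions))
  zero_var <- character()
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(m[, i], m[, j])
      n <- sum(ok)
      n_used[i, j] <- n_used[j, i] <- n
      if (n < 3L) next
      xi <- m[ok, i]; xj <- m[ok, j]
      if (sd(xi) == 0 || sd(xj) == 0) {
        if (sd(xi) == 0) zero_var <- c(zero_var, regions[i])
        if (sd(xj) == 0) zero_var <- c(zero_var, regions[j])
        next
      }
      rij <- cor(xi, xj)
      r[i, j] <- r[j, i] <- rij
      if (i == j) {
        p[i, j] <- 0
      } else {
        tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.xmin))
        p[i, j] <- p[j, i] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
      }
    }
  }
  diag(p) <- 0
  zero_var <- unique(zero_var)
  if (length(zero_var))
    warning("zero-variance region(s), correlations undefined: ",
            paste(zero_var, collapse = ", "))
  structure(list(r = r, p = p, n_used = n_used),
            class = "correlation_matrices")
}

#' @export
print.correlation_matrices <- function(x, ...) {
  k <- ncol(x$r)
  cat(sprintf("<correlation_matrices> %d regions, n per pair %d-%d\n",
              k, min(x$n_used), max(x$n_used)))
  invisible(x)
}

#' Ward hierarchical clustering of a density table
#'
#' Agglomerative clustering with squared Euclidean distances and Ward's
#' minimum-variance criterion, i.e. `hclust(dist(x)^2, method = "ward.D")`
#' — the classical Ward algorithm whose Lance-Williams update operates on
#' squared distances. Heights are in squared-distance units and are
#' non-decreasing along the merge sequence. Input is expected to be
#' autoscaled (and, for the published procedure, group-averaged)
#' beforehand. Rows with missing entries are dropped with a warning.
#'
#' @param t a [density_table()], a `group_means()` result, or a numeric
#'   matrix.
#' @param axis `"rows"` (cluster subjects/groups) or `"columns"` (cluster
#'   regions).
#' @return An [stats::hclust] object (merge history, heights, leaf order).
#' @export
hierarchical_cluster <- function(t, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- cluster_input_matrix(t)
  if (axis == "columns") m <- t(m)
  drop <- !stats::complete.cases(m)
  if (any(drop)) {
    warning("dropping ", sum(drop), " item(s) with missing entries: ",
            paste(rownames(m)[drop], collapse = ", "))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  hclust(dist(m)^2, method = "ward.D")
}

cluster_input_matrix <- function(t) {
  if (is.matrix(t)) return(t)
  if (!is.null(t$group) && is.null(t$subject)) {
    m <- as.matrix(as.data.frame(t)[setdiff(names(t), "group")])
    rownames(m) <- t$group
    return(m)
  }
  density_matrix(t)
}

#' Two-way hierarchical clustering with reordered heatmap matrix
#'
#' Independent row and column Ward dendrograms plus the input matrix
#' reordered by both leaf orders, ready for heatmap display of the
#' autoscaled densities.
#'
#' @param t as in [hierarchical_cluster()].
#' @return List with `rows`, `columns` (hclust objects) and `matrix`
#'   (reordered).
#' @export
two_way_cluster <- function(t) {
  m <- cluster_input_matrix(t)
  hr <- hierarchical_cluster(m, "rows")
  hc <- hierarchical_cluster(m, "columns")
  list(rows = hr, columns = hc,
       matrix = m[hr$order, hc$order, drop = FALSE])
}

#' Serialize a dendrogram as a Newick string
#'
#' @param hc an [stats::hclust] object.
#' @return Single Newick string with branch lengths derived from merge
#'   heights.
#' @export
hclust_to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labs <- if (is.null(hc$labels)) as.character(seq_len(nrow(hc$merge) + 1L))
          else hc$labels
  node <- function(k) {
    if (k < 0) return(list(str = labs[-k], h = 0))
    a <- node(hc$merge[k, 1]); b <- node(hc$merge[k, 2])
    h <- hc$height[k]
    list(str = sprintf("(%s:%g,%s:%g)", a$str, h - a$h, b$str, h - b$h),
         h = h)
  }
  paste0(node(nrow(hc$merge))$str, ";")
}
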