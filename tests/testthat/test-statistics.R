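rand_table <- function(seed, n = 10, regions = paste0("R", 1:8)) {
  withr::with_seed(seed, {
    vals <- matrix(abs(rnorm(n * length(regions), 100, 20)),
                   n, length(regions), dimnames = list(NULL, regions))
    density_table(data.frame(subject = sprintf("m%02d", 1:n),
                             group = rep(c("control", "defeat"), length.out = n),
                             subpopulation = rep("Non-Av", n),
                             vals, check.names = FALSE))
  })
}

test_that("correlations hit the exact r for linearly dependent regions", {
  t <- rand_table(1)
  t$R2 <- 2 * t$R1
  t$R3 <- pmax(0, 200 - t$R1)  # strictly decreasing map on this draw
  cm <- correlation_matrices(t)
  expect_equal(cm$r["R1", "R2"], 1, tolerance = 1e-12)
  expect_equal(cm$r["R1", "R3"], -1, tolerance = 1e-12)
  expect_equal(diag(cm$r), rep(1, ncol(cm$r)), ignore_attr = TRUE)
})

test_that("r and p match naive-formula and cor.test oracles", {
  t <- rand_table(2)
  cm <- correlation_matrices(t)
  m <- density_matrix(t)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      expect_equal(cm$r[i, j], oracle_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
      ct <- cor.test(m[, i], m[, j])
      expect_equal(cm$p[i, j], ct$p.value, tolerance = 1e-12)
    }
  }
  expect_identical(cm$r, t(cm$r))
  expect_identical(cm$p, t(cm$p))
})

test_that("r is invariant under positive affine rescaling of a column", {
  t <- rand_table(3)
  cm0 <- correlation_matrices(t)
  t$R4 <- 3.7 * t$R4 + 11
  cm1 <- correlation_matrices(t)
  expect_equal(cm1$r, cm0$r, tolerance = 1e-12)
})

test_that("|r| and 1 - p are rank-consistent at fixed n", {
  cm <- correlation_matrices(rand_table(4))
  up <- upper.tri(cm$r)
  expect_equal(order(abs(cm$r[up])), order(1 - cm$p[up]))
})

test_that("zero-variance regions yield missing correlations with a warning", {
  t <- rand_table(5)
  t$R8 <- 50
  expect_warning(cm <- correlation_matrices(t), "zero-variance")
  expect_true(all(is.na(cm$r["R8", setdiff(colnames(cm$r), "R8")])))
})

test_that("autoscaling standardizes each region to mean 0, sample SD 1", {
  t <- rand_table(6)
  z <- autoscale(t)
  for (rg in table_regions(t)) {
    expect_equal(mean(z[[rg]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[rg]]), 1, tolerance = 1e-12)
  }
  expect_equal(as.matrix(autoscale(z)[table_regions(t)]),
               as.matrix(z[table_regions(t)]), tolerance = 1e-12)

  t3 <- t[1:3, ]
  t3$R1 <- c(1, 2, 3)
  expect_equal(autoscale(density_table(t3))$R1, c(-1, 0, 1))

  t$R2 <- 5
  expect_error(autoscale(t), "R2")
})

test_that("group means average member rows and reject empty groups", {
  t <- rand_table(7, n = 6)
  t$subpopulation <- c("a", "a", "b", "b", "b", "c")
  gm <- group_means(t)
  m <- density_matrix(t)
  expect_equal(unlist(gm[gm$group == "a", table_regions(t)]),
               colMeans(m[1:2, ]), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unlist(gm[gm$group == "c", table_regions(t)]),
               m[6, ], tolerance = 1e-12, ignore_attr = TRUE)
  t$subpopulation[6] <- ""
  expect_error(group_means(t), "label")
})

test_that("Ward clustering reproduces the Lance-Williams recurrence", {
  # identical rows merge first at height 0
  x <- withr::with_seed(8, matrix(rnorm(20), 5, 4))
  x[3, ] <- x[1, ]
  hc <- hierarchical_cluster(x, "rows")
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(-hc$merge[1, ], c(1, 3))

  # two tight 2D pairs: within-pair merges first, pairs join last
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  hc2 <- hierarchical_cluster(pts, "rows")
  sets <- hclust_merge_sets(hc2)
  expect_setequal(list(sets[[1]]$members, sets[[2]]$members),
                  list(c(1L, 2L), c(3L, 4L)))
  expect_equal(sets[[3]]$members, 1:4)

  # full merge-history equality on random tables
  for (s in 1:20) {
    y <- withr::with_seed(300 + s, matrix(rnorm(24), 6, 4))
    got <- hclust_merge_sets(hierarchical_cluster(y, "rows"))
    want <- oracle_ward(y)
    for (k in seq_along(want)) {
      expect_equal(got[[k]]$height, want[[k]]$height, tolerance = 1e-8)
      expect_identical(got[[k]]$members, want[[k]]$members)
    }
  }
})

test_that("Ward merge heights are monotone non-decreasing", {
  for (s in 1:5) {
    y <- withr::with_seed(400 + s, matrix(rnorm(40), 8, 5))
    hc <- hierarchical_cluster(y, "rows")
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("rows with missing entries are dropped from clustering with a warning", {
  t <- rand_table(9, n = 5)
  t$R1[2] <- NA
  expect_warning(hc <- hierarchical_cluster(t, "rows"), "missing")
  expect_equal(length(hc$order), 4L)
  expect_error(hierarchical_cluster(density_matrix(t)[1, , drop = FALSE]),
               "at least 2")
})

test_that("two-way clustering reorders the heatmap matrix by both dendrograms", {
  t <- rand_table(10, n = 8)
  gm <- group_means(autoscale(t), by = "group")
  tw <- two_way_cluster(gm)
  expect_identical(rownames(tw$matrix),
                   tw$rows$labels[tw$rows$order])
  expect_identical(colnames(tw$matrix),
                   tw$columns$labels[tw$columns$order])
})

test_that("dendrograms serialize to valid Newick", {
  t <- rand_table(11, n = 6)
  hc <- hierarchical_cluster(density_matrix(t), "rows")
  nwk <- hclust_to_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, t$subject)
})

test_that("density tables validate and round-trip through CSV", {
  t <- rand_table(12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_density_table(t, path)
  back <- read_density_table(path)
  expect_equal(density_matrix(back), density_matrix(t), tolerance = 1e-9)

  bad <- as.data.frame(t); bad$R1[1] <- -5
  expect_error(density_table(bad), "non-negative")
  dup <- as.data.frame(t); dup$subject[2] <- dup$subject[1]
  expect_error(density_table(dup), "duplicate")
})
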