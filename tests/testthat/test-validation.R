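sq10 <- function(ox = 0, oy = 0, side = 10)
  cbind(c(0, side, side, 0) + ox, c(0, 0, side, side) + oy)

test_that("count matching reproduces the sensitivity/precision formulas", {
  pts <- withr::with_seed(1, cbind(runif(20, 0, 100), runif(20, 0, 100)))
  perfect <- match_counts(pts, pts)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$precision_pct, 100)

  # auto = {A, B}, manual = {A, C}; B and C far from everything
  auto <- rbind(c(0, 0), c(100, 0))
  manual <- rbind(c(0, 0), c(0, 100))
  mr <- match_counts(auto, manual, max_dist_px = 10)
  expect_equal(mr$true_positive, 1)
  expect_equal(mr$false_positive, 1)
  expect_equal(mr$false_negative, 1)
  expect_equal(mr$sensitivity_pct, 50)
  expect_equal(mr$precision_pct, 50)
})

test_that("jittered detections plus decoys give the expected 80/80 split", {
  # 50 ground-truth points on a jittered grid (>= 25 px apart), so
  # mutual-nearest-neighbor matching coincides with optimal assignment
  grid <- as.matrix(expand.grid(seq(0, 450, by = 50), seq(0, 450, by = 50)))
  truth <- grid[withr::with_seed(2, sample(nrow(grid), 50)), ] +
    withr::with_seed(2, matrix(runif(100, -5, 5), 50, 2))
  jit <- withr::with_seed(3, matrix(runif(80, -0.7, 0.7), 40, 2))
  decoys <- cbind(seq(600, 690, by = 10), seq(600, 690, by = 10))
  auto <- rbind(truth[1:40, ] + jit, decoys)
  mr <- match_counts(auto, truth, max_dist_px = 10)
  expect_equal(mr$true_positive, 40)
  expect_equal(mr$false_negative, 10)
  expect_equal(mr$false_positive, 10)
  expect_equal(mr$sensitivity_pct, 80)
  expect_equal(mr$precision_pct, 80)
})

test_that("swapping auto and manual swaps sensitivity and precision", {
  a <- withr::with_seed(4, cbind(runif(30, 0, 100), runif(30, 0, 100)))
  b <- withr::with_seed(5, cbind(runif(22, 0, 100), runif(22, 0, 100)))
  ab <- match_counts(a, b, max_dist_px = 15)
  ba <- match_counts(b, a, max_dist_px = 15)
  expect_equal(ab$sensitivity_pct, ba$precision_pct)
  expect_equal(ab$precision_pct, ba$sensitivity_pct)

  ra <- region_outline("a", rand_star_polygon(6, center = c(3, 0)), "section")
  rb <- region_outline("b", rand_convex_polygon(7), "section")
  ab2 <- match_areas(ra, rb)
  ba2 <- match_areas(rb, ra)
  expect_equal(ab2$sensitivity_pct, ba2$precision_pct, tolerance = 1e-9)
  expect_equal(ab2$precision_pct, ba2$sensitivity_pct, tolerance = 1e-9)
})

test_that("count metrics are monotone in the matching distance", {
  a <- withr::with_seed(8, cbind(runif(25, 0, 50), runif(25, 0, 50)))
  b <- withr::with_seed(9, cbind(runif(25, 0, 50), runif(25, 0, 50)))
  prev <- -1
  for (d in c(1, 2, 5, 10, 20, 50, Inf)) {
    mr <- match_counts(a, b, max_dist_px = d)
    expect_gte(mr$true_positive, prev)
    prev <- mr$true_positive
  }
})

test_that("empty inputs yield NaN metrics with a warning", {
  none <- matrix(numeric(), 0, 2)
  expect_warning(mr <- match_counts(none, none), "undefined")
  expect_true(is.nan(mr$sensitivity_pct))
  expect_equal(mr$true_positive, 0)
})

test_that("area overlap reproduces rectangle arithmetic", {
  a <- region_outline("a", sq10(), "section")
  expect_equal(match_areas(a, a)$sensitivity_pct, 100, tolerance = 1e-9)
  expect_equal(match_areas(a, a)$precision_pct, 100, tolerance = 1e-9)

  b <- region_outline("b", sq10(ox = 5), "section")
  mr <- match_areas(a, b)
  expect_equal(mr$true_positive, 50, tolerance = 1e-9)
  expect_equal(mr$sensitivity_pct, 50, tolerance = 1e-9)
  expect_equal(mr$precision_pct, 50, tolerance = 1e-9)

  # auto fully inside a manual square of 4x the area
  inner <- region_outline("in", sq10(ox = 2.5, oy = 2.5, side = 10), "section")
  outer4 <- region_outline("out", sq10(side = 20), "section")
  mr2 <- match_areas(inner, outer4)
  expect_equal(mr2$precision_pct, 100, tolerance = 1e-9)
  expect_equal(mr2$sensitivity_pct, 25, tolerance = 1e-9)

  far <- region_outline("far", sq10(ox = 1000), "section")
  mr3 <- match_areas(a, far)
  expect_equal(mr3$true_positive, 0)
  expect_equal(mr3$sensitivity_pct, 0)
  expect_equal(mr3$precision_pct, 0)
})

test_that("clipped intersection areas agree with fine-grid point sampling", {
  # dual route: Sutherland-Hodgman clipping vs dense point-in-polygon
  # sampling; the two share no geometry code
  for (s in 1:4) {
    a <- rand_convex_polygon(s * 11, center = c(0, 0))
    b <- rand_convex_polygon(s * 13, center = c(2, 1))
    exact <- polygon_intersection_area(a, b)
    sampled <- fosquant:::polygon_overlap_grid(a, b, 2000L)
    expect_lt(abs(exact - sampled), 0.005 * max(exact, 1))
  }
})

test_that("the grid method approximates the exact intersection", {
  a <- rand_star_polygon(31, center = c(0, 0))
  b <- rand_convex_polygon(32, center = c(1, 1))
  exact <- match_areas(region_outline("a", a, "section"),
                       region_outline("b", b, "section"))
  grid <- match_areas(region_outline("a", a, "section"),
                      region_outline("b", b, "section"),
                      method = "grid", grid_n = 600)
  expect_equal(grid$true_positive, exact$true_positive, tolerance = 0.01)

  # two non-convex polygons fall back with a clear error on the exact path
  c1 <- rand_star_polygon(33)
  c2 <- rand_star_polygon(34)
  if (!fosquant:::is_convex_polygon(c1) && !fosquant:::is_convex_polygon(c2))
    expect_error(polygon_intersection_area(c1, c2), "convex")
})
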