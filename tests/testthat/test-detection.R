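params_fast <- detection_params(ball_radius_px = 15)

test_that("candidate extraction labels components and measures them", {
  p <- detection_params()
  blank <- gray_image(matrix(255, 20, 20))
  expect_identical(extract_candidates(blank, p), list())

  # three well-separated dark squares
  m <- matrix(255, 40, 40)
  m[3:6, 3:6] <- 100        # 16 px
  m[20:24, 20:24] <- 120    # 25 px
  m[33:35, 5:9] <- 90       # 15 px
  cands <- extract_candidates(gray_image(m), p)
  expect_length(cands, 3)
  expect_setequal(vapply(cands, function(c) c$area_px, 0L), c(16L, 25L, 15L))
  expect_setequal(vapply(cands, function(c) c$min_intensity, 0),
                  c(100, 120, 90))
  # centroid of the first square: rows/cols 3..6 (1-based) -> 0-based 3.5
  c1 <- cands[[which(vapply(cands, function(c) c$area_px, 0L) == 16L)]]
  expect_equal(unname(c1$centroid), c(3.5, 3.5))
})

test_that("connectivity controls diagonal merging", {
  m <- matrix(255, 12, 12)
  m[3:5, 3:5] <- 100
  m[6:8, 6:8] <- 100  # touches the first blob only diagonally
  c8 <- extract_candidates(gray_image(m), detection_params(connectivity = 8))
  c4 <- extract_candidates(gray_image(m), detection_params(connectivity = 4))
  expect_length(c8, 1)
  expect_length(c4, 2)
})

test_that("classification uses inclusive area bounds and strict intensity cut", {
  p <- detection_params()
  mk <- function(area, mi) {
    mask <- cbind(row = rep(1:ceiling(area / 25), each = 25)[1:area],
                  col = rep(1:25, times = ceiling(area / 25))[1:area])
    candidate_signal(mask, mi)
  }
  expect_true(classify_signal(mk(100, 150), p))
  expect_false(classify_signal(mk(9, 50), p))
  expect_false(classify_signal(mk(100, 170), p))
})

test_that("detect_cfos finds planted blobs and rejects distractors", {
  blobs <- random_blob_layout(20, seed = 101)
  sec <- make_section(section_spec(blobs = blobs, seed = 101))
  ss <- detect_cfos(sec$image, params_fast)
  mr <- match_counts(ss, truth_centroids_xy(sec$truth), max_dist_px = 10)
  expect_equal(mr$sensitivity_pct, 100)
  expect_equal(mr$precision_pct, 100)

  # add sub-area specks: accepted count unchanged
  specks <- data.frame(row = c(30, 110, 190, 60, 140),
                       col = c(205, 12, 205, 110, 8),
                       r_row = 1, r_col = 1, depth = 120)
  sec2 <- make_section(section_spec(blobs = rbind(blobs, specks), seed = 101))
  ss2 <- detect_cfos(sec2$image, params_fast)
  expect_equal(sum(ss2$signals$accepted), sum(ss$signals$accepted))

  # blank noisy background: empty signal set
  blank <- make_section(section_spec(blobs = blobs[0, ], seed = 7))
  expect_equal(nrow(detect_cfos(blank$image, params_fast)$signals), 0L)
})

test_that("detection is deterministic and monotone in the gates", {
  sec <- make_section(section_spec(blobs = random_blob_layout(8, seed = 5),
                                   seed = 5))
  a <- detect_cfos(sec$image, params_fast)
  b <- detect_cfos(sec$image, params_fast)
  expect_identical(a$signals, b$signals)

  base <- sum(a$signals$accepted)
  wider <- detection_params(ball_radius_px = 15, area_min_px = 1,
                            area_max_px = 5000)
  higher <- detection_params(ball_radius_px = 15,
                             min_intensity_threshold = 255)
  expect_gte(sum(detect_cfos(sec$image, wider)$signals$accepted), base)
  expect_gte(sum(detect_cfos(sec$image, higher)$signals$accepted), base)
})

test_that("signal tables round-trip through CSV", {
  sec <- make_section(section_spec(blobs = random_blob_layout(5, seed = 2),
                                   seed = 2))
  ss <- detect_cfos(sec$image, params_fast)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signals_csv(ss, path)
  back <- read_signals_csv(path)
  expect_equal(back$centroid_row, ss$signals$centroid_row)
  expect_equal(back$area_px, ss$signals$area_px)
  expect_equal(back$accepted, ss$signals$accepted)
})

test_that("images round-trip through PNG and TIFF", {
  px <- round(rand_image(3, 12, 10))
  img <- gray_image(px)
  for (ext in c(".png", ".tiff")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gray_image(img, path)
    back <- read_gray_image(path)
    expect_equal(back$pixels, px, tolerance = 1e-6)
  }
})

test_that("detection parameter validation catches bad configurations", {
  expect_error(detection_params(area_min_px = 0), "area_min")
  expect_error(detection_params(mean_kernel_px = 4), "odd")
  expect_error(detection_params(connectivity = 6), "connectivity")
  expect_error(detection_params(min_intensity_threshold = 300), "255")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ball_radius_px: 30", "area_max_px: 400"), path)
  p <- read_detection_params(path)
  expect_equal(p$ball_radius_px, 30L)
  expect_equal(p$area_max_px, 400L)
  expect_equal(p$area_min_px, 10L)
})
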