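test_that("segment grids tile the scan with the remainder discarded", {
  # 8192-px lines in 1024-px segments -> 8 per line
  s <- toy_scan(matrix(1L, 4, 8192))
  g <- segment_grid(s, "x", 1024)
  expect_equal(max(g$col), 8)
  expect_equal(nrow(g), 8 * 4)

  # 204800 lines in 6400-line segments -> 32 per column
  m <- acq_meta(3e-6, 1.94e-7, "fast_x_linescan", line_frequency = 1800)
  s2 <- scan_data(matrix(0L, 204800, 4), m)
  g2 <- segment_grid(s2, "y", 6400)
  expect_equal(max(g2$row), 32)
  expect_equal(nrow(g2), 32 * 4)

  # 100 px in segments of 30 -> 3 segments, 10 px discarded
  s3 <- toy_scan(matrix(1L, 2, 100))
  g3 <- segment_grid(s3, "x", 30)
  expect_equal(max(g3$col), 3)
  expect_equal(max(g3$px_end), 90)

  expect_error(segment_grid(s3, "x", 101), class = "segfcs_validation_error")
})

test_that("segment ranges are contiguous, non-overlapping and equal-sized", {
  set.seed(42)
  for (i in 1:20) {
    n_px <- sample(10:200, 1); n_lines <- sample(2:20, 1)
    n_seg <- sample(2:n_px, 1)
    s <- toy_scan(matrix(0L, n_lines, n_px))
    for (axis in c("x", "y")) {
      extent <- if (axis == "x") n_px else n_lines
      if (n_seg > extent) next
      g <- segment_grid(s, axis, n_seg)
      expect_true(all(g$px_end - g$px_start + 1L == n_seg))
      per_group <- split(g, if (axis == "x") g$row else g$col)
      for (gg in per_group) {
        covered <- unlist(Map(seq, gg$px_start, gg$px_end))
        expect_equal(length(covered), length(unique(covered)))
        expect_equal(length(covered), (extent %/% n_seg) * n_seg)
      }
    }
  }
})

test_that("intensity map holds per-segment means with channels summed", {
  s <- toy_scan(matrix(5L, 3, 16))
  mp <- suppressMessages(segment_map(s, "x", 4))
  expect_true(all(mp$raw_mean == 5))

  s2 <- toy_scan(matrix(c(1L, 2L, 3L, 6L), 1, 4))
  mp2 <- suppressMessages(segment_map(s2, "x", 4))
  expect_equal(mp2$raw_mean, 3)

  s3 <- toy_scan(matrix(1L, 2, 8), n_channels = 2L)
  s3$channels[[2]][] <- 2L
  mp3 <- suppressMessages(segment_map(s3, "x", 4))
  expect_true(all(mp3$raw_mean == 3))  # channel-sum convention
})

test_that("per-line normalization corrects slow decay and is idempotent", {
  # row 10, 20, 40, 40 -> 0.25, 0.5, 1, 1
  s <- toy_scan(matrix(rep(c(10L, 20L, 40L, 40L), each = 2), 1, 8))
  mp <- normalize_map(suppressMessages(segment_map(s, "x", 2)))
  expect_equal(mp$norm_mean, c(0.25, 0.5, 1, 1))

  # global exponential decay along lines, flat X profile -> norm == 1
  decay <- matrix(rep(round(1000 * exp(-(0:19) / 8)), 12), 20, 12)
  storage.mode(decay) <- "integer"
  sd2 <- toy_scan(decay)
  mp2 <- normalize_map(suppressMessages(segment_map(sd2, "x", 4)))
  expect_equal(mp2$norm_mean, rep(1, nrow(mp2)), tolerance = 1e-12)

  # all-zero rows stay at zero, flagged; others have max exactly 1
  z <- matrix(c(rep(0L, 8), rep(3L, 8)), 2, 8, byrow = TRUE)
  mp3 <- suppressMessages(normalize_map(suppressMessages(
    segment_map(toy_scan(z), "x", 2))))
  expect_true(all(mp3$norm_mean[mp3$row == 1] == 0))
  expect_true(all(mp3$all_zero[mp3$row == 1]))
  expect_equal(max(mp3$norm_mean[mp3$row == 2]), 1)

  # idempotence
  expect_equal(normalize_map(mp2)$norm_mean, mp2$norm_mean)
})

test_that("threshold selection is disjoint, complete and scale-invariant", {
  s <- toy_scan(matrix(rep(c(10L, 20L, 40L, 40L), each = 2), 1, 8))
  mp <- normalize_map(suppressMessages(segment_map(s, "x", 2)))
  sel <- select_segments(mp, thresholds = c(0.4, 0.8))
  expect_equal(as.character(sel$class), c("low", "mid", "high", "high"))

  # all segments identical -> one class occupied, empties warned
  su <- toy_scan(matrix(7L, 2, 8))
  mpu <- normalize_map(suppressMessages(segment_map(su, "x", 2)))
  expect_warning(selu <- select_segments(mpu, thresholds = c(0.4, 0.8)),
                 "empty")
  expect_true(all(selu$class == "high"))

  # multiplying all counts by a constant leaves classes unchanged
  s10 <- toy_scan(matrix(rep(c(100L, 200L, 400L, 400L), each = 2), 1, 8))
  mp10 <- normalize_map(suppressMessages(segment_map(s10, "x", 2)))
  sel10 <- select_segments(mp10, thresholds = c(0.4, 0.8))
  expect_equal(as.character(sel10$class), as.character(sel$class))

  expect_error(select_segments(mp, thresholds = c(0.8, 0.4)),
               class = "segfcs_validation_error")
  raw_only <- suppressMessages(segment_map(s, "x", 2))
  expect_error(select_segments(raw_only, thresholds = 0.5),
               class = "segfcs_validation_error")
})

test_that("segment duration check applies the 100x correlation-time rule", {
  tau_d <- 0.181^2 / (4 * 106.4)          # ~77 us for GFP in solution
  expect_silent(check_segment_duration(25e-3, tau_d))
  expect_warning(check_segment_duration(25e-3, 1e-3))
  expect_silent(check_segment_duration(3.5, 8e-3))
  expect_error(check_segment_duration(0, 1), class = "segfcs_validation_error")
})
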