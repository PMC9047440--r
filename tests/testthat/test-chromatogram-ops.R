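test_that("moving-average smoothing keeps length, constants and identity width", {
  expect_equal(smooth_trace(c(5, 5, 5, 5), 3), c(5, 5, 5, 5))
  expect_equal(smooth_trace(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  x <- c(2, 7, 1, 9, 4)
  expect_identical(smooth_trace(x, 1), x)
  expect_error(smooth_trace(x, 2), "odd")
  expect_error(smooth_trace(x, 7), "length")
})

test_that("interior windows of the uniform kernel average exactly", {
  x <- c(0, 0, 1, 5, 2, 8, 3, 0, 0)
  s <- smooth_trace(x, 3)
  for (i in 2:8) expect_equal(3 * s[i], x[i - 1] + x[i] + x[i + 1])
  # hence the kernel preserves the sum exactly when the signal's support is
  # interior (every nonzero point is covered by full windows)
  expect_equal(sum(3 * s[2:8]), 3 * sum(x))
})

test_that("candidate search finds ranked strict local maxima", {
  chrom <- tibble::tibble(time = (0:4) / 10, intensity = c(0, 1, 0, 2, 0))
  cand <- find_peak_candidates(chrom, smoothing_width = 1)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$apex_time, c(0.3, 0.1))
  expect_equal(cand$apex_intensity, c(2, 1))

  flat <- tibble::tibble(time = (0:9) / 10, intensity = rep(0, 10))
  expect_equal(nrow(find_peak_candidates(flat, smoothing_width = 1)), 0L)
})

test_that("candidate list is capped at the n tallest maxima", {
  heights <- c(3, 7, 1, 9, 5, 8, 2)
  y <- numeric(29)
  apex_at <- seq(3, 27, by = 4)
  y[apex_at] <- heights
  chrom <- tibble::tibble(time = (seq_along(y) - 1) / 100, intensity = y)
  cand <- find_peak_candidates(chrom, n_candidates = 5, smoothing_width = 1)
  expect_equal(nrow(cand), 5L)
  expect_equal(cand$apex_intensity, sort(heights, decreasing = TRUE)[1:5])
  expect_true(all(diff(cand$apex_intensity) <= 0))
})

test_that("equal-height candidates are ordered by earlier retention time", {
  y <- c(0, 4, 0, 4, 0)
  chrom <- tibble::tibble(time = (0:4) / 10, intensity = y)
  cand <- find_peak_candidates(chrom, smoothing_width = 1)
  expect_equal(cand$apex_time, c(0.1, 0.3))
})

test_that("borders stop at flanking low points of an isolated peak", {
  chrom <- tibble::tibble(time = (0:4) / 10, intensity = c(0, 0, 10, 0, 0))
  b <- detect_peak_borders(chrom, 3L, smoothing_width = 1)
  expect_equal(b$start_time, 0.1)
  expect_equal(b$end_time, 0.3)
  expect_error(detect_peak_borders(chrom, 2L, smoothing_width = 1), "local maximum")
})

test_that("merged Gaussians share a border at the interior valley", {
  t <- seq(0, 2, by = 0.005)
  y <- 100 * exp(-0.5 * ((t - 0.8) / 0.08)^2) + 80 * exp(-0.5 * ((t - 1.2) / 0.08)^2)
  chrom <- tibble::tibble(time = t, intensity = y)
  # numeric oracle: interior minimum between the two apexes
  between <- which(t > 0.8 & t < 1.2)
  valley <- t[between[which.min(y[between])]]
  apex1 <- which.min(abs(t - 0.8))
  b1 <- detect_peak_borders(chrom, apex1, smoothing_width = 1)
  apex2 <- which.min(abs(t - 1.2))
  b2 <- detect_peak_borders(chrom, apex2, smoothing_width = 1)
  expect_equal(b1$end_time, valley, tolerance = 0.01)
  expect_equal(b2$start_time, valley, tolerance = 0.01)
})

test_that("plateau apex with monotone decay stops at the border fraction", {
  y <- c(0.5, 10, 10, 10, 9, 6, 3, 1, 0.7, 0.4, 0.3)
  chrom <- tibble::tibble(time = (seq_along(y) - 1) / 10, intensity = y)
  b <- detect_peak_borders(chrom, 2L, smoothing_width = 1, border_frac = 0.05)
  # first point below 0.05 * 10 = 0.5 on the right is 0.4 at index 10
  expect_equal(b$end_idx, 10L)
  expect_equal(b$start_idx, 1L)  # 0.5 < 10 * 0.05 is false; 0.5 is a boundary point
})

test_that("integration uses a linear baseline between the borders", {
  chrom <- tibble::tibble(time = c(0, 1, 2), intensity = c(0, 100, 0))
  ih <- integrate_peak(chrom, 0, 2)
  expect_equal(ih$area, 100)
  expect_equal(ih$height, 100)
  expect_equal(ih$apex_time, 1)

  const <- tibble::tibble(time = 0:5, intensity = rep(50, 6))
  ih2 <- integrate_peak(const, 1, 4)
  expect_equal(ih2$area, 0)
  expect_equal(ih2$height, 0)

  expect_error(integrate_peak(chrom, -1, 2), "outside")
  expect_error(integrate_peak(chrom, 2, 0), "start_time")
})

test_that("a rectangle pulse integrates to width times height", {
  t <- seq(0, 2, by = 0.01)
  y <- ifelse(t >= 0.75 & t <= 1.25, 10, 0)
  chrom <- tibble::tibble(time = t, intensity = y)
  ih <- integrate_peak(chrom, 0.5, 1.5)
  expect_equal(ih$area, 5, tolerance = 0.01 * 10 / 5)  # one grid step slack
  expect_equal(ih$height, 10)
})

test_that("noise-free Gaussian area matches the closed form within 1%", {
  for (sigma in c(0.03, 0.05, 0.1)) {
    A <- 5000
    chrom <- gaussian_chrom(apex = 5, A = A, sigma = sigma, dt = sigma / 5)
    ih <- integrate_peak(chrom, 5 - 5 * sigma, 5 + 5 * sigma)
    expect_equal(ih$area, A * sigma * sqrt(2 * pi), tolerance = 0.01)
  }
})

test_that("resampling interpolates linearly and extrapolates to zero", {
  chrom <- tibble::tibble(time = 0:5, intensity = 2 * (0:5))
  expect_equal(resample_trace(chrom, 0:5), chrom$intensity)
  expect_equal(resample_trace(chrom, c(0.5, 2.5)), c(1, 5))
  expect_equal(resample_trace(chrom, c(-1, 6)), c(0, 0))
  expect_error(resample_trace(chrom, numeric(0)), "non-empty")
})
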