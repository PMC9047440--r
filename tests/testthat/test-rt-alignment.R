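test_that("reference selection maximises the mean picking score", {
  scores <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    metabolite = rep(c("a", "b"), 3),
    score = c(0.5, 0.5, 0.9, 0.9, 0.7, 0.7))
  expect_equal(select_reference_sample(scores), "s2")
  expect_equal(select_reference_sample(scores[1:2, ]), "s1")
  tie <- tibble::tibble(sample_id = c("s1", "s2"), metabolite = "a",
                        score = c(0.8, 0.8))
  expect_equal(select_reference_sample(tie), "s1")
  # a metabolite missing in one sample counts as score 0
  part <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                         metabolite = c("a", "b", "a"),
                         score = c(0.6, 0.6, 0.9))
  expect_equal(select_reference_sample(part, c("s1", "s2"), c("a", "b")), "s1")
  expect_error(select_reference_sample(tie, character(0)), "Empty batch")
})

test_that("cross-correlation recovers a constructed translation", {
  ref <- list(quantifier = gaussian_chrom(apex = 5, sigma = 0.05, dt = 0.01, span = 1))
  expect_equal(estimate_rt_shift(ref, ref, center = 5, halfwidth = 0.5), 0)

  shifted <- list(quantifier = gaussian_chrom(apex = 5.1, sigma = 0.05, dt = 0.01, span = 1))
  sh <- estimate_rt_shift(shifted, ref, center = 5, halfwidth = 0.5)
  expect_equal(sh, 0.1, tolerance = 0.011)

  # both roles pull the estimate simultaneously
  two_ref <- c(ref, list(qualifier = gaussian_chrom(apex = 5, A = 300, sigma = 0.05,
                                                    dt = 0.01, span = 1)))
  two_s <- list(quantifier = shifted$quantifier,
                qualifier = gaussian_chrom(apex = 5.1, A = 300, sigma = 0.05,
                                           dt = 0.01, span = 1))
  expect_equal(estimate_rt_shift(two_s, two_ref, 5, 0.5), 0.1, tolerance = 0.011)
})

test_that("shifts beyond the search window are clamped to its edge", {
  ref <- list(quantifier = gaussian_chrom(apex = 5, sigma = 0.05, dt = 0.01, span = 1.5))
  far <- list(quantifier = gaussian_chrom(apex = 5.8, sigma = 0.05, dt = 0.01, span = 1.5))
  sh <- estimate_rt_shift(far, ref, center = 5, halfwidth = 0.5)
  # the search cannot leave the window: the estimate saturates at an edge
  expect_lte(abs(sh), 0.5 + 1e-9)
  expect_equal(abs(sh), 0.5, tolerance = 0.011)
})

test_that("flat windows warn and return the search centre", {
  t <- seq(4, 6, by = 0.01)
  flat <- list(quantifier = tibble::tibble(time = t, intensity = rep(0, length(t))))
  expect_warning(sh <- estimate_rt_shift(flat, flat, center = 5, halfwidth = 0.5),
                 "Flat")
  expect_equal(sh, 0)
})

test_that("quadratic drift fit is exact with three points and degrades gracefully", {
  rt <- c(1, 2, 3)
  sh <- 0.01 * rt^2
  co <- fit_quadratic_shift(rt, sh)
  # independent oracle: direct linear solve of the 3x3 Vandermonde system
  oracle <- solve(cbind(rt^2, rt, 1), sh)
  expect_equal(unname(co), unname(oracle), tolerance = 1e-9)
  expect_equal(unname(co), c(0.01, 0, 0), tolerance = 1e-9)

  expect_equal(unname(fit_quadratic_shift(rt, rep(0, 3))), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(fit_quadratic_shift(c(1, 2), c(0.2, 0.4))), c(0, 0, 0.3))
  expect_warning(co0 <- fit_quadratic_shift(numeric(0), numeric(0)), "zero")
  expect_equal(unname(co0), c(0, 0, 0))
})

test_that("quadratic coefficient is recovered from noisy shifts within 3 SE", {
  withr::with_seed(42, {
    rt <- seq(0.5, 9, length.out = 20)
    sh <- 0.01 * rt^2 + rnorm(20, 0, 0.01)
    co <- fit_quadratic_shift(rt, sh)
    fit <- stats::lm(sh ~ I(rt^2) + rt)
    se_a <- summary(fit)$coefficients["I(rt^2)", "Std. Error"]
    expect_lt(abs(co[["a"]] - 0.01), 3 * se_a)
  })
})

test_that("two-pass alignment recovers pure quadratic drift on noise-free data", {
  batch <- noise_free_batch()
  res <- noise_free_result()
  ref <- res$reference_sample
  a_ref <- batch$samples$drift_coef[batch$samples$sample_id == ref]
  true_ref <- batch$truth$true_shift[batch$truth$sample_id == ref]
  names(true_ref) <- batch$truth$metabolite[batch$truth$sample_id == ref]
  sh <- dplyr::left_join(res$shifts, batch$truth, by = c("sample_id", "metabolite"))
  err <- abs(sh$fitted_shift - (sh$true_shift - true_ref[sh$metabolite]))
  # one sampling interval = 0.01 min
  expect_lte(stats::median(err), 0.01)
  expect_lte(max(err), 0.02)
  # the most drifted sample's quadratic coefficient within 10%
  cmp <- dplyr::left_join(res$shift_models, batch$samples, by = "sample_id")
  worst <- cmp[which.max(abs(cmp$drift_coef - a_ref)), ]
  expect_equal(worst$a, worst$drift_coef - a_ref, tolerance = 0.1)
})

test_that("zero-drift batches give an approximately zero drift model", {
  batch <- generate_batch(sim_config(n_samples = 4, n_metabolites = 6, drift_a = 0,
                                     jitter_sd = 0, noise_sd = 0, p_missing = 0,
                                     p_decoy = 0, seed = 5))
  res <- process_batch(batch)
  pred <- with(res$shift_models, a * 25 + b * 5 + c)  # evaluated at rt = 5
  expect_true(all(abs(pred) <= 0.011))
})

test_that("alignment is equivariant under translating non-reference samples", {
  batch <- generate_batch(sim_config(n_samples = 3, n_metabolites = 6, drift_a = 0,
                                     jitter_sd = 0, noise_sd = 0, p_missing = 0,
                                     p_decoy = 0, seed = 8))
  delta <- 0.12
  chroms <- batch$chromatograms
  res0 <- process_batch(batch)
  ref <- res0$reference_sample
  chroms$chromatogram <- purrr::map2(chroms$chromatogram, chroms$sample_id, function(ch, s) {
    if (s != ref) ch$time <- ch$time + delta
    ch
  })
  align <- estimate_shift_models(chroms, batch$metabolites, ref)
  m0 <- res0$shift_models[res0$shift_models$sample_id != ref, ]
  m1 <- align$models[align$models$sample_id != ref, ]
  rts <- range(batch$metabolites$expected_rt)
  for (r in c(rts[1], mean(rts), rts[2])) {
    p0 <- m0$a * r^2 + m0$b * r + m0$c
    p1 <- m1$a * r^2 + m1$b * r + m1$c
    expect_equal(p1, p0 + delta, tolerance = 0.011)
  }
})

test_that("prototype summation is linear and aligns shifted samples", {
  batch <- noise_free_batch()
  res <- noise_free_result()
  met <- batch$metabolites[3, ]
  proto <- res$prototypes[[met$metabolite]]
  expect_s3_class(proto, "mrm_prototype")
  expect_false(is.null(proto$best_peak))
  # six aligned identical-shape peaks: summed apex ~ sum of per-sample apexes
  apexes <- purrr::map_dbl(batch$samples$sample_id, function(s) {
    tr <- mrmpick:::trace_list(batch$chromatograms, s, met$metabolite)
    max(tr$quantifier$intensity)
  })
  expect_equal(max(proto$summed$quantifier), sum(apexes), tolerance = 0.05)
  # aligned prototype peak is not wider than a single-sample peak
  width_proto <- proto$best_peak$end_time - proto$best_peak$start_time
  tr1 <- mrmpick:::trace_list(batch$chromatograms, res$reference_sample, met$metabolite)
  b1 <- find_peak_candidates(tr1$quantifier)[1, ]
  expect_lte(width_proto, (b1$end_time - b1$start_time) + 2 * 0.01)
})

test_that("prototypes of all-zero traces have no best peak", {
  t <- seq(4, 6, by = 0.01)
  chroms <- tibble::tibble(
    sample_id = c("s1", "s2"), metabolite = "m",
    role = "quantifier",
    chromatogram = list(tibble::tibble(time = t, intensity = rep(0, length(t))),
                        tibble::tibble(time = t, intensity = rep(0, length(t)))))
  met <- tibble::tibble(metabolite = "m", expected_rt = 5, expected_ratio = NA_real_)
  shifts <- tibble::tibble(sample_id = c("s1", "s2"), metabolite = "m",
                           expected_rt = 5, raw_shift = 0, fitted_shift = 0)
  proto <- build_prototype(chroms, met, shifts, "s1")
  expect_null(proto$best_peak)
})

test_that("border propagation applies the fitted shift and clips to the trace", {
  proto <- structure(list(metabolite = "m",
                          best_peak = tibble::tibble(start_time = 5.0, end_time = 5.3)),
                     class = "mrm_prototype")
  expect_equal(unname(propagate_borders(proto, 0.1)), c(5.1, 5.4))
  expect_equal(unname(propagate_borders(proto, 0)), c(5.0, 5.3))
  trace <- tibble::tibble(time = seq(4, 5.35, by = 0.01), intensity = 0)
  expect_warning(b <- propagate_borders(proto, 0.1, trace), "clipped")
  expect_equal(unname(b), c(5.1, 5.35))
  expect_null(propagate_borders(structure(list(best_peak = NULL), class = "mrm_prototype"), 0.1))
})

test_that("noise-free areas after border propagation match the generator truth", {
  batch <- noise_free_batch()
  res <- noise_free_result()
  d <- dplyr::left_join(res$peaks, batch$truth, by = c("metabolite", "sample_id"))
  rel <- abs(d$area / d$true_area - 1)
  expect_true(all(is.finite(rel)))
  expect_lte(max(rel), 0.05)
})
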