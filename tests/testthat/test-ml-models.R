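make_candidates <- function() {
  tibble::tibble(
    metabolite = "m", sample_id = "s",
    apex_time = c(2.5, 2.2, 2.65),
    !!!stats::setNames(as.list(rep(0.5, 20)), qs_names()))
}

test_that("picking labels follow the apex-between-borders rule", {
  cand <- make_candidates()
  sol <- tibble::tibble(metabolite = "m", sample_id = "s",
                        area = 1000, start = 2.4, end = 2.7)
  lab <- derive_picking_labels(cand, sol)
  expect_equal(lab$label, c(1L, 0L, 1L))
  # absent peak: every candidate is negative
  sol0 <- sol; sol0$area <- 0
  expect_equal(derive_picking_labels(cand, sol0)$label, c(0L, 0L, 0L))
  # unmatched pair is an error naming the pair
  expect_error(derive_picking_labels(dplyr::mutate(cand, metabolite = "other"), sol),
               "other s")
})

test_that("reporting labels map 2/0 to classes and drop 1s", {
  f <- tibble::tibble(metabolite = "m", sample_id = c("s1", "s2", "s3"),
                      !!!stats::setNames(as.list(rep(0.5, 26)), reporting_feature_names()))
  sol <- tibble::tibble(metabolite = "m", sample_id = c("s1", "s2", "s3"),
                        value = c(2, 1, 0))
  lab <- derive_reporting_labels(f, sol)
  expect_equal(nrow(lab), 2L)
  expect_equal(lab$label, c(1L, 0L))
  expect_error(derive_reporting_labels(f, dplyr::mutate(sol, value = c(3, 1, 0))),
               "Invalid reporting-solution value 3")
  expect_error(derive_reporting_labels(f, dplyr::mutate(sol, value = 1)),
               "No usable training examples")
})

test_that("F1 combines precision and recall as expected", {
  # counts from the published confusion table of the reference tool
  expect_equal(f1_score(887, 1, 70), 0.9615, tolerance = 1e-4)
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 5, 5), 0)
  expect_error(f1_score(0, 0, 0), "undefined")
  expect_error(f1_score(-1, 0, 5), "non-negative")
})

test_that("fallback scoring is the mean of the quality scores", {
  expect_equal(fallback_score(stats::setNames(rep(1, 20), qs_names())), 1)
  expect_equal(fallback_score(stats::setNames(rep(0.5, 20), qs_names())), 0.5)
  expect_equal(fallback_score(stats::setNames(rep(c(1, 0), each = 10), qs_names())), 0.5)
  m <- tibble::tibble(!!!stats::setNames(as.list(rep(0.25, 20)), qs_names()))
  expect_equal(fallback_score(m), 0.25)
})

test_that("the random forest separates constructed blobs and is deterministic", {
  ex <- separable_examples(500, seed = 1)
  m1 <- train_peak_classifier(ex, task = "picking", seed = 1)
  expect_equal(m1$validation_f1, 1.0)
  m2 <- train_peak_classifier(ex, task = "picking", seed = 1)
  expect_identical(m1$validation_f1, m2$validation_f1)
  expect_identical(predict_score(m1, ex[1:20, ]), predict_score(m2, ex[1:20, ]))

  # scores live in [0, 1] and agree with the true class on training examples
  p <- predict_score(m1, ex)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(min(p[ex$label == 1]), 0.9)
  expect_lt(max(p[ex$label == 0]), 0.1)
})

test_that("shuffled labels cannot be learned", {
  ex <- separable_examples(400, seed = 1)
  ex$label <- withr::with_seed(1, sample(ex$label))
  m <- train_peak_classifier(ex, task = "picking", seed = 1)
  expect_lt(m$validation_f1, 0.7)
})

test_that("training rejects degenerate inputs", {
  ex <- separable_examples(100, seed = 2)
  expect_error(train_peak_classifier(ex[ex$label == 1, ], task = "picking"),
               "both classes")
  expect_error(train_peak_classifier(ex[1:10, ], task = "picking"), "at least 20")
  expect_error(train_peak_classifier(dplyr::select(ex, -qs_t_o), task = "picking"),
               "qs_t_o")
})

test_that("feature importances are normalised and rank informative features first", {
  ex <- separable_examples(500, seed = 1)
  m <- train_peak_classifier(ex, task = "picking", seed = 1)
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  top2 <- imp$feature[1:2]
  expect_setequal(top2, c("qs_t_o", "qs_gauss"))
  noise_imp <- imp$importance[!imp$feature %in% top2]
  expect_true(all(noise_imp < min(imp$importance[imp$feature %in% top2])))
})

test_that("model persistence round-trips predictions exactly", {
  ex <- separable_examples(200, seed = 3)
  m <- train_peak_classifier(ex, task = "picking", seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(predict_score(m, ex), predict_score(m2, ex))
  expect_equal(m2$validation_f1, m$validation_f1)
})

test_that("alternative backends train and score within contract", {
  ex <- separable_examples(200, seed = 4)
  for (alg in c("gradient_boosted_trees", "svm", "neural_net")) {
    m <- train_peak_classifier(ex, task = "picking", algorithm = alg, seed = 4)
    expect_gte(m$validation_f1, 0.9)
    p <- predict_score(m, ex[1:10, ])
    expect_true(all(p >= 0 & p <= 1))
  }
  m_svm <- train_peak_classifier(ex, task = "picking", algorithm = "svm", seed = 4)
  expect_error(feature_importance(m_svm), "not defined")
})
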