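#' Select the reference sample for RT alignment
#'
#' The sample with the highest average peak-picking classification score
#' across all metabolites becomes the reference. Metabolites without a scored
#' candidate count as 0; ties go to the earlier sample in batch order.
#'
#' @param scores Tibble with columns `sample_id`, `metabolite`, `score`
#'   (best-candidate picking score).
#' @param sample_ids Character vector fixing batch order (defaults to the
#'   order of first appearance in `scores`).
#' @param metabolites Character vector of all metabolite names (defaults to
#'   those present in `scores`); missing combinations count as score 0.
#' @return The reference `sample_id` (length-1 character).
#' @export
select_reference_sample <- function(scores, sample_ids = unique(scores$sample_id),
                                    metabolites = unique(scores$metabolite)) {
  if (length(sample_ids) == 0L) abort("Empty batch: no samples to choose from.")
  n_met <- max(1L, length(metabolites))
  means <- vapply(sample_ids, function(s) {
    sc <- scores$score[scores$sample_id == s & scores$metabolite %in% metabolites]
    sum(sc, na.rm = TRUE) / n_met
  }, numeric(1))
  sample_ids[which.max(means)]
}

#' Estimate the RT shift of a sample against the reference by cross-correlation
#'
#' Quantifier and qualifier traces are cross-correlated simultaneously: for
#' every candidate lag the Pearson correlations of all roles present in both
#' samples are summed and the lag with the highest total wins. Positive shift
#' means the sample elutes later than the reference. The lag grid is the
#' common sampling interval of the reference trace.
#'
#' @param traces,ref_traces Named lists of chromatograms (roles `quantifier`,
#'   `qualifier`, `istd`) for the sample and the reference.
#' @param center Window centre in minutes on the reference time axis
#'   (typically the expected RT).
#' @param halfwidth Half-width (min) of the lag search range.
#' @param shift_center Centre (min) of the lag search range: 0 in the first
#'   pass, the fitted shift in the refinement pass, so refined shifts are
#'   searched in `shift_center +/- halfwidth`.
#' @param support_halfwidth Half-width (min) of the correlation support
#'   window around `center` (defaults to `halfwidth`).
#' @return Shift in minutes, in `shift_center + [-halfwidth, +halfwidth]`.
#'   Flat windows in both traces give `shift_center` with a warning.
#' @export
estimate_rt_shift <- function(traces, ref_traces, center, halfwidth,
                              shift_center = 0, support_halfwidth = halfwidth) {
  ref_q <- ref_traces$quantifier
  if (is.null(traces$quantifier) || is.null(ref_q)) {
    abort("Both samples must provide the quantifier trace.")
  }
  near <- abs(ref_q$time - center) <= 2 * support_halfwidth
  dt <- if (sum(near) >= 3L) stats::median(diff(ref_q$time[near])) else stats::median(diff(ref_q$time))
  grid <- seq(center - support_halfwidth, center + support_halfwidth, by = dt)
  lags <- shift_center + seq(-floor(halfwidth / dt), floor(halfwidth / dt)) * dt

  roles <- intersect(names(ref_traces), names(traces))
  roles <- roles[!vapply(roles, function(r) is.null(traces[[r]]) || is.null(ref_traces[[r]]), logical(1))]
  ref_w <- lapply(roles, function(r) resample_trace(ref_traces[[r]], grid))
  usable <- vapply(ref_w, stats::sd, numeric(1)) > 0
  any_signal <- FALSE
  score <- vapply(lags, function(lag) {
    tot <- 0
    for (k in seq_along(roles)) {
      if (!usable[k]) next
      sv <- resample_trace(traces[[roles[k]]], grid + lag)
      if (stats::sd(sv) == 0) next
      any_signal <<- TRUE
      tot <- tot + stats::cor(ref_w[[k]], sv)
    }
    tot
  }, numeric(1))
  if (!any_signal || all(score == 0)) {
    warn("Flat correlation window; returning the search centre.")
    return(shift_center)
  }
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  cand <- cand[order(abs(lags[cand] - shift_center), lags[cand])][1L]
  lags[cand]
}

#' Fit per-sample RT drift as a quadratic function of retention time
#'
#' Ordinary least squares of shift on (rt^2, rt, 1). Run-to-run drift in
#' HILIC chromatography is typically quadratic in RT; regularising the raw
#' per-metabolite shifts through this model suppresses implausibly large
#' individual shifts. With fewer than 3 finite points the model degrades to a
#' constant (the median shift); with none it is the zero model.
#'
#' @param expected_rts Numeric vector of metabolite expected RTs (minutes).
#' @param shifts Numeric vector of measured shifts (minutes); `NA`s dropped.
#' @param robust If `TRUE`, one reweighting pass drops points whose residual
#'   exceeds 3x the median absolute deviation of the residuals.
#' @return Named numeric `c(a, b, c)` of `shift(rt) = a rt^2 + b rt + c`.
#' @export
fit_quadratic_shift <- function(expected_rts, shifts, robust = FALSE) {
  ok <- is.finite(expected_rts) & is.finite(shifts)
  rt <- expected_rts[ok]
  sh <- shifts[ok]
  if (length(sh) == 0L) {
    warn("No usable shifts; returning the zero drift model.")
    return(c(a = 0, b = 0, c = 0))
  }
  if (length(sh) < 3L) return(c(a = 0, b = 0, c = stats::median(sh)))
  fit <- stats::lm(sh ~ I(rt^2) + rt)
  if (robust) {
    res <- stats::residuals(fit)
    s <- stats::mad(res)
    keep <- if (s > 0) abs(res) <= 3 * s else rep(TRUE, length(res))
    if (sum(keep) >= 3L && any(!keep)) {
      rt <- rt[keep]; sh <- sh[keep]
      fit <- stats::lm(sh ~ I(rt^2) + rt)
    }
  }
  co <- stats::coef(fit)
  c(a = unname(co[2L]), b = unname(co[3L]), c = unname(co[1L]))
}

predict_shift <- function(coeffs, rt) {
  coeffs[["a"]] * rt^2 + coeffs[["b"]] * rt + coeffs[["c"]]
}

# one alignment pass over the whole batch: raw shift per (sample, metabolite),
# then a quadratic fit per sample. shift_centers: list metabolite -> named
# vector sample -> centre of the lag search (0 in the first pass).
shift_pass <- function(chroms, metabolites, ref_id, shift_centers, halfwidth,
                       support_halfwidth = halfwidth) {
  sample_ids <- unique(chroms$sample_id)
  ref_traces_of <- function(met) trace_list(chroms, ref_id, met)
  met_traces <- lapply(metabolites$metabolite, ref_traces_of)
  names(met_traces) <- metabolites$metabolite

  raw <- list_rbind(map(sample_ids, function(s) {
    shifts <- vapply(seq_len(nrow(metabolites)), function(i) {
      met <- metabolites$metabolite[i]
      tr <- trace_list(chroms, s, met)
      rf <- met_traces[[met]]
      if (is.null(tr$quantifier) || is.null(rf$quantifier)) return(NA_real_)
      if (s == ref_id) return(0)
      suppressWarnings(
        estimate_rt_shift(tr, rf, center = metabolites$expected_rt[i],
                          halfwidth = halfwidth,
                          shift_center = shift_centers[[met]][[s]],
                          support_halfwidth = support_halfwidth)
      )
    }, numeric(1))
    tibble(sample_id = s, metabolite = metabolites$metabolite,
           expected_rt = metabolites$expected_rt, raw_shift = shifts)
  }))

  models <- list_rbind(map(sample_ids, function(s) {
    d <- raw[raw$sample_id == s, ]
    co <- suppressWarnings(fit_quadratic_shift(d$expected_rt, d$raw_shift))
    tibble(sample_id = s, a = co[["a"]], b = co[["b"]], c = co[["c"]])
  }))
  raw <- left_join(raw, models, by = "sample_id")
  raw$fitted_shift <- raw$a * raw$expected_rt^2 + raw$b * raw$expected_rt + raw$c
  list(shifts = raw[, c("sample_id", "metabolite", "expected_rt", "raw_shift", "fitted_shift")],
       models = models)
}

#' Two-pass RT shift estimation for a batch
#'
#' First pass: cross-correlation around the expected RT within
#' `initial_shift_window`, then a quadratic fit of shift versus RT per
#' sample. Second pass: the search is repeated in the narrower
#' `refined_shift_window` around the fitted shift, and the quadratic is
#' refitted on the refined shifts.
#'
#' @param chroms Batch chromatogram tibble (`sample_id`, `metabolite`, `role`,
#'   `chromatogram` list-column).
#' @param metabolites Metabolite definition tibble (needs `metabolite`,
#'   `expected_rt`).
#' @param ref_id Reference sample id, see [select_reference_sample()].
#' @param params [proc_params()] list.
#' @return List with `shifts` (tibble: `sample_id`, `metabolite`,
#'   `expected_rt`, `raw_shift`, `fitted_shift`) and `models` (tibble:
#'   `sample_id`, `a`, `b`, `c`).
#' @export
estimate_shift_models <- function(chroms, metabolites, ref_id, params = proc_params()) {
  sample_ids <- unique(chroms$sample_id)
  centers0 <- lapply(metabolites$metabolite, function(m) {
    stats::setNames(rep(0, length(sample_ids)), sample_ids)
  })
  names(centers0) <- metabolites$metabolite
  pass1 <- shift_pass(chroms, metabolites, ref_id, centers0,
                      params$initial_shift_window)

  centers1 <- lapply(metabolites$metabolite, function(m) {
    d <- pass1$shifts[pass1$shifts$metabolite == m, ]
    fs <- ifelse(is.finite(d$fitted_shift), d$fitted_shift, 0)
    stats::setNames(fs, d$sample_id)
  })
  names(centers1) <- metabolites$metabolite
  pass2 <- shift_pass(chroms, metabolites, ref_id, centers1,
                      params$refined_shift_window,
                      support_halfwidth = params$initial_shift_window)
  models <- list_rbind(map(sample_ids, function(s) {
    d <- pass2$shifts[pass2$shifts$sample_id == s, ]
    co <- suppressWarnings(fit_quadratic_shift(d$expected_rt, d$raw_shift))
    tibble(sample_id = s, a = co[["a"]], b = co[["b"]], c = co[["c"]])
  }))
  sh <- pass2$shifts[, c("sample_id", "metabolite", "expected_rt", "raw_shift")]
  sh <- left_join(sh, models, by = "sample_id")
  sh$fitted_shift <- sh$a * sh$expected_rt^2 + sh$b * sh$expected_rt + sh$c
  list(shifts = sh[, c("sample_id", "metabolite", "expected_rt", "raw_shift", "fitted_shift")],
       models = models, pass1 = pass1)
}

# helper: named list of role -> chromatogram tibble for one (sample, metabolite)
trace_list <- function(chroms, sample, metabolite) {
  d <- chroms[chroms$sample_id == sample & chroms$metabolite == metabolite, ]
  out <- stats::setNames(d$chromatogram, d$role)
  list(quantifier = out[["quantifier"]] %||% NULL,
       qualifier = out[["qualifier"]] %||% NULL,
       istd = out[["istd"]] %||% NULL)
}

#' Build the summed prototype chromatogram of a metabolite
#'
#' Every sample's traces are moved onto the reference time axis by
#' subtracting that sample's fitted shift, resampled onto a common uniform
#' grid around the expected RT, and summed per role. Peak picking with the
#' usual quality scores and classifier then selects the most likely peak on
#' the summed quantifier; summation makes this robust for noisy or
#' low-abundance signals.
#'
#' @inheritParams estimate_shift_models
#' @param metab One row of the metabolite tibble.
#' @param shifts The `shifts` tibble from [estimate_shift_models()].
#' @param score_fun Function mapping a 20-score matrix/tibble to picking
#'   scores (a trained classifier via [predict_score()] or
#'   [fallback_score()]).
#' @return List of class `mrm_prototype` with `metabolite`, `grid`, `summed`
#'   (named list role -> intensities), `candidates` (scored tibble) and
#'   `best_peak` (one-row tibble or `NULL` when no candidate exists).
#' @export
build_prototype <- function(chroms, metab, shifts, ref_id, params = proc_params(),
                            score_fun = fallback_score) {
  met <- metab$metabolite
  ref_q <- trace_list(chroms, ref_id, met)$quantifier
  dt <- if (!is.null(ref_q)) stats::median(diff(ref_q$time)) else NA_real_
  d <- chroms[chroms$metabolite == met, ]
  if (is.na(dt)) {
    any_q <- d$chromatogram[d$role == "quantifier"]
    if (length(any_q) == 0L) return(empty_prototype(met))
    dt <- stats::median(diff(any_q[[1L]]$time))
  }
  pad <- params$initial_shift_window + 0.35
  grid <- seq(metab$expected_rt - pad, metab$expected_rt + pad, by = dt)

  sh <- shifts[shifts$metabolite == met, ]
  shift_of <- stats::setNames(sh$fitted_shift, sh$sample_id)
  summed <- list()
  for (role in c("quantifier", "qualifier", "istd")) {
    rows <- d[d$role == role, ]
    if (nrow(rows) == 0L) next
    acc <- numeric(length(grid))
    used <- 0L
    for (i in seq_len(nrow(rows))) {
      s <- rows$sample_id[i]
      delta <- shift_of[[s]] %||% 0
      if (is.na(delta)) delta <- 0
      # aligned(t) = sample(t + shift): undo the sample's drift
      acc <- acc + resample_trace(rows$chromatogram[[i]], grid + delta)
      used <- used + 1L
    }
    if (used > 0L) summed[[role]] <- acc
  }
  if (is.null(summed$quantifier) || all(summed$quantifier == 0)) {
    return(empty_prototype(met, grid, summed))
  }

  proto_traces <- lapply(summed, function(y) tibble(time = grid, intensity = y))
  cand <- find_peak_candidates(proto_traces$quantifier,
                               n_candidates = params$n_candidates,
                               smoothing_width = params$smoothing_width,
                               border_frac = params$border_frac,
                               center = metab$expected_rt,
                               halfwidth = params$initial_shift_window)
  if (nrow(cand) == 0L) return(empty_prototype(met, grid, summed))
  qs <- list_rbind(map(seq_len(nrow(cand)), function(i) {
    as_tibble(as.list(compute_quality_scores(cand[i, ], proto_traces,
                                             expected_rt = metab$expected_rt,
                                             expected_ratio = metab$expected_ratio,
                                             predicted_shift = 0, params = params)))
  }))
  cand <- dplyr::bind_cols(cand, qs)
  cand$score <- score_fun(qs)
  best <- cand[order(-cand$score, cand$apex_time), ][1L, ]
  structure(list(metabolite = met, grid = grid, summed = summed,
                 candidates = cand, best_peak = best),
            class = "mrm_prototype")
}

empty_prototype <- function(met, grid = numeric(), summed = list()) {
  structure(list(metabolite = met, grid = grid, summed = summed,
                 candidates = tibble(), best_peak = NULL),
            class = "mrm_prototype")
}

#' Propagate prototype peak borders back into a sample's time axis
#'
#' The prototype lives on the reference time axis; a sample's peak is the
#' prototype peak moved by that sample's fitted shift at the metabolite's
#' expected RT. Borders are clipped to the sample trace extent.
#'
#' @param prototype An `mrm_prototype` from [build_prototype()].
#' @param fitted_shift Fitted shift (minutes) of the sample at this
#'   metabolite's expected RT.
#' @param trace The sample's quantifier chromatogram (for clipping), or
#'   `NULL` to skip clipping.
#' @return Named numeric `c(start_time, end_time)` or `NULL` when the
#'   prototype has no best peak.
#' @export
propagate_borders <- function(prototype, fitted_shift, trace = NULL) {
  bp <- prototype$best_peak
  if (is.null(bp)) return(NULL)
  st <- bp$start_time + fitted_shift
  en <- bp$end_time + fitted_shift
  if (!is.null(trace)) {
    rng <- range(trace$time)
    st2 <- min(max(st, rng[1L]), rng[2L])
    en2 <- min(max(en, rng[1L]), rng[2L])
    if (st2 != st || en2 != en) {
      warn(sprintf("Propagated borders clipped to trace extent for %s.", prototype$metabolite))
    }
    st <- st2; en <- en2
  }
  c(start_time = st, end_time = en)
}
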