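#' Names of the 20 chromatographic quality scores
#'
#' Every score lies in \[0, 1\] with 1 ideal, and is invariant under scaling
#' all intensities by a positive constant. The scores fall into three
#' families: peak shape, agreement between quantifier and qualifier traces,
#' and deviation from the expected retention time.
#'
#' \describe{
#'   \item{qs_t_o}{Quantifier apex height over the highest point outside the
#'     peak borders, squashed onto \[0,1\] by `1 - 1/r`.}
#'   \item{qs_to2}{Same ratio for the (unlabelled) qualifier trace.}
#'   \item{qs_t_h}{Qualifier apex over the higher of its two border
#'     intensities, squashed.}
#'   \item{qs_t_l}{Qualifier apex over the lower border intensity, squashed.}
#'   \item{qs_quant_h, qs_quant_l}{Quantifier analogues of the two border
#'     ratios.}
#'   \item{qs_drt}{`max(0, 1 - |apex - expected_rt| / drt_window)`.}
#'   \item{qs_drts}{As `qs_drt` with the expected RT moved by the predicted
#'     shift of this sample relative to the reference.}
#'   \item{qs_cor123}{Mean pairwise Pearson correlation among the available
#'     quantifier/qualifier/ISTD traces inside the peak window, clipped at 0.}
#'   \item{qs_gauss}{Pearson correlation of the quantifier peak with a
#'     least-squares Gaussian, clipped at 0.}
#'   \item{qs_qual_gauss}{Gaussian correlation of the qualifier peak.}
#'   \item{qs_sym, qs_qual_sym}{Peak symmetry: ratio of the shorter to the
#'     longer half-width at half maximum (quantifier / qualifier).}
#'   \item{qs_ratio_h}{Agreement of the observed quantifier/qualifier apex
#'     height ratio with the expected ratio, `min(r/e, e/r)`.}
#'   \item{qs_ratio_a}{Same agreement computed on baseline-subtracted areas.}
#'   \item{qs_width}{Peak-width plausibility: 1 inside `peak_width_range`,
#'     falling linearly to 0 towards width 0 and twice the upper bound.}
#'   \item{qs_noise}{Apex height over three times the noise floor estimated
#'     outside the peak (median absolute successive difference), squashed.}
#'   \item{qs_missing}{Fraction of strictly positive points inside the peak.}
#'   \item{qs_qual_present}{1 if any qualifier/ISTD trace carries signal
#'     inside the peak window, else 0.}
#'   \item{qs_smooth}{Correlation of the raw and smoothed quantifier trace
#'     inside the window, clipped at 0 (penalises spiky noise).}
#' }
#'
#' Scores that require a qualifier trace are 0 when no qualifier is present.
#' @export
qs_names <- function() {
  c("qs_t_o", "qs_to2", "qs_t_h", "qs_t_l", "qs_quant_h", "qs_quant_l",
    "qs_drt", "qs_drts", "qs_cor123", "qs_gauss", "qs_qual_gauss", "qs_sym",
    "qs_qual_sym", "qs_ratio_h", "qs_ratio_a", "qs_width", "qs_noise",
    "qs_missing", "qs_qual_present", "qs_smooth")
}

# correlation clipped to [0,1]; degenerate inputs give 0
cor_pos <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  max(0, stats::cor(x, y))
}

# correlation with a Gaussian whose centre/width maximise the fit
# (moment initialisation, Nelder-Mead refinement); amplitude and offset are
# absorbed by the correlation itself
gauss_cor <- function(t, y) {
  if (length(t) < 4L || stats::sd(y) == 0) return(0)
  w <- pmax(y, 0)
  if (sum(w) == 0) return(0)
  mu0 <- sum(w * t) / sum(w)
  s0 <- sqrt(sum(w * (t - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- (t[length(t)] - t[1L]) / 6
  obj <- function(p) {
    g <- exp(-0.5 * ((t - p[1L]) / exp(p[2L]))^2)
    if (stats::sd(g) == 0) return(0)
    -suppressWarnings(stats::cor(y, g))
  }
  fit <- stats::optim(c(mu0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 200))
  max(0, -fit$value, na.rm = TRUE)
}

# half-width-at-half-max symmetry of the maximum inside [start, end]
symmetry_score <- function(t, y) {
  k <- which.max(y)
  apex <- y[k]
  if (apex <= 0 || k == 1L || k == length(y)) return(0)
  half <- apex / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(k, 1L) else seq(k, length(y))
    below <- which(y[idx] <= half)
    if (length(below) == 0L) return(abs(t[idx[length(idx)]] - t[k]))
    j <- below[1L]
    i1 <- idx[j - 1L]; i2 <- idx[j]
    frac <- (y[i1] - half) / (y[i1] - y[i2])
    abs(t[i1] + frac * (t[i2] - t[i1]) - t[k])
  }
  l <- cross(-1); r <- cross(+1)
  if (max(l, r) == 0) return(0)
  min(l, r) / max(l, r)
}

ratio_agreement <- function(observed, expected) {
  if (!is.finite(observed) || !is.finite(expected) || observed <= 0 || expected <= 0) return(0)
  min(observed / expected, expected / observed)
}

#' Compute the 20-element quality-score vector for one peak candidate
#'
#' @param candidate A one-row data frame (or list) with at least `apex_time`,
#'   `start_time` and `end_time` (minutes), as produced by
#'   [find_peak_candidates()].
#' @param traces Named list of chromatograms for this metabolite in this
#'   sample; roles `quantifier` (required), `qualifier` and `istd` (optional,
#'   `NULL` when absent).
#' @param expected_rt Expected retention time (minutes).
#' @param expected_ratio Expected quantifier/qualifier intensity ratio, or
#'   `NA` when unknown.
#' @param predicted_shift Predicted RT shift (minutes) of this sample versus
#'   the reference sample at this metabolite's RT; 0 before alignment.
#' @param params An [proc_params()] list.
#' @return Named numeric vector of length 20 (see [qs_names()]), all values
#'   finite and in \[0, 1\].
#' @export
compute_quality_scores <- function(candidate, traces, expected_rt,
                                   expected_ratio = NA_real_,
                                   predicted_shift = 0, params = proc_params()) {
  quant <- traces$quantifier
  if (is.null(quant)) abort("`traces$quantifier` is required.")
  assert_chromatogram(quant, "traces$quantifier")
  st <- candidate$start_time
  en <- candidate$end_time
  apex_t <- candidate$apex_time

  inside <- quant$time >= st & quant$time <= en
  t_in <- quant$time[inside]
  q_in <- quant$intensity[inside]
  q_out <- quant$intensity[!inside]
  q_apex <- if (length(q_in)) max(q_in) else 0

  qual <- traces$qualifier
  istd <- traces$istd
  has_qual <- !is.null(qual)
  border_pair <- function(chrom) {
    c(interp_at(chrom$time, chrom$intensity, st),
      interp_at(chrom$time, chrom$intensity, en))
  }

  qs <- stats::setNames(numeric(20L), qs_names())

  # -- height relative to surroundings (shape family) -----------------------
  out_max <- if (length(q_out)) max(q_out) else 0
  qs["qs_t_o"] <- squash_ratio(if (out_max > 0) q_apex / out_max else Inf * (q_apex > 0))
  qb <- border_pair(quant)
  qs["qs_quant_h"] <- squash_ratio(if (max(qb) > 0) q_apex / max(qb) else Inf * (q_apex > 0))
  qs["qs_quant_l"] <- squash_ratio(if (min(qb) > 0) q_apex / min(qb) else Inf * (q_apex > 0))

  if (has_qual) {
    ql_in <- qual$intensity[qual$time >= st & qual$time <= en]
    ql_out <- qual$intensity[qual$time < st | qual$time > en]
    ql_apex <- if (length(ql_in)) max(ql_in) else 0
    ql_out_max <- if (length(ql_out)) max(ql_out) else 0
    qs["qs_to2"] <- squash_ratio(if (ql_out_max > 0) ql_apex / ql_out_max else Inf * (ql_apex > 0))
    qlb <- border_pair(qual)
    qs["qs_t_h"] <- squash_ratio(if (max(qlb) > 0) ql_apex / max(qlb) else Inf * (ql_apex > 0))
    qs["qs_t_l"] <- squash_ratio(if (min(qlb) > 0) ql_apex / min(qlb) else Inf * (ql_apex > 0))
  }

  # -- deviation from expected RT -------------------------------------------
  qs["qs_drt"] <- max(0, 1 - abs(apex_t - expected_rt) / params$drt_window)
  qs["qs_drts"] <- max(0, 1 - abs(apex_t - (expected_rt + predicted_shift)) / params$drt_window)

  # -- quantifier/qualifier agreement ---------------------------------------
  roles_in <- list(q_in)
  for (tr in list(qual, istd)) {
    if (!is.null(tr)) roles_in <- c(roles_in, list(resample_trace(tr, t_in)))
  }
  if (length(roles_in) >= 2L && length(t_in) >= 3L) {
    pairs <- utils::combn(length(roles_in), 2L)
    cors <- apply(pairs, 2L, function(p) {
      a <- roles_in[[p[1L]]]; b <- roles_in[[p[2L]]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    })
    cors <- cors[is.finite(cors)]
    if (length(cors)) qs["qs_cor123"] <- max(0, mean(cors))
  }
  if (has_qual) {
    ql_res <- resample_trace(qual, t_in)
    ql_apex_in <- if (length(ql_res)) max(ql_res) else 0
    if (ql_apex_in > 0) {
      qs["qs_ratio_h"] <- ratio_agreement(q_apex / ql_apex_in, expected_ratio)
      a_q <- integrate_peak(quant, st, en)$area
      a_l <- tryCatch(integrate_peak(qual, max(st, qual$time[1L]),
                                     min(en, qual$time[nrow(qual)]))$area,
                      error = function(e) 0)
      if (a_q > 0 && a_l > 0) qs["qs_ratio_a"] <- ratio_agreement(a_q / a_l, expected_ratio)
    }
  }
  present <- FALSE
  for (tr in list(qual, istd)) {
    if (!is.null(tr) && any(resample_trace(tr, t_in) > 0)) present <- TRUE
  }
  qs["qs_qual_present"] <- as.numeric(present)

  # -- peak shape -------------------------------------------------------------
  if (length(t_in) >= 4L) {
    qs["qs_gauss"] <- gauss_cor(t_in, q_in)
    qs["qs_sym"] <- symmetry_score(t_in, q_in)
    if (has_qual) {
      ql_res <- resample_trace(qual, t_in)
      qs["qs_qual_gauss"] <- gauss_cor(t_in, ql_res)
      qs["qs_qual_sym"] <- symmetry_score(t_in, ql_res)
    }
    sm <- smooth_trace(q_in, min(params$smoothing_width, largest_odd(length(q_in))))
    qs["qs_smooth"] <- cor_pos(q_in, sm)
  }
  w <- en - st
  wr <- params$peak_width_range
  qs["qs_width"] <- if (w < wr[1L]) w / wr[1L] else if (w <= wr[2L]) 1 else max(0, 2 - w / wr[2L])
  if (length(q_out) >= 3L) {
    noise <- stats::mad(diff(q_out)) / sqrt(2)
    h <- integrate_peak(quant, st, en)$height
    qs["qs_noise"] <- if (noise == 0) as.numeric(h > 0) else squash_ratio(h / (3 * noise))
  } else {
    qs["qs_noise"] <- as.numeric(q_apex > 0)
  }
  qs["qs_missing"] <- if (length(q_in)) mean(q_in > 0) else 0

  qs[!is.finite(qs)] <- 0
  pmin(pmax(qs, 0), 1)
}

#' Assemble the 26-feature vector for the peak-reporting classifier
#'
#' Appends to the 20 quality scores the peak-picking classification score of
#' this metabolite in this sample (`output_h`) and the 0th/25th/50th/75th/
#' 100th percentiles of that score for this metabolite across all samples of
#' the batch, so the reporting model can judge a peak relative to its peers.
#'
#' @param qs Named numeric vector of 20 quality scores ([qs_names()]).
#' @param output_h Peak-picking classification score for this sample.
#' @param all_scores Numeric vector of picking scores of this metabolite
#'   across all samples in the batch (must be non-empty).
#' @return Named numeric vector of length 26 in fixed order: the 20 scores,
#'   `output_h`, `rf0`, `rf25`, `rf50`, `rf75`, `rf100`.
#' @export
assemble_reporting_features <- function(qs, output_h, all_scores) {
  if (length(all_scores) == 0L) abort("`all_scores` must be non-empty.")
  stopifnot(length(qs) == 20L)
  qt <- stats::quantile(all_scores, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(stats::setNames(as.numeric(qs), qs_names()),
    output_h = as.numeric(output_h),
    rf0 = qt[1L], rf25 = qt[2L], rf50 = qt[3L], rf75 = qt[4L], rf100 = qt[5L])
}

#' @rdname qs_names
#' @export
reporting_feature_names <- function() {
  c(qs_names(), "output_h", "rf0", "rf25", "rf50", "rf75", "rf100")
}
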