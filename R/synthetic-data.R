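#' Configuration for the synthetic MRM batch generator
#'
#' The generator emulates the statistical structure targeted preprocessing
#' has to cope with: run-order RT drift that is quadratic in RT,
#' per-metabolite RT jitter on top of the trend, Gaussian (optionally
#' exponentially modified) peaks with sample-to-sample amplitude variation,
#' qualifier traces proportional to the quantifier, a constant-amplitude
#' \eqn{^{13}}C internal-standard trace, additive baseline noise, randomly
#' absent peaks, and interfering decoy peaks near the target that may exceed
#' it in intensity.
#'
#' @param n_samples,n_metabolites Batch dimensions.
#' @param rt_range Length-2 numeric, range (min) over which expected RTs are
#'   drawn uniformly.
#' @param drift_a Quadratic drift coefficient (min^-1): the last sample in
#'   run order is shifted by `drift_a * rt^2`; earlier samples scale linearly
#'   down to 0 for the first sample.
#' @param jitter_sd SD (min) of per-metabolite-per-sample RT jitter around
#'   the drift trend, truncated at +/- 0.5 min.
#' @param peak_sd_range Range (min) of Gaussian peak SDs, drawn per
#'   metabolite.
#' @param amplitude_range Range (counts) of per-metabolite base amplitudes,
#'   drawn log-uniformly.
#' @param noise_sd SD (counts) of additive Gaussian noise (clipped at 0).
#' @param baseline Constant background level (counts).
#' @param qualifier_ratio Qualifier amplitude as a fraction of the
#'   quantifier amplitude; the metabolite's expected quantifier/qualifier
#'   ratio is its reciprocal.
#' @param p_missing Probability that a metabolite's peak is absent in a
#'   sample (truth area 0).
#' @param p_decoy Probability of an interfering peak 0.3--0.8 min away from
#'   the target on the quantifier trace only, with 0.5--1.5x the target
#'   amplitude.
#' @param sampling_interval Trace sampling interval (min).
#' @param emg_tau Exponential tail constant (min) for exponentially modified
#'   Gaussian peaks; 0 (default) gives pure Gaussians.
#' @param amplitude_cv Log-scale SD of the per-sample amplitude variation.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `mrm_sim_config`.
#' @export
sim_config <- function(n_samples = 12L, n_metabolites = 10L,
                       rt_range = c(0.5, 9), drift_a = 0.005,
                       jitter_sd = 0.02, peak_sd_range = c(0.03, 0.06),
                       amplitude_range = c(1e4, 1e6), noise_sd = 50,
                       baseline = 100, qualifier_ratio = 0.5,
                       p_missing = 0.1, p_decoy = 0.2,
                       sampling_interval = 0.01, emg_tau = 0, seed = 1L) {
  if (n_samples < 1L || n_metabolites < 1L) abort("Batch dimensions must be >= 1.")
  for (p in c(p_missing, p_decoy)) {
    if (p < 0 || p > 1) abort("Probabilities must lie in [0, 1].")
  }
  if (diff(rt_range) <= 8 * max(peak_sd_range)) {
    abort("`rt_range` is too short for the configured peak widths.")
  }
  if (sampling_interval <= 0 || any(peak_sd_range <= 0) || any(amplitude_range <= 0)) {
    abort("Intervals, widths and amplitudes must be positive.")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_metabolites = as.integer(n_metabolites),
    rt_range = rt_range, drift_a = drift_a, jitter_sd = jitter_sd,
    peak_sd_range = peak_sd_range, amplitude_range = amplitude_range,
    noise_sd = noise_sd, baseline = baseline, qualifier_ratio = qualifier_ratio,
    p_missing = p_missing, p_decoy = p_decoy,
    sampling_interval = sampling_interval, emg_tau = emg_tau,
    seed = as.integer(seed)
  ), class = "mrm_sim_config")
}

# peak shape on a grid: Gaussian, or exponentially modified Gaussian when
# tau > 0. Both integrate to A * sigma * sqrt(2*pi).
peak_shape <- function(t, apex, A, sigma, tau = 0) {
  if (tau <= 0) return(A * exp(-0.5 * ((t - apex) / sigma)^2))
  # EMG parameterised by the Gaussian centre mu = apex (mode shifts right)
  z <- (sigma / tau - (t - apex) / sigma) / sqrt(2)
  A * sigma / tau * sqrt(pi / 2) * exp(0.5 * (sigma / tau)^2 - (t - apex) / tau) *
    erfc_stable(z)
}

erfc_stable <- function(z) {
  # complementary error function via pnorm; guard the exp overflow region
  2 * stats::pnorm(-sqrt(2) * z)
}

#' Generate a synthetic MRM batch with known ground truth
#'
#' Returns in-memory chromatograms (one trace per role per metabolite per
#' sample, on a window of +/- 1.2 min around the expected RT, mimicking
#' per-transition acquisition segments), the metabolite definition table and
#' a truth table with the true apex, borders (+/- 3 SD, the visible peak
#' extent an expert marks as start/end; the signal there is ~1% of the
#' apex), analytic area
#' `A * sigma * sqrt(2*pi)` and presence flag for every cell. The
#' internal-standard trace is always present with a constant amplitude per
#' metabolite, also when the analyte peak is absent.
#'
#' @param cfg An [sim_config()] object.
#' @return List of class `mrm_sim_batch` with elements `samples`,
#'   `metabolites`, `chromatograms`, `truth` and `config`. Deterministic
#'   given `cfg$seed`.
#' @export
generate_batch <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "mrm_sim_config"))
  n_s <- cfg$n_samples
  n_m <- cfg$n_metabolites

  mets <- withr::with_seed(derive_seed(cfg$seed, 1L), {
    rt <- sort(stats::runif(n_m, cfg$rt_range[1L], cfg$rt_range[2L]))
    q1 <- round(stats::runif(n_m, 100, 600), 1)
    q3 <- round(stats::runif(n_m, 40, 90) + q1 * stats::runif(n_m, 0.1, 0.5), 1)
    tibble(
      metabolite = sprintf("M%02d", seq_len(n_m)),
      quant_precursor = q1, quant_product = q3,
      qual_precursor = q1, qual_product = round(q3 + stats::runif(n_m, 5, 25), 1),
      istd_precursor = q1 + 6, istd_product = q3 + 6,
      polarity = "positive",
      expected_rt = rt,
      expected_ratio = 1 / cfg$qualifier_ratio,
      db_id = sprintf("SYN:%04d", seq_len(n_m)),
      peak_sd = stats::runif(n_m, cfg$peak_sd_range[1L], cfg$peak_sd_range[2L]),
      base_amplitude = exp(stats::runif(n_m, log(cfg$amplitude_range[1L]),
                                        log(cfg$amplitude_range[2L]))),
      istd_amplitude = exp(stats::runif(n_m, log(cfg$amplitude_range[1L]),
                                        log(cfg$amplitude_range[2L])))
    )
  })

  drift_coef <- if (n_s == 1L) 0 else cfg$drift_a * (seq_len(n_s) - 1L) / (n_s - 1L)
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(n_s)),
    run_index = seq_len(n_s),
    drift_coef = drift_coef,
    group = sprintf("G%02d", (seq_len(n_s) - 1L) %/% 4L + 1L)
  )

  chroms <- vector("list", n_s * n_m)
  truth <- vector("list", n_s * n_m)
  k <- 0L
  for (si in seq_len(n_s)) {
    for (mi in seq_len(n_m)) {
      k <- k + 1L
      met <- mets[mi, ]
      res <- withr::with_seed(derive_seed(cfg$seed, si + 1L, mi), {
        simulate_cell(met, samples$drift_coef[si], cfg)
      })
      res$chroms$sample_id <- samples$sample_id[si]
      res$truth$sample_id <- samples$sample_id[si]
      chroms[[k]] <- res$chroms
      truth[[k]] <- res$truth
    }
  }
  chroms <- list_rbind(chroms)[, c("sample_id", "metabolite", "role", "chromatogram")]
  truth <- list_rbind(truth)[, c("metabolite", "sample_id", "present", "true_apex",
                                 "true_start", "true_end", "true_area",
                                 "true_height", "true_shift")]
  structure(list(samples = samples, metabolites = mets,
                 chromatograms = chroms, truth = truth, config = cfg),
            class = "mrm_sim_batch")
}

# one (sample, metabolite) cell: all role traces plus its truth row
simulate_cell <- function(met, a_s, cfg) {
  rt <- met$expected_rt
  shift <- a_s * rt^2 + max(-0.5, min(0.5, stats::rnorm(1L, 0, cfg$jitter_sd)))
  apex <- rt + shift
  sigma <- met$peak_sd
  amp <- met$base_amplitude * exp(stats::rnorm(1L, 0, 0.25))
  present <- stats::runif(1L) >= cfg$p_missing
  decoy <- stats::runif(1L) < cfg$p_decoy

  grid <- seq(rt - 1.2, rt + 1.2, by = cfg$sampling_interval)
  signal_q <- numeric(length(grid))
  signal_l <- numeric(length(grid))
  if (present) {
    signal_q <- peak_shape(grid, apex, amp, sigma, cfg$emg_tau)
    signal_l <- cfg$qualifier_ratio * signal_q
  }
  if (decoy) {
    off <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.3, 0.8)
    d_amp <- amp * stats::runif(1L, 0.5, 1.5)
    signal_q <- signal_q + peak_shape(grid, apex + off, d_amp, sigma, cfg$emg_tau)
  }
  signal_i <- peak_shape(grid, apex, met$istd_amplitude, sigma, cfg$emg_tau)

  noisy <- function(sig) {
    y <- sig + cfg$baseline + stats::rnorm(length(grid), 0, cfg$noise_sd)
    tibble(time = grid, intensity = pmax(0, y))
  }
  chroms <- tibble(
    metabolite = met$metabolite,
    role = c("quantifier", "qualifier", "istd"),
    chromatogram = list(noisy(signal_q), noisy(signal_l), noisy(signal_i))
  )
  # truth apex: mode of the (possibly tailed) peak shape
  true_apex <- if (cfg$emg_tau > 0) grid[which.max(peak_shape(grid, apex, amp, sigma, cfg$emg_tau))] else apex
  truth <- tibble(
    metabolite = met$metabolite,
    present = present,
    true_apex = if (present) true_apex else NA_real_,
    true_start = if (present) true_apex - 3 * sigma else NA_real_,
    true_end = if (present) true_apex + 3 * sigma + 4 * cfg$emg_tau else NA_real_,
    true_area = if (present) amp * sigma * sqrt(2 * pi) else 0,
    true_height = if (present) amp else 0,
    true_shift = shift
  )
  list(chroms = chroms, truth = truth)
}

#' Emit training-solution tables for a synthetic batch
#'
#' The picking solution gives peak area, start and end per metabolite per
#' sample (area 0 where the peak is absent); the reporting solution assigns
#' 2 (report) to present peaks and 0 (do not report) to absent ones.
#'
#' @param truth Truth table from [generate_batch()].
#' @param dir Optional directory; when given, the two tables are written as
#'   `training_solution.csv` and `reporting_solution.csv`.
#' @return List with tibbles `picking` (`metabolite`, `sample_id`, `area`,
#'   `start`, `end`) and `reporting` (`metabolite`, `sample_id`, `value`).
#' @export
emit_training_solutions <- function(truth, dir = NULL) {
  picking <- tibble(
    metabolite = truth$metabolite, sample_id = truth$sample_id,
    area = ifelse(truth$present, truth$true_area, 0),
    start = ifelse(truth$present, truth$true_start, 0),
    end = ifelse(truth$present, truth$true_end, 0)
  )
  reporting <- tibble(
    metabolite = truth$metabolite, sample_id = truth$sample_id,
    value = ifelse(truth$present, 2L, 0L)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(picking, file.path(dir, "training_solution.csv"))
    readr::write_csv(reporting, file.path(dir, "reporting_solution.csv"))
  }
  list(picking = picking, reporting = reporting)
}

#' @export
print.mrm_sim_batch <- function(x, ...) {
  cat(sprintf("<mrm_sim_batch: %d samples x %d metabolites, seed %d>\n",
              nrow(x$samples), nrow(x$metabolites), x$config$seed))
  cat(sprintf("  present peaks: %d / %d | traces: %d\n",
              sum(x$truth$present), nrow(x$truth), nrow(x$chromatograms)))
  invisible(x)
}
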