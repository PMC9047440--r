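#' Processing parameters for batch preprocessing
#'
#' Collects the tunable knobs of the preprocessing chain in one validated
#' list. All times are minutes.
#'
#' @param smoothing_width Odd moving-average width in points (default 5).
#' @param n_candidates Number of candidate peaks evaluated per metabolite per
#'   sample (default 5).
#' @param initial_shift_window Half-width (min) of the first-pass
#'   cross-correlation search around the expected retention time (default 0.5,
#'   the scale of run-to-run HILIC drift).
#' @param refined_shift_window Half-width (min) of the second pass around the
#'   fitted shift (default 0.17, about 10 s).
#' @param drt_window Scale (min) on which deviation from the expected
#'   retention time degrades the RT quality scores (default 0.5).
#' @param border_frac Peak borders stop at the first point below this fraction
#'   of the apex (default 0.01).
#' @param peak_width_range Length-2 numeric, the range of plausible peak
#'   widths in minutes used by the width quality score (default 0.05--0.6).
#' @param mz_tolerance Transition matching tolerance in Th (default 0.05).
#' @param report_threshold Reporting-gate cutoff on the reporting score in
#'   \[0, 1\] (default 0.5).
#' @param random_seed Integer seed recorded with trained models.
#' @return A named list of class `mrm_params`.
#' @export
proc_params <- function(smoothing_width = 5L, n_candidates = 5L,
                        initial_shift_window = 0.5, refined_shift_window = 0.17,
                        drt_window = 0.5, border_frac = 0.01,
                        peak_width_range = c(0.05, 0.6), mz_tolerance = 0.05,
                        report_threshold = 0.5, random_seed = 1L) {
  smoothing_width <- as.integer(smoothing_width)
  if (smoothing_width < 1L || !is_odd(smoothing_width)) {
    abort("`smoothing_width` must be an odd integer >= 1.")
  }
  if (n_candidates < 1L) abort("`n_candidates` must be >= 1.")
  for (w in c(initial_shift_window, refined_shift_window, drt_window)) {
    if (!is.numeric(w) || w <= 0) abort("shift/RT windows must be positive.")
  }
  if (border_frac <= 0 || border_frac >= 1) abort("`border_frac` must be in (0, 1).")
  if (report_threshold < 0 || report_threshold > 1) {
    abort("`report_threshold` must be in [0, 1].")
  }
  structure(list(
    smoothing_width = smoothing_width, n_candidates = as.integer(n_candidates),
    initial_shift_window = initial_shift_window,
    refined_shift_window = refined_shift_window, drt_window = drt_window,
    border_frac = border_frac, peak_width_range = peak_width_range,
    mz_tolerance = mz_tolerance, report_threshold = report_threshold,
    random_seed = as.integer(random_seed)
  ), class = "mrm_params")
}

#' Read processing parameters from a YAML or TSV key-value file
#'
#' YAML files (`.yml`/`.yaml`) are parsed with the yaml package when
#' available; otherwise the file is read as a two-column TSV of
#' `parameter<TAB>value` pairs. Unknown keys are rejected.
#'
#' @param path Path to the parameter file.
#' @return An `mrm_params` list, see [proc_params()].
#' @export
read_processing_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("Parameter file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE) &&
      requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    kv <- utils::read.delim(path, header = FALSE, col.names = c("key", "value"),
                            stringsAsFactors = FALSE, comment.char = "#")
    vals <- as.list(kv$value)
    names(vals) <- kv$key
    vals <- lapply(vals, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
  }
  known <- names(formals(proc_params))
  extra <- setdiff(names(vals), known)
  if (length(extra)) abort(sprintf("Unknown parameter(s): %s", paste(extra, collapse = ", ")))
  do.call(proc_params, vals)
}
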