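#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows row_number desc n across all_of
#' @importFrom purrr map map_dbl map2 pmap list_rbind
#' @keywords internal
"_PACKAGE"

# trapezoidal integral of y over t (t increasing)
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

# squashing map for unbounded ratios r >= 0 onto [0, 1]:
# r <= 1 -> 0, r -> Inf -> 1. Keeps all quality scores commensurable.
squash_ratio <- function(r) {
  ifelse(is.finite(r) & r > 0, pmax(0, 1 - 1 / r), ifelse(is.infinite(r) & r > 0, 1, 0))
}

# linear interpolation of a trace at time t (single value), 0 outside range
interp_at <- function(time, intensity, t) {
  stats::approx(time, intensity, xout = t, rule = 1)$y %||% NA_real_
}

is_odd <- function(x) x %% 2 == 1

assert_chromatogram <- function(chrom, arg = "chrom") {
  if (!is.data.frame(chrom) || !all(c("time", "intensity") %in% names(chrom))) {
    abort(sprintf("`%s` must be a data frame with columns `time` and `intensity`.", arg))
  }
  if (nrow(chrom) < 2L) abort(sprintf("`%s` must contain at least 2 points.", arg))
  if (is.unsorted(chrom$time, strictly = TRUE)) {
    abort(sprintf("`%s$time` must be strictly increasing.", arg))
  }
  invisible(chrom)
}

# deterministic sub-seed derivation so batches are reproducible independent
# of the order in which samples/metabolites are generated
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 7919 + i * 104729 + j * 1299709) %% 2147483647)
}
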