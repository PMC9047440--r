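#' Smooth an intensity series with a centred moving average
#'
#' Windows shrink symmetrically-as-available at the trace edges, so the output
#' has the same length as the input and a constant series is left unchanged.
#' `width = 1` is the identity.
#'
#' @param intensities Numeric vector of non-negative intensities.
#' @param width Odd integer window width in points (default 5).
#' @return Numeric vector, same length as `intensities`.
#' @examples
#' smooth_trace(c(0, 0, 3, 0, 0), 3)
#' @export
smooth_trace <- function(intensities, width = 5L) {
  width <- as.integer(width)
  if (width < 1L || !is_odd(width)) abort("`width` must be an odd integer >= 1.")
  n <- length(intensities)
  if (width > n) abort("`width` must not exceed the series length.")
  if (width == 1L) return(as.numeric(intensities))
  h <- (width - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- cumsum(c(0, as.numeric(intensities)))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# indices of strict local maxima; runs of equal values are collapsed and the
# first index of a qualifying plateau is reported. Endpoints never qualify.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(as.numeric(y))
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  run_start <- cumsum(c(1L, r$lengths[-k]))
  j <- 2L:(k - 1L)
  is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  run_start[j][is_max]
}

#' Detect peak borders by walking outward from an apex
#'
#' Walks out from the apex on the smoothed trace in each direction until the
#' first point that is a local minimum or falls below
#' `border_frac * apex intensity`, whichever comes first. Borders are clipped
#' to the trace extent.
#'
#' @param chrom Chromatogram: data frame with `time` and `intensity`.
#' @param apex_idx Index (1-based) of a local maximum of the smoothed trace.
#' @param smoothing_width Odd moving-average width used for the walk.
#' @param border_frac Fraction of the apex intensity below which the walk
#'   stops (default 0.01).
#' @return Named list with `start_time`, `end_time`, `start_idx`, `end_idx`.
#' @export
detect_peak_borders <- function(chrom, apex_idx, smoothing_width = 5L,
                                border_frac = 0.01) {
  assert_chromatogram(chrom)
  y <- smooth_trace(chrom$intensity, min(smoothing_width, largest_odd(nrow(chrom))))
  n <- length(y)
  apex_idx <- as.integer(apex_idx)
  if (apex_idx < 1L || apex_idx > n) abort("`apex_idx` out of range.")
  if ((apex_idx > 1L && y[apex_idx - 1L] > y[apex_idx]) ||
      (apex_idx < n && y[apex_idx + 1L] > y[apex_idx])) {
    abort("`apex_idx` is not a local maximum of the smoothed trace.")
  }
  lim <- border_frac * y[apex_idx]
  walk <- function(dir) {
    i <- apex_idx
    repeat {
      nxt <- i + dir
      if (nxt < 1L || nxt > n) return(i)
      if (y[nxt] < lim) return(nxt)       # first point below the fraction
      if (y[nxt] > y[i]) return(i)        # i is a local minimum
      i <- nxt
    }
  }
  s <- walk(-1L)
  e <- walk(+1L)
  list(start_time = chrom$time[s], end_time = chrom$time[e],
       start_idx = s, end_idx = e)
}

largest_odd <- function(n) if (is_odd(n)) n else n - 1L

#' Find candidate peaks on a chromatogram
#'
#' Strict local maxima of the smoothed trace inside the search window, ranked
#' by smoothed apex intensity (descending; ties broken by earlier retention
#' time). Each candidate carries borders from [detect_peak_borders()] and the
#' raw area/height from [integrate_peak()].
#'
#' @param chrom Chromatogram: data frame with `time` (minutes) and `intensity`.
#' @param n_candidates Maximum number of candidates to return (default 5).
#' @param smoothing_width Odd moving-average width in points (default 5).
#' @param border_frac Border fraction, see [detect_peak_borders()].
#' @param center,halfwidth Optional search window `[center - halfwidth,
#'   center + halfwidth]` in minutes; both `NULL` searches the whole trace.
#' @return Tibble with one row per candidate: `rank`, `apex_idx`, `apex_time`,
#'   `apex_intensity` (smoothed), `start_time`, `end_time`, `height`, `area`.
#'   Zero rows if the trace is flat in the window.
#' @export
find_peak_candidates <- function(chrom, n_candidates = 5L, smoothing_width = 5L,
                                 border_frac = 0.01, center = NULL,
                                 halfwidth = NULL) {
  assert_chromatogram(chrom)
  if (n_candidates < 1L) abort("`n_candidates` must be >= 1.")
  y <- smooth_trace(chrom$intensity, min(smoothing_width, largest_odd(nrow(chrom))))
  idx <- local_maxima(y)
  if (!is.null(center) && !is.null(halfwidth)) {
    keep <- chrom$time[idx] >= center - halfwidth & chrom$time[idx] <= center + halfwidth
    idx <- idx[keep]
  }
  if (length(idx) == 0L) {
    return(tibble(rank = integer(), apex_idx = integer(), apex_time = double(),
                  apex_intensity = double(), start_time = double(),
                  end_time = double(), height = double(), area = double()))
  }
  ord <- order(-y[idx], chrom$time[idx])
  idx <- idx[ord][seq_len(min(n_candidates, length(idx)))]
  cand <- map(idx, function(i) {
    b <- detect_peak_borders(chrom, i, smoothing_width, border_frac)
    ih <- integrate_peak(chrom, b$start_time, b$end_time)
    tibble(apex_idx = i, apex_time = chrom$time[i], apex_intensity = y[i],
           start_time = b$start_time, end_time = b$end_time,
           height = ih$height, area = ih$area)
  })
  out <- list_rbind(cand)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "apex_idx", "apex_time", "apex_intensity", "start_time",
          "end_time", "height", "area")]
}

#' Integrate a peak between two borders above a linear baseline
#'
#' The baseline is the straight line between the trace intensities at
#' `start_time` and `end_time`; this absorbs non-flat backgrounds. Area is the
#' trapezoidal integral of intensity above the baseline, height the maximal
#' intensity above the baseline inside the window; both are clamped at 0.
#'
#' @inheritParams detect_peak_borders
#' @param start_time,end_time Window borders in minutes, within the trace.
#' @return Named list with `area` (counts * min), `height` (counts) and
#'   `apex_time` (minutes, position of the maximum inside the window).
#' @export
integrate_peak <- function(chrom, start_time, end_time) {
  assert_chromatogram(chrom)
  if (!(start_time < end_time)) abort("`start_time` must be < `end_time`.")
  if (start_time < chrom$time[1L] - 1e-9 ||
      end_time > chrom$time[nrow(chrom)] + 1e-9) {
    abort("Integration window lies outside the trace extent.")
  }
  inside <- chrom$time > start_time & chrom$time < end_time
  t <- c(start_time, chrom$time[inside], end_time)
  y0 <- interp_at(chrom$time, chrom$intensity, start_time)
  y1 <- interp_at(chrom$time, chrom$intensity, end_time)
  y <- c(y0, chrom$intensity[inside], y1)
  base <- y0 + (y1 - y0) * (t - start_time) / (end_time - start_time)
  resid <- y - base
  k <- which.max(resid)
  list(area = max(0, trapz(t, resid)),
       height = max(0, resid[k]),
       apex_time = t[k])
}

#' Resample a chromatogram onto a new time grid
#'
#' Linear interpolation at the grid points; points outside the source time
#' range are set to 0.
#'
#' @inheritParams detect_peak_borders
#' @param grid Strictly increasing numeric vector of times (minutes).
#' @return Numeric vector of intensities, one per grid point.
#' @export
resample_trace <- function(chrom, grid) {
  assert_chromatogram(chrom)
  if (length(grid) == 0L) abort("`grid` must be non-empty.")
  y <- stats::approx(chrom$time, chrom$intensity, xout = grid, rule = 1)$y
  y[is.na(y)] <- 0
  y
}
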