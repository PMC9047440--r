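#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline labs facet_wrap theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot per-sample RT shifts with the fitted quadratic drift curves
#'
#' The per-metabolite raw shifts against the reference sample, overlaid with
#' each sample's fitted `a rt^2 + b rt + c` drift curve (the diagnostic
#' usually inspected when alignment misbehaves).
#'
#' @param batch An `mrm_batch` from [process_batch()].
#' @return A ggplot object.
#' @export
plot_shift_models <- function(batch) {
  stopifnot(inherits(batch, "mrm_batch"))
  sh <- batch$shifts
  rng <- range(sh$expected_rt, na.rm = TRUE)
  grid <- seq(rng[1L], rng[2L], length.out = 50)
  curves <- list_rbind(map(seq_len(nrow(batch$shift_models)), function(i) {
    m <- batch$shift_models[i, ]
    tibble(sample_id = m$sample_id, expected_rt = grid,
           fitted = m$a * grid^2 + m$b * grid + m$c)
  }))
  ggplot(sh, aes(x = .data$expected_rt)) +
    geom_point(aes(y = .data$raw_shift), size = 0.8, alpha = 0.6) +
    geom_line(data = curves, aes(y = .data$fitted), colour = "steelblue") +
    facet_wrap(~sample_id) +
    labs(x = "expected RT [min]", y = "shift vs reference [min]",
         title = "RT drift per sample (points: raw, line: quadratic fit)") +
    theme_minimal()
}

#' Plot a prototype chromatogram with its best peak
#'
#' @param batch An `mrm_batch`.
#' @param metabolite Metabolite name.
#' @return A ggplot object.
#' @export
plot_prototype <- function(batch, metabolite) {
  stopifnot(inherits(batch, "mrm_batch"))
  proto <- batch$prototypes[[metabolite]]
  if (is.null(proto) || length(proto$grid) == 0L) {
    abort(sprintf("No prototype available for %s.", metabolite))
  }
  d <- list_rbind(map(names(proto$summed), function(rl) {
    y <- proto$summed[[rl]]
    tibble(role = rl, time = proto$grid, intensity = y)
  }))
  p <- ggplot(d, aes(x = .data$time, y = .data$intensity, colour = .data$role)) +
    geom_line() +
    labs(x = "RT [min]", y = "summed intensity [counts]",
         title = sprintf("Prototype chromatogram: %s", metabolite)) +
    theme_minimal()
  if (!is.null(proto$best_peak)) {
    p <- p + geom_vline(xintercept = c(proto$best_peak$start_time,
                                       proto$best_peak$end_time),
                        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Autoplot methods
#'
#' `autoplot.mrm_batch` draws the shift diagnostic (`type = "shifts"`) or a
#' prototype chromatogram (`type = "prototype"`, needs `metabolite`);
#' `autoplot.mrm_classifier` draws the feature-importance profile of a
#' tree-based model.
#'
#' @param object An `mrm_batch` or `mrm_classifier`.
#' @param type For batches: `"shifts"` or `"prototype"`.
#' @param metabolite Metabolite name for `type = "prototype"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrm_batch <- function(object, type = c("shifts", "prototype"),
                               metabolite = NULL, ...) {
  type <- match.arg(type)
  if (type == "shifts") return(plot_shift_models(object))
  if (is.null(metabolite)) abort("`metabolite` is required for type = 'prototype'.")
  plot_prototype(object, metabolite)
}

#' @rdname autoplot.mrm_batch
#' @export
autoplot.mrm_classifier <- function(object, ...) {
  imp <- feature_importance(object)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot(imp, aes(x = .data$feature, y = .data$importance)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "relative importance",
         title = sprintf("Feature importance (%s model)", object$task)) +
    theme_minimal()
}
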