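#' Confusion counts for reported peaks against a truth table
#'
#' Each metabolite/sample cell is classified: a correct peak exists and the
#' reported peak's apex falls inside the truth borders (TP); no correct peak
#' exists and nothing was reported (TN); something was reported but either no
#' correct peak exists or the apex lies outside the truth borders (FP); a
#' correct peak exists but nothing was reported (FN). Counts always sum to
#' the number of cells.
#'
#' @param reported Tibble with `metabolite`, `sample_id`, `reported`
#'   (logical) and `apex_time`; the `peaks` table of an `mrm_batch` fits
#'   directly.
#' @param truth Tibble with `metabolite`, `sample_id`, `present`,
#'   `true_start`, `true_end` (the generator truth table fits directly).
#' @return Named list of class `mrm_confusion` with `tp`, `tn`, `fp`, `fn`.
#' @export
classify_outputs <- function(reported, truth) {
  key_r <- paste(reported$metabolite, reported$sample_id)
  key_t <- paste(truth$metabolite, truth$sample_id)
  if (!setequal(key_r, key_t) || length(key_r) != length(key_t)) {
    abort("`reported` and `truth` must cover the same (metabolite, sample) cells.")
  }
  idx <- match(key_t, key_r)
  rep_flag <- reported$reported[idx] %in% TRUE
  apex <- reported$apex_time[idx]
  present <- truth$present %in% TRUE
  inside <- is.finite(apex) & present &
    apex >= truth$true_start & apex <= truth$true_end
  tp <- sum(rep_flag & inside)
  fp <- sum(rep_flag & !inside)
  fn <- sum(!rep_flag & present)
  tn <- sum(!rep_flag & !present)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "mrm_confusion")
}

#' Accuracy and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / total`; `specificity = TN / (TN + FP)` (the
#' fraction of truly absent peaks correctly left unreported), both rounded
#' to 3 decimals. Specificity is `NA` when no negatives exist.
#'
#' @param counts An `mrm_confusion` list or anything with elements
#'   `tp`, `tn`, `fp`, `fn`.
#' @return Tibble with one row: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `specificity`, `f1`.
#' @examples
#' confusion_metrics(list(tp = 887, tn = 530, fp = 1, fn = 70))
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) abort("Confusion counts are all zero.")
  spec <- if (tn + fp > 0) round(tn / (tn + fp), 3) else NA_real_
  f1 <- if (tp + fp == 0 && tp + fn == 0) NA_real_ else f1_score(tp, fp, fn)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = round((tp + tn) / total, 3),
         specificity = spec, f1 = f1)
}

#' Mean relative standard deviation among replicate groups
#'
#' For every metabolite, the relative SD (sample SD over mean) of the peak
#' areas within each replicate group is computed and averaged over groups.
#' Groups contribute only when at least two members carry a value.
#'
#' @param areas Tibble with `metabolite`, `sample_id`, `area`.
#' @param groups Named character vector or tibble (`sample_id`, `group`)
#'   mapping samples to replicate groups.
#' @return Tibble with `metabolite`, `mean_rsd`, `n_groups` (usable groups);
#'   metabolites without any usable group get `NA`.
#' @export
replicate_sd <- function(areas, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)
  }
  areas$group <- groups[areas$sample_id]
  areas |>
    filter(!is.na(.data$group)) |>
    group_by(.data$metabolite, .data$group) |>
    summarise(n = sum(is.finite(.data$area)),
              rsd = ifelse(.data$n[1L] >= 2L && mean(.data$area, na.rm = TRUE) > 0,
                           stats::sd(.data$area, na.rm = TRUE) /
                             mean(.data$area, na.rm = TRUE), NA_real_),
              .groups = "drop") |>
    group_by(.data$metabolite) |>
    summarise(mean_rsd = if (any(is.finite(.data$rsd)))
                mean(.data$rsd[is.finite(.data$rsd)]) else NA_real_,
              n_groups = sum(is.finite(.data$rsd)), .groups = "drop")
}

#' Pearson correlation of reported intensities against reference values
#'
#' Correlation over the pairs where a value was reported; when nothing is
#' reported the correlation is defined as 0 (the convention used to flag
#' metabolites filtered out entirely). With fewer than 3 reporting pairs the
#' value is flagged unreliable.
#'
#' @param ours Numeric vector of reported intensities (`NA` = not reported).
#' @param reference Numeric vector of reference intensities, same length.
#' @return Tibble with `r`, `n_pairs`, `reliable`.
#' @export
correlate_to_reference <- function(ours, reference) {
  stopifnot(length(ours) == length(reference))
  ok <- is.finite(ours) & is.finite(reference)
  if (!any(ok)) return(tibble(r = 0, n_pairs = 0L, reliable = FALSE))
  n <- sum(ok)
  r <- if (n >= 2L && stats::sd(ours[ok]) > 0 && stats::sd(reference[ok]) > 0) {
    stats::cor(ours[ok], reference[ok])
  } else 0
  tibble(r = r, n_pairs = n, reliable = n >= 3L)
}

#' @export
print.mrm_confusion <- function(x, ...) {
  cat(sprintf("<confusion: TP %d | TN %d | FP %d | FN %d>\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
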