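#' Process one MRM batch end to end
#'
#' Runs the full preprocessing chain: initial candidate picking with quality
#' scores and classification per metabolite per sample, reference-sample
#' selection, two-pass RT-shift estimation with a quadratic drift model,
#' prototype (summed) chromatogram peak picking, border propagation and
#' per-sample integration, reporting-feature assembly, and the reporting
#' gate. Without trained models the mean of the 20 quality scores serves as
#' the classification score for both stages.
#'
#' Per-metabolite failures are contained: the affected cells stay empty and
#' the batch continues. The result's `log` records the stages in order with
#' the counts they produced.
#'
#' @param chroms Batch chromatograms: a tibble (`sample_id`, `metabolite`,
#'   `role`, `chromatogram` list-column) or an `mrm_sim_batch` from
#'   [generate_batch()].
#' @param metabolites Metabolite definition tibble; taken from the batch
#'   object when `chroms` is an `mrm_sim_batch`.
#' @param params [proc_params()] list.
#' @param picking_model,reporting_model Optional `mrm_classifier` objects;
#'   `NULL` selects the quality-score-average fallback.
#' @return Object of class `mrm_batch` with elements `peaks` (one row per
#'   metabolite per sample), `candidates` (initial scored candidates, the
#'   qslog analogue), `features` (reporting features per cell),
#'   `shift_models`, `shifts`, `prototypes`, `reference_sample`,
#'   `sample_ids`, `metabolites`, `params`, `log`.
#' @export
process_batch <- function(chroms, metabolites = NULL, params = proc_params(),
                          picking_model = NULL, reporting_model = NULL) {
  if (inherits(chroms, "mrm_sim_batch")) {
    metabolites <- metabolites %||% chroms$metabolites
    chroms <- chroms$chromatograms
  }
  if (is.null(metabolites) || nrow(metabolites) == 0L) abort("No metabolites defined.")
  if (is.null(chroms) || nrow(chroms) == 0L) abort("No chromatograms in the batch.")
  sample_ids <- unique(chroms$sample_id)
  log <- list()
  note <- function(stage, detail) log[[length(log) + 1L]] <<- tibble(stage = stage, detail = detail)
  note("parse", sprintf("%d samples, %d metabolites, %d traces",
                        length(sample_ids), nrow(metabolites), nrow(chroms)))

  pick_fun <- if (is.null(picking_model)) fallback_score else function(qs) predict_score(picking_model, qs)

  # -- stage 1: initial candidate picking + scoring --------------------------
  cand_rows <- list()
  for (s in sample_ids) {
    for (i in seq_len(nrow(metabolites))) {
      met <- metabolites[i, ]
      tr <- trace_list(chroms, s, met$metabolite)
      if (is.null(tr$quantifier)) next
      cand <- tryCatch(
        find_peak_candidates(tr$quantifier, n_candidates = params$n_candidates,
                             smoothing_width = params$smoothing_width,
                             border_frac = params$border_frac),
        error = function(e) {
          warn(sprintf("Candidate search failed for %s/%s: %s", met$metabolite,
                       s, conditionMessage(e)))
          NULL
        })
      if (is.null(cand) || nrow(cand) == 0L) next
      qs <- list_rbind(map(seq_len(nrow(cand)), function(k) {
        as_tibble(as.list(compute_quality_scores(cand[k, ], tr,
                                                 expected_rt = met$expected_rt,
                                                 expected_ratio = met$expected_ratio,
                                                 predicted_shift = 0,
                                                 params = params)))
      }))
      cand <- dplyr::bind_cols(
        tibble(metabolite = met$metabolite, sample_id = s), cand, qs)
      cand$score <- pick_fun(qs)
      cand_rows[[length(cand_rows) + 1L]] <- cand
    }
  }
  candidates <- if (length(cand_rows)) list_rbind(cand_rows) else tibble()
  note("initial_picking", sprintf("%d candidates scored", nrow(candidates)))
  if (nrow(candidates) == 0L) abort("No peak candidates found anywhere in the batch.")

  best_initial <- candidates |>
    group_by(.data$sample_id, .data$metabolite) |>
    summarise(score = max(.data$score), .groups = "drop")

  # -- stage 2: reference selection ------------------------------------------
  ref_id <- select_reference_sample(best_initial, sample_ids,
                                    metabolites$metabolite)
  note("reference_selection", ref_id)

  # -- stage 3: two-pass shift estimation + quadratic drift model ------------
  align <- estimate_shift_models(chroms, metabolites, ref_id, params)
  note("rt_alignment", sprintf("%d raw shifts, %d sample models",
                               sum(is.finite(align$shifts$raw_shift)),
                               nrow(align$models)))

  # -- stage 4: prototype build + best-peak selection ------------------------
  prototypes <- list()
  for (i in seq_len(nrow(metabolites))) {
    met <- metabolites[i, ]
    prototypes[[met$metabolite]] <- tryCatch(
      build_prototype(chroms, met, align$shifts, ref_id, params, pick_fun),
      error = function(e) {
        warn(sprintf("Prototype failed for %s: %s", met$metabolite, conditionMessage(e)))
        empty_prototype(met$metabolite)
      })
  }
  n_proto <- sum(!vapply(prototypes, function(p) is.null(p$best_peak), logical(1)))
  note("prototype_picking", sprintf("%d/%d prototypes with a best peak",
                                    n_proto, nrow(metabolites)))

  # -- stage 5: border propagation + integration + per-sample QS -------------
  peak_rows <- list()
  feat_ctx <- list()
  for (i in seq_len(nrow(metabolites))) {
    met <- metabolites[i, ]
    proto <- prototypes[[met$metabolite]]
    sh <- align$shifts[align$shifts$metabolite == met$metabolite, ]
    for (s in sample_ids) {
      tr <- trace_list(chroms, s, met$metabolite)
      fitted <- sh$fitted_shift[sh$sample_id == s]
      fitted <- if (length(fitted) && is.finite(fitted[1L])) fitted[1L] else 0
      row <- tibble(metabolite = met$metabolite, sample_id = s,
                    apex_time = NA_real_, start_time = NA_real_,
                    end_time = NA_real_, area = NA_real_, height = NA_real_,
                    area_istd = NA_real_, height_istd = NA_real_,
                    output_h = NA_real_, fitted_shift = fitted)
      qs <- NULL
      if (!is.null(proto$best_peak) && !is.null(tr$quantifier)) {
        b <- suppressWarnings(propagate_borders(proto, fitted, tr$quantifier))
        if (!is.null(b) && b[["start_time"]] < b[["end_time"]]) {
          ih <- tryCatch(integrate_peak(tr$quantifier, b[["start_time"]], b[["end_time"]]),
                         error = function(e) NULL)
          if (!is.null(ih)) {
            row$apex_time <- ih$apex_time
            row$start_time <- b[["start_time"]]
            row$end_time <- b[["end_time"]]
            row$area <- ih$area
            row$height <- ih$height
            if (!is.null(tr$istd)) {
              is_rng <- range(tr$istd$time)
              is_st <- max(b[["start_time"]], is_rng[1L])
              is_en <- min(b[["end_time"]], is_rng[2L])
              ii <- tryCatch(integrate_peak(tr$istd, is_st, is_en),
                             error = function(e) NULL)
              if (!is.null(ii)) {
                row$area_istd <- normalize_to_istd(ih$area, ii$area)
                row$height_istd <- normalize_to_istd(ih$height, ii$height)
              }
            }
            peak <- list(apex_time = ih$apex_time, start_time = b[["start_time"]],
                         end_time = b[["end_time"]])
            qs <- compute_quality_scores(peak, tr, expected_rt = met$expected_rt,
                                         expected_ratio = met$expected_ratio,
                                         predicted_shift = fitted, params = params)
            row$output_h <- pick_fun(as_tibble(as.list(qs)))
          }
        }
      }
      peak_rows[[length(peak_rows) + 1L]] <- row
      feat_ctx[[paste(met$metabolite, s)]] <- qs
    }
  }
  peaks <- list_rbind(peak_rows)
  note("integration", sprintf("%d/%d cells integrated", sum(is.finite(peaks$area)),
                              nrow(peaks)))

  # -- stage 6: reporting features + gate ------------------------------------
  feat_rows <- list()
  for (i in seq_len(nrow(metabolites))) {
    met <- metabolites$metabolite[i]
    sel <- peaks$metabolite == met
    all_scores <- peaks$output_h[sel]
    all_scores <- all_scores[is.finite(all_scores)]
    for (s in sample_ids) {
      qs <- feat_ctx[[paste(met, s)]]
      oh <- peaks$output_h[sel & peaks$sample_id == s]
      if (is.null(qs) || !length(oh) || !is.finite(oh) || !length(all_scores)) next
      fv <- assemble_reporting_features(qs, oh, all_scores)
      feat_rows[[length(feat_rows) + 1L]] <- dplyr::bind_cols(
        tibble(metabolite = met, sample_id = s), as_tibble(as.list(fv)))
    }
  }
  features <- if (length(feat_rows)) list_rbind(feat_rows) else tibble()
  note("reporting_features", sprintf("%d feature rows", nrow(features)))

  if (nrow(features)) {
    rep_score <- if (is.null(reporting_model)) {
      fallback_score(features)
    } else {
      predict_score(reporting_model, features)
    }
    key <- paste(features$metabolite, features$sample_id)
    idx <- match(paste(peaks$metabolite, peaks$sample_id), key)
    peaks$report_score <- rep_score[idx]
  } else {
    peaks$report_score <- NA_real_
  }
  peaks$reported <- is.finite(peaks$report_score) & is.finite(peaks$area) &
    peaks$report_score >= params$report_threshold
  note("reporting_gate", sprintf("%d/%d peaks reported (threshold %.2f)",
                                 sum(peaks$reported), nrow(peaks),
                                 params$report_threshold))

  structure(list(peaks = peaks, candidates = candidates, features = features,
                 shift_models = align$models, shifts = align$shifts,
                 prototypes = prototypes, reference_sample = ref_id,
                 sample_ids = sample_ids, metabolites = metabolites,
                 params = params, log = list_rbind(log)),
            class = "mrm_batch")
}

#' Normalise a peak quantity to the \eqn{^{13}}C internal standard
#'
#' @param x Peak area (or height) of the analyte.
#' @param istd Matching quantity of the \eqn{^{13}}C-labelled internal
#'   standard over the same borders.
#' @return `x / istd`, or `NA` when the internal-standard quantity is not
#'   positive.
#' @export
normalize_to_istd <- function(x, istd) {
  if (!is.finite(istd) || istd <= 0) return(NA_real_)
  x / istd
}

#' Train the peak-picking and peak-reporting classifiers for a batch
#'
#' Stage 1 processes the batch without models, labels the initial candidates
#' against the picking solution (apex between solution start and end of a
#' present peak = correct) and trains the picking classifier. Stage 2
#' reprocesses the batch with that classifier to obtain reporting features
#' whose percentile context reflects the trained scores, labels them against
#' the reporting solution (2 = report, 0 = do not, 1 = excluded) and trains
#' the reporting classifier.
#'
#' @inheritParams process_batch
#' @param picking_solution Tibble (`metabolite`, `sample_id`, `area`,
#'   `start`, `end`).
#' @param reporting_solution Tibble (`metabolite`, `sample_id`, `value`) with
#'   values in 0/1/2, or `NULL` to train the picking model only.
#' @param algorithm,seed Passed to [train_peak_classifier()].
#' @return List with `picking` and `reporting` (`mrm_classifier` or `NULL`),
#'   the labelled example tables, and `template` (a reporting-solution
#'   skeleton with one row per metabolite per sample).
#' @export
train_models <- function(chroms, picking_solution, reporting_solution = NULL,
                         metabolites = NULL, params = proc_params(),
                         algorithm = "random_forest", seed = 1L) {
  stage1 <- process_batch(chroms, metabolites, params)
  picking_examples <- derive_picking_labels(stage1$candidates, picking_solution)
  picking <- train_peak_classifier(picking_examples, task = "picking",
                                   algorithm = algorithm, seed = seed)

  stage2 <- process_batch(chroms, metabolites, params, picking_model = picking)
  template <- tidyr::expand_grid(metabolite = stage2$metabolites$metabolite,
                                 sample_id = stage2$sample_ids)
  template$value <- NA_integer_

  reporting <- NULL
  reporting_examples <- NULL
  if (!is.null(reporting_solution)) {
    reporting_examples <- derive_reporting_labels(stage2$features, reporting_solution)
    reporting <- train_peak_classifier(reporting_examples, task = "reporting",
                                       algorithm = algorithm, seed = seed)
  }
  list(picking = picking, reporting = reporting,
       picking_examples = picking_examples,
       reporting_examples = reporting_examples,
       template = template, stage2 = stage2)
}

#' @export
print.mrm_batch <- function(x, ...) {
  cat(sprintf("<mrm_batch: %d samples x %d metabolites, reference %s>\n",
              length(x$sample_ids), nrow(x$metabolites), x$reference_sample))
  cat(sprintf("  integrated: %d | reported: %d (threshold %.2f)\n",
              sum(is.finite(x$peaks$area)), sum(x$peaks$reported),
              x$params$report_threshold))
  invisible(x)
}
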