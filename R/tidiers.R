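#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained classifier
#'
#' For tree-based models, one row per feature with its normalised
#' importance; for the other backends, one row per tuned hyperparameter.
#'
#' @param x An `mrm_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mrm_classifier <- function(x, ...) {
  if (x$algorithm %in% c("random_forest", "gradient_boosted_trees")) {
    feature_importance(x)
  } else {
    tibble(term = names(x$tuned_hyperparams),
           value = as.numeric(unlist(x$tuned_hyperparams)))
  }
}

#' @rdname tidy.mrm_classifier
#' @export
glance.mrm_classifier <- function(x, ...) {
  tibble(task = x$task, algorithm = x$algorithm,
         n_train = x$n_train, n_validation = x$n_validation,
         cv_f1 = x$cv_f1, validation_f1 = x$validation_f1,
         train_seed = x$train_seed)
}

#' Tidy a processed batch
#'
#' One row per metabolite per sample with borders, area, height,
#' internal-standard normalised values, the picking score (`output_h`), the
#' reporting score and the reported flag.
#'
#' @param x An `mrm_batch` from [process_batch()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mrm_batch <- function(x, ...) {
  as_tibble(x$peaks)
}

#' @rdname tidy.mrm_batch
#' @export
glance.mrm_batch <- function(x, ...) {
  tibble(n_samples = length(x$sample_ids),
         n_metabolites = nrow(x$metabolites),
         reference_sample = x$reference_sample,
         n_candidates = nrow(x$candidates),
         n_integrated = sum(is.finite(x$peaks$area)),
         n_reported = sum(x$peaks$reported),
         report_threshold = x$params$report_threshold)
}
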