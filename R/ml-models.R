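#' Derive peak-picking training labels from a training solution
#'
#' A candidate is a correct peak (label 1) when the solution marks the
#' metabolite/sample pair as present (area > 0) and the candidate apex lies
#' between the solution's peak start and end; all other candidates are
#' incorrect (label 0). Absent peaks are indicated by area = 0 in the
#' solution, making every candidate for that pair a negative example.
#'
#' @param candidates Tibble of scored candidates with columns `metabolite`,
#'   `sample_id`, `apex_time` and the 20 quality-score columns
#'   ([qs_names()]).
#' @param solution Tibble with columns `metabolite`, `sample_id`, `area`,
#'   `start` and `end` (one row per metabolite per sample).
#' @return The `candidates` tibble with an integer `label` column appended.
#' @export
derive_picking_labels <- function(candidates, solution) {
  key <- paste(candidates$metabolite, candidates$sample_id)
  skey <- paste(solution$metabolite, solution$sample_id)
  hit <- match(key, skey)
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    abort(sprintf("No training-solution row for: %s", paste(miss, collapse = "; ")))
  }
  area <- solution$area[hit]
  st <- solution$start[hit]
  en <- solution$end[hit]
  candidates$label <- as.integer(area > 0 & candidates$apex_time >= st &
                                   candidates$apex_time <= en)
  candidates
}

#' Derive peak-reporting training labels from a reporting solution
#'
#' Solution values: 2 = the peak should be reported (label 1), 0 = it should
#' not (label 0), 1 = do not use for training (row excluded).
#'
#' @param features Tibble with columns `metabolite`, `sample_id` and the 26
#'   reporting-feature columns ([reporting_feature_names()]).
#' @param solution Tibble with columns `metabolite`, `sample_id`, `value`
#'   where `value` is 0, 1 or 2.
#' @return `features` restricted to usable rows, with `label` appended.
#' @export
derive_reporting_labels <- function(features, solution) {
  bad <- !solution$value %in% c(0, 1, 2)
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf("Invalid reporting-solution value %s for %s / %s (row %d); must be 0, 1 or 2.",
                  solution$value[i], solution$metabolite[i], solution$sample_id[i], i))
  }
  key <- paste(features$metabolite, features$sample_id)
  skey <- paste(solution$metabolite, solution$sample_id)
  hit <- match(key, skey)
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    abort(sprintf("No reporting-solution row for: %s", paste(miss, collapse = "; ")))
  }
  val <- solution$value[hit]
  out <- features[val != 1, , drop = FALSE]
  out$label <- as.integer(val[val != 1] == 2)
  if (nrow(out) == 0L) abort("No usable training examples: all reporting-solution values are 1.")
  out
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision and recall; 0 when there are no true
#' positives.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return F1 in \[0, 1\].
#' @examples
#' f1_score(887, 1, 70)
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("Counts must be non-negative.")
  if (tp + fp == 0 && tp + fn == 0) abort("F1 undefined: no positive predictions or positives.")
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

f1_from_pred <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp + fp == 0 && tp + fn == 0) return(0)
  if (tp == 0) return(0)
  f1_score(tp, fp, fn)
}

#' Fallback classification score when no model is available
#'
#' The arithmetic mean of the 20 quality scores. Used for peak picking and
#' reporting alike when no trained classifier is supplied.
#'
#' @param qs A named numeric vector of the 20 quality scores, or a data
#'   frame/matrix with the [qs_names()] columns (one row per candidate).
#' @return Numeric score(s) in \[0, 1\].
#' @export
fallback_score <- function(qs) {
  if (is.data.frame(qs) || is.matrix(qs)) {
    m <- as.matrix(as.data.frame(qs)[, qs_names(), drop = FALSE])
    return(rowMeans(m))
  }
  mean(qs[qs_names()])
}

# -- training ----------------------------------------------------------------

# stratified index split: returns indices of the held-out part
stratified_holdout <- function(labels, frac, seed) {
  idx <- withr::with_seed(seed, {
    unlist(lapply(unique(labels), function(l) {
      i <- which(labels == l)
      sample(i, size = max(1L, round(length(i) * frac)))
    }))
  })
  sort(idx)
}

stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (l in unique(labels)) {
      i <- sample(which(labels == l))
      fold[i] <- rep_len(seq_len(k), length(i))
    }
    fold
  })
}

hyper_grids <- function(algorithm) {
  switch(algorithm,
    random_forest = expand.grid(num_trees = c(200L, 500L), mtry_frac = c(0.3, 0.6)),
    gradient_boosted_trees = expand.grid(nrounds = c(100L, 200L), max_depth = c(3L, 6L)),
    svm = expand.grid(cost = c(0.1, 1, 10)),
    neural_net = expand.grid(size = c(8L, 32L), decay = c(1e-4, 1e-2)),
    abort(sprintf("Unknown algorithm '%s'.", algorithm))
  )
}

fit_one <- function(algorithm, x, y, hp, seed) {
  switch(algorithm,
    random_forest = {
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     num.trees = hp$num_trees,
                     mtry = max(1L, floor(hp$mtry_frac * ncol(x))),
                     probability = TRUE, importance = "impurity",
                     seed = seed, num.threads = 1L)
    },
    gradient_boosted_trees = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        abort("Package 'xgboost' is required for gradient_boosted_trees.")
      }
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = 0.3, nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1L),
        nrounds = hp$nrounds, verbose = 0)
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        abort("Package 'e1071' is required for svm.")
      }
      withr::with_seed(seed,
        e1071::svm(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                   kernel = "radial", cost = hp$cost, probability = TRUE))
    },
    neural_net = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        abort("Package 'nnet' is required for neural_net.")
      }
      withr::with_seed(seed,
        nnet::nnet(x = as.matrix(x), y = y, size = hp$size, decay = hp$decay,
                   maxit = 300, entropy = TRUE, trace = FALSE))
    }
  )
}

predict_prob <- function(algorithm, fit, x) {
  x <- as.matrix(x)
  p <- switch(algorithm,
    random_forest = stats::predict(fit, data = as.data.frame(x),
                                   num.threads = 1L)$predictions[, "1"],
    gradient_boosted_trees = stats::predict(fit, x),
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    neural_net = as.numeric(stats::predict(fit, x))
  )
  pmin(1, pmax(0, as.numeric(p)))
}

#' Train a peak-picking or peak-reporting classifier
#'
#' The labelled examples are split stratified by label into 80% training and
#' 20% validation. A small fixed hyperparameter grid is searched by 3-fold
#' cross-validated F1 on the training split; the best configuration is
#' refitted on the full training split and its F1 evaluated once on the
#' held-out 20%.
#'
#' @param examples Tibble with a `label` column (0/1) and the feature columns
#'   for the task (20 quality scores for picking, 26 reporting features for
#'   reporting).
#' @param task `"picking"` or `"reporting"`; fixes the expected feature set.
#' @param algorithm One of `"random_forest"` (default),
#'   `"gradient_boosted_trees"`, `"svm"`, `"neural_net"`.
#' @param seed Integer seed controlling the split, the folds and the fit.
#' @return An object of class `mrm_classifier` with the fitted model, the
#'   ordered feature names, the tuned hyperparameters and `validation_f1`.
#' @export
train_peak_classifier <- function(examples, task = c("picking", "reporting"),
                                  algorithm = c("random_forest",
                                                "gradient_boosted_trees",
                                                "svm", "neural_net"),
                                  seed = 1L) {
  task <- match.arg(task)
  algorithm <- match.arg(algorithm)
  feats <- if (task == "picking") qs_names() else reporting_feature_names()
  missing_cols <- setdiff(c(feats, "label"), names(examples))
  if (length(missing_cols)) {
    abort(sprintf("Missing feature column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  y <- as.integer(examples$label)
  if (length(y) < 20L) abort("Need at least 20 labelled examples.")
  if (length(unique(y)) < 2L) abort("Training requires both classes to be present.")
  x <- as.data.frame(examples[, feats, drop = FALSE])

  hold <- stratified_holdout(y, 0.2, seed)
  x_tr <- x[-hold, , drop = FALSE]; y_tr <- y[-hold]
  x_va <- x[hold, , drop = FALSE]; y_va <- y[hold]

  grid <- hyper_grids(algorithm)
  fold <- stratified_folds(y_tr, 3L, seed + 1L)
  cv_f1 <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- grid[g, , drop = FALSE]
    mean(vapply(1:3, function(k) {
      tr <- fold != k
      fit <- fit_one(algorithm, x_tr[tr, , drop = FALSE], y_tr[tr], hp, seed + k)
      p <- predict_prob(algorithm, fit, x_tr[!tr, , drop = FALSE])
      f1_from_pred(y_tr[!tr], as.integer(p >= 0.5))
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_f1)
  hp <- grid[best, , drop = FALSE]
  fit <- fit_one(algorithm, x_tr, y_tr, hp, seed)
  val_f1 <- f1_from_pred(y_va, as.integer(predict_prob(algorithm, fit, x_va) >= 0.5))

  structure(list(task = task, algorithm = algorithm, fit = fit,
                 feature_names = feats, tuned_hyperparams = as.list(hp),
                 cv_f1 = cv_f1[best], validation_f1 = val_f1,
                 n_train = nrow(x_tr), n_validation = nrow(x_va),
                 train_seed = as.integer(seed)),
            class = "mrm_classifier")
}

#' Classification score of candidates under a trained model
#'
#' Returns the class-1 probability for each row; SVM decision values are
#' mapped to probabilities by the model's internal calibration so all
#' backends produce scores in \[0, 1\].
#'
#' @param model An `mrm_classifier` from [train_peak_classifier()].
#' @param features Data frame/matrix containing the model's feature columns,
#'   or a named numeric vector for a single candidate.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_score <- function(model, features) {
  stopifnot(inherits(model, "mrm_classifier"))
  if (is.numeric(features) && !is.matrix(features)) {
    features <- as.data.frame(as.list(features))
  }
  features <- as.data.frame(features)
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols)) {
    abort(sprintf("Feature mismatch; missing: %s", paste(missing_cols, collapse = ", ")))
  }
  predict_prob(model$algorithm, model$fit,
               features[, model$feature_names, drop = FALSE])
}

#' Impurity-based feature importances of a tree model
#'
#' Normalised to sum to 1 and sorted descending. Only defined for the
#' tree-based backends (random forest, gradient boosted trees).
#'
#' @inheritParams predict_score
#' @return Tibble with columns `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "mrm_classifier"))
  imp <- switch(model$algorithm,
    random_forest = ranger::importance(model$fit),
    gradient_boosted_trees = {
      tb <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(tb$Gain, tb$Feature)
    },
    abort(sprintf("Feature importance is not defined for algorithm '%s'.", model$algorithm))
  )
  full <- stats::setNames(numeric(length(model$feature_names)), model$feature_names)
  full[names(imp)] <- imp
  if (sum(full) > 0) full <- full / sum(full)
  out <- tibble(feature = names(full), importance = unname(full))
  out[order(-out$importance), ]
}

#' Save / load a trained classifier
#'
#' The artifact embeds the feature schema, tuned hyperparameters, seed and
#' validation metrics, so a reloaded model verifiably matches its features.
#'
#' @param model An `mrm_classifier`.
#' @param path File path (`.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the `mrm_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "mrm_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mrm_classifier")) abort("File does not contain an mrm_classifier.")
  model
}

#' @export
print.mrm_classifier <- function(x, ...) {
  cat(sprintf("<mrm_classifier: %s / %s>\n", x$task, x$algorithm))
  cat(sprintf("  features: %d | train: %d | validation: %d\n",
              length(x$feature_names), x$n_train, x$n_validation))
  cat(sprintf("  validation F1: %.4f (CV F1 %.4f, seed %d)\n",
              x$validation_f1, x$cv_f1, x$train_seed))
  invisible(x)
}
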