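#' Run the deletion-detection pipeline end to end
#'
#' QC cascade, predictor computation, classifier training (at the shipped
#' default hyper-parameters or after a fresh grid search), deletion
#' calling for every qualified pair, and merging into intervals.
#'
#' @param dm raw [depth_matrix()].
#' @param catalog an [sts_catalog()].
#' @param training a [training_set()] built on features from THIS matrix
#'   (use [compute_features()] on the QC output, e.g. via
#'   [make_training_subset()] for simulated cohorts), or `NULL` to train
#'   later.
#' @param qc a [qc_params()].
#' @param merge a [merge_params()].
#' @param C,sigma classifier hyper-parameters (default: the shipped
#'   operating point `C = 2^9`, `sigma = 2^3`).
#' @param grid_search optional [svm_config()]; when supplied, `C` and
#'   `sigma` are selected by cross-validated grid search on `training`
#'   instead.
#' @param f1_mode first-predictor convention, see [compute_features()].
#' @return list with `qc` (matrix + report), `features`, `model`, `calls`,
#'   `intervals`, and `search` (grid-search result or `NULL`).
#' @export
run_pipeline <- function(dm, catalog, training,
                         qc = qc_params(), merge = merge_params(),
                         C = svm_defaults()$C, sigma = svm_defaults()$sigma,
                         grid_search = NULL, f1_mode = "density") {
  qc_res <- run_qc(dm, qc)
  features <- compute_features(qc_res$matrix, f1_mode = f1_mode)
  search <- NULL
  if (!is.null(grid_search)) {
    search <- grid_search_cv(training, grid_search)
    C <- search$best_C
    sigma <- search$best_sigma
  }
  model <- train_classifier(training, C = C, sigma = sigma,
                            f1_mode = f1_mode)
  calls <- classify(model, features, dm = qc_res$matrix)
  intervals <- merge_calls(calls, catalog, merge)
  list(qc = qc_res, features = features, model = model, calls = calls,
       intervals = intervals, search = search)
}

#' Confusion summary of calls against truth labels
#'
#' @param calls a `call_matrix`.
#' @param truth logical sample x STS matrix (e.g. from
#'   [simulate_cohort()]); only pairs present in `calls` with state
#'   `deleted`/`not_deleted` are scored.
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `fn`, `tn`.
#' @export
call_accuracy <- function(calls, truth) {
  ev <- calls[calls$state %in% c("deleted", "not_deleted"), ]
  tr <- truth[cbind(ev$sample_id, ev$sts_id)]
  pred <- ev$state == "deleted"
  tp <- sum(pred & tr); fp <- sum(pred & !tr)
  fn <- sum(!pred & tr); tn <- sum(!pred & !tr)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
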