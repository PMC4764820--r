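FEATURE_COLS <- c("f1", "f2", "f3")

#' Assemble a training set
#'
#' Labeled deletion events for the SVM: one row per (sample, STS) pair with
#' the three predictors and a logical `deleted` label (in the published
#' workflow these labels come from PCR validation of 134 events).
#'
#' @param features a [compute_features()] result (or any data frame with
#'   `sample_id`, `sts_id`, `f1`, `f2`, `f3`).
#' @param labels data frame with `sample_id`, `sts_id`, `deleted`
#'   (logical).
#' @return a `training_set` data frame.
#' @export
training_set <- function(features, labels) {
  stopifnot(all(c("sample_id", "sts_id", "deleted") %in% names(labels)))
  key_f <- paste(features$sample_id, features$sts_id)
  key_l <- paste(labels$sample_id, labels$sts_id)
  if (anyDuplicated(key_l)) {
    ycm_stop("duplicate (sample, STS) pairs in labels", "ycm_validation_error")
  }
  idx <- match(key_l, key_f)
  if (any(is.na(idx))) {
    ycm_stop(sprintf("labeled pair(s) missing from feature matrix: %s",
                     paste(head(key_l[is.na(idx)], 5), collapse = "; ")),
             "ycm_validation_error")
  }
  out <- cbind(labels[, c("sample_id", "sts_id")],
               features[idx, FEATURE_COLS],
               deleted = as.logical(labels$deleted))
  rownames(out) <- NULL
  if (length(unique(out$deleted)) < 2) {
    ycm_stop("training set must contain both classes", "ycm_validation_error")
  }
  if (any(!is.finite(as.matrix(out[, FEATURE_COLS])))) {
    bad <- which(!stats::complete.cases(out[, FEATURE_COLS]))[1]
    ycm_stop(sprintf("non-finite feature for pair (%s, %s)",
                     out$sample_id[bad], out$sts_id[bad]),
             "ycm_validation_error")
  }
  class(out) <- c("training_set", "data.frame")
  out
}

#' SVM configuration
#'
#' Hyper-parameter search space and cross-validation layout for the
#' deletion classifier: exponentially growing `C` and `sigma` grids
#' (powers of two from 2^-5 to 2^15), 4-fold stratified cross-validation
#' repeated 1000 times. The shipped default operating point, used when no
#' grid search is run, is `C = 2^9`, `sigma = 2^3` (the combination
#' selected by the published search).
#'
#' @param C_grid candidate soft-margin costs.
#' @param sigma_grid candidate RBF bandwidths (kernel
#'   `exp(-||x-y||^2 / (2 sigma^2))`).
#' @param cv_folds folds per repetition (>= 2).
#' @param cv_repetitions number of repetitions.
#' @param seed integer seed driving fold assignment.
#' @return an `svm_config` list.
#' @export
svm_config <- function(C_grid = 2^(-5:15), sigma_grid = 2^(-5:15),
                       cv_folds = 4, cv_repetitions = 1000, seed = 1L) {
  stopifnot(length(C_grid) > 0, length(sigma_grid) > 0, cv_folds >= 2,
            cv_repetitions >= 1)
  structure(list(C_grid = C_grid, sigma_grid = sigma_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_repetitions = as.integer(cv_repetitions),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Shipped default hyper-parameters
#' @return list with elements `C` (2^9) and `sigma` (2^3).
#' @export
svm_defaults <- function() list(C = 2^9, sigma = 2^3)

train_xy <- function(train) {
  list(X = as.matrix(train[, FEATURE_COLS]),
       y = ifelse(train$deleted, 1L, -1L))
}

#' Cross-validated grid search for (C, sigma)
#'
#' For every grid cell, the mean CV concordance — the fraction of held-out
#' events whose predicted state matches the label — over
#' `cv_repetitions` repetitions of stratified `cv_folds`-fold
#' cross-validation. The argmax is returned with deterministic
#' tie-breaking: smallest `C`, then smallest `sigma` (prefer the least
#' complex boundary). Features are used as-is, without rescaling, so
#' `sigma` retains its meaning on the predictor scale.
#'
#' @param train a [training_set()].
#' @param config an [svm_config()].
#' @return list with `best_C`, `best_sigma`, `best_concordance` and
#'   `concordance` (matrix, rows = C, columns = sigma).
#' @export
grid_search_cv <- function(train, config = svm_config()) {
  stopifnot(inherits(train, "training_set"), inherits(config, "svm_config"))
  xy <- train_xy(train)
  set.seed(config$seed)
  conc <- cpp_grid_cv(xy$X, xy$y, config$C_grid, config$sigma_grid,
                      config$cv_folds, config$cv_repetitions)
  dimnames(conc) <- list(C = vapply(config$C_grid, format, ""),
                         sigma = vapply(config$sigma_grid, format, ""))
  best <- max(conc)
  # ties broken by smallest C then smallest sigma: scan in C-major order
  hit <- which(conc >= best - 1e-12, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  list(best_C = config$C_grid[hit[1, 1]],
       best_sigma = config$sigma_grid[hit[1, 2]],
       best_concordance = best,
       concordance = conc)
}

#' Train the RBF-kernel SVM deletion classifier
#'
#' Fits a soft-margin SVM with Gaussian kernel
#' `K(x, y) = exp(-||x-y||^2 / (2 sigma^2))` on all training events and
#' reports resubstitution accuracy.
#'
#' @param train a [training_set()].
#' @param C soft-margin cost.
#' @param sigma RBF bandwidth.
#' @param f1_mode feature convention recorded in the model (must match the
#'   features later classified).
#' @param seed seed recorded in provenance.
#' @return a `ycm_svm` classifier object.
#' @export
train_classifier <- function(train, C = svm_defaults()$C,
                             sigma = svm_defaults()$sigma,
                             f1_mode = "density", seed = NA_integer_) {
  stopifnot(inherits(train, "training_set"))
  xy <- train_xy(train)
  fit <- cpp_svm_train(xy$X, xy$y, C, sigma)
  sv <- fit$alpha > 1e-8
  model <- structure(list(
    X_sv = xy$X[sv, , drop = FALSE],
    coef = fit$alpha[sv] * xy$y[sv],
    b = fit$b,
    C = C, sigma = sigma,
    feature_names = FEATURE_COLS,
    f1_mode = f1_mode,
    seed = seed,
    n_train = nrow(xy$X)
  ), class = "ycm_svm")
  pred <- svm_decision(model, xy$X) >= 0
  model$resub_accuracy <- mean(pred == (xy$y > 0))
  model
}

svm_decision <- function(model, X) {
  stopifnot(inherits(model, "ycm_svm"))
  cpp_svm_decision(model$X_sv, model$coef, model$b, model$sigma,
                   as.matrix(X))
}

#' Call deletion states for all pairs
#'
#' Applies a trained classifier to a feature matrix and labels every
#' qualified (sample, STS) pair `deleted` or `not_deleted`. Pairs present
#' in the qualified depth matrix but absent from the feature matrix
#' (degenerate zero-variance STSs) are labeled `not_evaluated` when `dm`
#' is supplied.
#'
#' @param model a [train_classifier()] result.
#' @param features a [compute_features()] result from the same QC pipeline
#'   and `f1_mode` as the training features.
#' @param dm optional qualified [depth_matrix()] defining the full pair
#'   universe.
#' @return a `call_matrix` data frame: `sample_id`, `sts_id`, `state`.
#' @export
classify <- function(model, features, dm = NULL) {
  stopifnot(inherits(model, "ycm_svm"))
  if (!all(model$feature_names %in% names(features))) {
    ycm_stop("feature columns do not match the training features",
             "ycm_contract_error")
  }
  fmode <- attr(features, "f1_mode")
  if (!is.null(fmode) && !identical(fmode, model$f1_mode)) {
    ycm_stop(sprintf("classifier was trained with f1_mode='%s' but features use '%s'",
                     model$f1_mode, fmode), "ycm_contract_error")
  }
  dec <- svm_decision(model, features[, model$feature_names])
  out <- data.frame(sample_id = features$sample_id,
                    sts_id = features$sts_id,
                    state = ifelse(dec >= 0, "deleted", "not_deleted"),
                    stringsAsFactors = FALSE)
  if (!is.null(dm)) {
    all_pairs <- expand.grid(sample_id = sample_ids(dm), sts_id = sts_ids(dm),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key_all <- paste(all_pairs$sample_id, all_pairs$sts_id)
    key_out <- paste(out$sample_id, out$sts_id)
    missing <- all_pairs[!(key_all %in% key_out), , drop = FALSE]
    if (nrow(missing) > 0) {
      missing$state <- "not_evaluated"
      out <- rbind(out, missing)
    }
  }
  out <- out[order(out$sample_id, out$sts_id), ]
  rownames(out) <- NULL
  class(out) <- c("call_matrix", "data.frame")
  out
}

#' Write / read the classifier artifact
#'
#' Self-describing JSON storing support vectors, coefficients, intercept,
#' hyper-parameters, seed and the feature conventions.
#'
#' @param model a `ycm_svm`.
#' @param path file path.
#' @return `path` (write) or a `ycm_svm` (read).
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "ycm_svm"))
  payload <- unclass(model)
  payload$X_sv <- as.data.frame(payload$X_sv)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$X_sv <- as.matrix(payload$X_sv)
  colnames(payload$X_sv) <- payload$feature_names
  structure(payload, class = "ycm_svm")
}

#' Write a call matrix to TSV
#' @param calls a `call_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a call matrix from TSV
#' @param path input path.
#' @return a `call_matrix` data frame.
#' @export
read_calls <- function(path) {
  out <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "sts_id", "state") %in% names(out)))
  class(out) <- c("call_matrix", "data.frame")
  out
}

#' @export
print.ycm_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM deletion classifier: %d SVs / %d events, C=%g, sigma=%g, resubstitution accuracy %.3f\n",
              nrow(x$X_sv), x$n_train, x$C, x$sigma, x$resub_accuracy))
  invisible(x)
}

deleted_ids_by_sample <- function(calls) {
  del <- calls[calls$state == "deleted", , drop = FALSE]
  split(del$sts_id, del$sample_id)
}
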