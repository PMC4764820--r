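#' QC parameters
#'
#' Tunables for the depth-matrix quality-control cascade. Defaults are the
#' published operating point: outliers beyond 1.5x the interquartile range,
#' a 15x cutoff on raw per-STS median depth, and exclusion of samples whose
#' normalized-depth standard deviation exceeds 0.7.
#'
#' @param iqr_multiplier multiplier k in the \[Q1 - k IQR, Q3 + k IQR\]
#'   fences (dimensionless, default 1.5).
#' @param median_depth_cutoff minimum raw median depth (reads) an STS must
#'   reach across remaining samples (default 15; an STS at exactly the
#'   cutoff is kept).
#' @param sd_cutoff maximum standard deviation of normalized depth a sample
#'   may show (default 0.7; a sample at exactly the cutoff is kept).
#' @param iqr_stat whether the IQR rule screens per-sample/per-STS `"mean"`
#'   depth (default) or `"median"` depth.
#' @return a `qc_params` list.
#' @export
qc_params <- function(iqr_multiplier = 1.5, median_depth_cutoff = 15,
                      sd_cutoff = 0.7, iqr_stat = c("mean", "median")) {
  iqr_stat <- match.arg(iqr_stat)
  stopifnot(iqr_multiplier > 0, median_depth_cutoff > 0, sd_cutoff > 0)
  structure(list(iqr_multiplier = iqr_multiplier,
                 median_depth_cutoff = median_depth_cutoff,
                 sd_cutoff = sd_cutoff,
                 iqr_stat = iqr_stat),
            class = "qc_params")
}

iqr_fences <- function(x, k) {
  # type-7 quantiles (linear interpolation), the common default
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' IQR outlier filter on samples and STSs
#'
#' Screens per-sample and per-STS summary depths (mean by default) against
#' Tukey fences \[Q1 - k IQR, Q3 + k IQR\] of the respective distribution.
#' Both outlier sets are computed on the initial matrix and then removed
#' jointly (one stage, not sequentially). Values exactly on a fence are
#' kept.
#'
#' @param dm raw [depth_matrix()].
#' @param params [qc_params()].
#' @return list with elements `matrix` (filtered [depth_matrix()]),
#'   `removed_samples`, `removed_sts` (character vectors of ids).
#' @export
iqr_outlier_filter <- function(dm, params = qc_params()) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (dm$normalized) {
    ycm_stop("iqr_outlier_filter expects a raw matrix", "ycm_contract_error")
  }
  if (nrow(dm$depth) < 4 || ncol(dm$depth) < 4) {
    ycm_stop("need at least 4 samples and 4 STSs for quartile fences",
             "ycm_contract_error")
  }
  stat <- if (params$iqr_stat == "mean") {
    list(s = rowMeans(dm$depth), t = colMeans(dm$depth))
  } else {
    list(s = apply(dm$depth, 1, median), t = apply(dm$depth, 2, median))
  }
  fs <- iqr_fences(stat$s, params$iqr_multiplier)
  ft <- iqr_fences(stat$t, params$iqr_multiplier)
  # relative epsilon so that a zero-IQR constant distribution never flags
  # its own members through floating-point jitter
  eps_s <- 1e-9 * max(abs(fs), 1)
  eps_t <- 1e-9 * max(abs(ft), 1)
  rm_samples <- sample_ids(dm)[stat$s < fs["lower"] - eps_s |
                                 stat$s > fs["upper"] + eps_s]
  rm_sts <- sts_ids(dm)[stat$t < ft["lower"] - eps_t |
                          stat$t > ft["upper"] + eps_t]
  out <- subset_depth(dm,
                      keep_samples = setdiff(sample_ids(dm), rm_samples),
                      keep_sts = setdiff(sts_ids(dm), rm_sts))
  list(matrix = out, removed_samples = rm_samples, removed_sts = rm_sts)
}

#' Median-depth cutoff filter on STSs
#'
#' Removes STSs whose raw median depth across the remaining samples is
#' below the cutoff; an STS only has the statistical power to reveal a
#' deletion if it is captured deeply in undeleted samples.
#'
#' @param dm raw [depth_matrix()] (after the IQR stage).
#' @param params [qc_params()].
#' @return list with `matrix` and `removed_sts`.
#' @export
median_depth_filter <- function(dm, params = qc_params()) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (dm$normalized) {
    ycm_stop("median_depth_filter expects a raw matrix", "ycm_contract_error")
  }
  if (ncol(dm$depth) == 0 || nrow(dm$depth) == 0) {
    return(list(matrix = dm, removed_sts = character(0)))
  }
  med <- apply(dm$depth, 2, median)
  rm_sts <- sts_ids(dm)[med < params$median_depth_cutoff]
  out <- subset_depth(dm, keep_sts = setdiff(sts_ids(dm), rm_sts))
  list(matrix = out, removed_sts = rm_sts)
}

#' Per-sample depth normalization
#'
#' Divides each sample's depths by that sample's mean depth over the
#' current STS set, removing between-sample data-production variation.
#' Afterwards every row mean is exactly 1.
#'
#' @param dm raw [depth_matrix()]; every sample mean must be > 0.
#' @return normalized [depth_matrix()].
#' @export
normalize_depth <- function(dm) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (dm$normalized) return(dm)
  rm <- rowMeans(dm$depth)
  if (any(rm <= 0)) {
    ycm_stop(sprintf("sample(s) with zero total depth: %s",
                     paste(sample_ids(dm)[rm <= 0], collapse = ", ")),
             "ycm_validation_error")
  }
  depth_matrix(dm$depth / rm, normalized = TRUE)
}

#' Standard-deviation filter on samples
#'
#' Removes samples whose standard deviation of normalized depth across STSs
#' exceeds the cutoff (strict `>`; n-1 denominator); high dispersion marks
#' an inefficient capture experiment whose depths cannot support reliable
#' deletion judgment.
#'
#' @param dm normalized [depth_matrix()].
#' @param params [qc_params()].
#' @return list with `matrix` and `removed_samples`.
#' @export
sd_filter <- function(dm, params = qc_params()) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (!dm$normalized) {
    ycm_stop("sd_filter expects a normalized matrix", "ycm_contract_error")
  }
  sds <- apply(dm$depth, 1, sd)
  # strict > with an epsilon so a sample sitting exactly on the cutoff is
  # kept regardless of floating-point representation
  rm_samples <- sample_ids(dm)[sds > params$sd_cutoff * (1 + 1e-12)]
  out <- subset_depth(dm, keep_samples = setdiff(sample_ids(dm), rm_samples))
  list(matrix = out, removed_samples = rm_samples)
}

#' Assemble a QC report from stage-wise removal counts
#'
#' Pure bookkeeping: reconciles initial counts with stage removals and
#' derives qualified counts plus one-decimal retention percentages. Used by
#' [run_qc()] and directly reusable on externally reported stage counts.
#'
#' @param initial_sts,initial_samples counts before QC.
#' @param iqr_removed_sts,iqr_removed_samples removals at the IQR stage.
#' @param depth_cutoff_removed_sts removals at the median-depth stage.
#' @param sd_removed_samples removals at the SD stage.
#' @param removed_ids optional named list of per-stage removed id vectors.
#' @return a `qc_report` list with qualified counts and retention
#'   percentages.
#' @export
qc_report <- function(initial_sts, initial_samples,
                      iqr_removed_sts, iqr_removed_samples,
                      depth_cutoff_removed_sts, sd_removed_samples,
                      removed_ids = list()) {
  qualified_sts <- initial_sts - iqr_removed_sts - depth_cutoff_removed_sts
  qualified_samples <- initial_samples - iqr_removed_samples - sd_removed_samples
  structure(list(
    initial_sts = initial_sts,
    initial_samples = initial_samples,
    iqr_removed_sts = iqr_removed_sts,
    iqr_removed_samples = iqr_removed_samples,
    depth_cutoff_removed_sts = depth_cutoff_removed_sts,
    sd_removed_samples = sd_removed_samples,
    qualified_sts = qualified_sts,
    qualified_samples = qualified_samples,
    sts_retention_pct = pct1(qualified_sts, initial_sts),
    sample_retention_pct = pct1(qualified_samples, initial_samples),
    removed_ids = removed_ids
  ), class = "qc_report")
}

#' Run the full QC cascade
#'
#' Applies, in order: joint IQR outlier removal of samples and STSs, the
#' raw median-depth cutoff on STSs, per-sample normalization, and the
#' normalized-SD sample filter. Returns the qualified normalized matrix and
#' a stage-by-stage report.
#'
#' @param dm raw [depth_matrix()].
#' @param params [qc_params()].
#' @return list with `matrix` (normalized, qualified) and `report`
#'   ([qc_report()]).
#' @export
run_qc <- function(dm, params = qc_params()) {
  stopifnot(inherits(dm, "depth_matrix"))
  n0_sts <- ncol(dm$depth)
  n0_samples <- nrow(dm$depth)

  if (dm$normalized) {
    # Re-running QC on its own output: the IQR fences and the 15x median
    # cutoff are defined on raw depths and are skipped (re-applying Tukey
    # fences to an already-truncated distribution would keep flagging new
    # borderline values); normalization is the identity, so only the SD
    # filter applies — and it removes nothing from its own output.
    s1 <- list(matrix = dm, removed_samples = character(0),
               removed_sts = character(0))
    s2 <- list(matrix = dm, removed_sts = character(0))
    s3 <- dm
  } else {
    s1 <- iqr_outlier_filter(dm, params)
    s2 <- median_depth_filter(s1$matrix, params)
    s3 <- normalize_depth(s2$matrix)
  }
  s4 <- sd_filter(s3, params)

  report <- qc_report(
    initial_sts = n0_sts, initial_samples = n0_samples,
    iqr_removed_sts = length(s1$removed_sts),
    iqr_removed_samples = length(s1$removed_samples),
    depth_cutoff_removed_sts = length(s2$removed_sts),
    sd_removed_samples = length(s4$removed_samples),
    removed_ids = list(iqr_samples = s1$removed_samples,
                       iqr_sts = s1$removed_sts,
                       depth_cutoff_sts = s2$removed_sts,
                       sd_samples = s4$removed_samples)
  )
  list(matrix = s4$matrix, report = report)
}

#' Write a QC report as JSON
#'
#' @param report a [qc_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  STSs:    %d -> %d qualified (%.1f%%); IQR -%d, median-depth -%d\n",
              x$initial_sts, x$qualified_sts, x$sts_retention_pct,
              x$iqr_removed_sts, x$depth_cutoff_removed_sts))
  cat(sprintf("  samples: %d -> %d qualified (%.1f%%); IQR -%d, SD -%d\n",
              x$initial_samples, x$qualified_samples, x$sample_retention_pct,
              x$iqr_removed_samples, x$sd_removed_samples))
  invisible(x)
}
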