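#' Per-STS depth statistics
#'
#' For each STS of a normalized, QC-passed matrix: the mean `mu`, standard
#' deviation `sigma` (n-1 denominator) and median `rmd` (the "RMD",
#' reference median depth of that STS across all qualified samples) of its
#' normalized depths. The depth distribution of a well-captured STS is
#' approximately normal across samples, which the first classifier
#' predictor exploits; an STS with `sigma == 0` is flagged degenerate and
#' excluded from the feature matrix, since a zero-variance column carries
#' no classification information.
#'
#' @param dm normalized [depth_matrix()].
#' @return data frame with columns `sts_id`, `mu`, `sigma`, `rmd`,
#'   `degenerate`.
#' @export
sts_stats <- function(dm) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (!dm$normalized) {
    ycm_stop("sts_stats expects a normalized matrix", "ycm_contract_error")
  }
  m <- dm$depth
  data.frame(
    sts_id = colnames(m),
    mu = colMeans(m),
    sigma = apply(m, 2, sd),
    rmd = apply(m, 2, median),
    row.names = NULL,
    stringsAsFactors = FALSE
  ) -> out
  out$degenerate <- out$sigma == 0
  out
}

#' Per-sample depth statistics
#'
#' For each sample: the median of its normalized depths across all
#' qualified STSs (the "SMD", sample median depth), the denominator of the
#' third classifier predictor.
#'
#' @param dm normalized [depth_matrix()].
#' @return data frame with columns `sample_id`, `smd`.
#' @export
sample_stats <- function(dm) {
  stopifnot(inherits(dm, "depth_matrix"))
  if (!dm$normalized) {
    ycm_stop("sample_stats expects a normalized matrix", "ycm_contract_error")
  }
  data.frame(sample_id = rownames(dm$depth),
             smd = apply(dm$depth, 1, median),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the three deletion predictors
#'
#' For every qualified (sample i, STS j) pair of a normalized depth matrix
#' `D`, computes the feature vector fed to the SVM:
#' \describe{
#'   \item{f1}{log-probability of `D[i, j]` under the STS's approximated
#'     normal distribution: the depth is standardized to
#'     `z = (D[i, j] - mu_j) / sigma_j` and `f1 = log(phi(z))` with `phi`
#'     the standard normal density (so `f1 = -log(2*pi)/2 - z^2/2`,
#'     maximal at `D = mu_j`). `f1_mode = "tail"` substitutes the
#'     lower-tail log-CDF `log(Phi(z))` as an alternative reading of
#'     "probability".}
#'   \item{f2}{`D[i, j] / rmd_j`, the depth over the STS's reference
#'     median depth (depth/RMD).}
#'   \item{f3}{`D[i, j] / smd_i`, the depth over the sample's median depth
#'     (depth/SMD).}
#' }
#' Degenerate STSs (`sigma_j == 0`) are excluded with a warning; a sample
#' with `smd == 0` is an error.
#'
#' @param dm normalized [depth_matrix()].
#' @param stats per-STS statistics from [sts_stats()] computed on the same
#'   matrix (computed on the fly if omitted).
#' @param f1_mode `"density"` (default) or `"tail"`.
#' @return long-format `feature_matrix` data frame with columns
#'   `sample_id`, `sts_id`, `f1`, `f2`, `f3`.
#' @export
compute_features <- function(dm, stats = NULL, f1_mode = c("density", "tail")) {
  f1_mode <- match.arg(f1_mode)
  stopifnot(inherits(dm, "depth_matrix"))
  if (!dm$normalized) {
    ycm_stop("compute_features expects a normalized matrix",
             "ycm_contract_error")
  }
  if (is.null(stats)) stats <- sts_stats(dm)
  if (!setequal(stats$sts_id, colnames(dm$depth))) {
    ycm_stop("stats were not computed from this matrix (STS sets differ)",
             "ycm_contract_error")
  }
  smp <- sample_stats(dm)
  if (any(smp$smd == 0)) {
    ycm_stop(sprintf("sample(s) with zero median depth: %s",
                     paste(smp$sample_id[smp$smd == 0], collapse = ", ")),
             "ycm_validation_error")
  }
  degen <- stats$sts_id[stats$degenerate]
  if (length(degen) > 0) {
    warning(sprintf("excluding %d degenerate (zero-variance) STS(s): %s",
                    length(degen), paste(degen, collapse = ", ")))
  }
  keep <- setdiff(colnames(dm$depth), degen)
  stats <- stats[match(keep, stats$sts_id), ]
  m <- dm$depth[, keep, drop = FALSE]

  z <- sweep(sweep(m, 2, stats$mu, "-"), 2, stats$sigma, "/")
  f1 <- if (f1_mode == "density") dnorm(z, log = TRUE) else pnorm(z, log.p = TRUE)
  f2 <- sweep(m, 2, stats$rmd, "/")
  f3 <- sweep(m, 1, smp$smd, "/")

  out <- data.frame(
    sample_id = rep(rownames(m), times = ncol(m)),
    sts_id = rep(colnames(m), each = nrow(m)),
    f1 = as.vector(f1), f2 = as.vector(f2), f3 = as.vector(f3),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$f1) | !is.finite(out$f2) | !is.finite(out$f3))) {
    ycm_stop("non-finite feature value produced; check input matrix",
             "ycm_validation_error")
  }
  attr(out, "f1_mode") <- f1_mode
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write a feature matrix to TSV
#'
#' Long format: `sample_id`, `sts_id`, `f1`, `f2`, `f3`.
#'
#' @param features a [compute_features()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.table(as.data.frame(features), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path input path.
#' @return a `feature_matrix` data frame.
#' @export
read_features <- function(path) {
  out <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("sample_id", "sts_id", "f1", "f2", "f3") %in% names(out)))
  class(out) <- c("feature_matrix", "data.frame")
  out
}
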