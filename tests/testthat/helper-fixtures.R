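# Shared fixtures and independent oracles. All fixtures are built in code;
# the default-scenario pipeline is computed once per test run and memoized.

toy_catalog <- function(starts, ends = starts + 200,
                        copy_class = "single", chrom = "chrY",
                        region = "other", annotation = "intergenic",
                        ids = sprintf("S%02d", seq_along(starts))) {
  sts_catalog(data.frame(
    chrom = chrom, start = starts, end = ends, sts_id = ids,
    copy_class = rep_len(copy_class, length(starts)),
    region = rep_len(region, length(starts)),
    annotation = rep_len(annotation, length(starts)),
    gene = NA_character_, stringsAsFactors = FALSE))
}

toy_depth <- function(m, samples = sprintf("smp%02d", seq_len(nrow(m))),
                      sts = sprintf("S%02d", seq_len(ncol(m))),
                      normalized = FALSE) {
  dimnames(m) <- list(samples, sts)
  depth_matrix(m, normalized = normalized)
}

calls_from_sets <- function(deleted_by_sample, all_sts) {
  rows <- lapply(names(deleted_by_sample), function(s) {
    data.frame(sample_id = s, sts_id = all_sts,
               state = ifelse(all_sts %in% deleted_by_sample[[s]],
                              "deleted", "not_deleted"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("call_matrix", "data.frame")
  out
}

# --- independent oracles ------------------------------------------------

# Tukey-fence outliers via an explicit type-7 quantile computation
oracle_iqr_outliers <- function(x, k = 1.5) {
  srt <- sort(x)
  n <- length(srt)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75); iqr <- q3 - q1
  which(x < q1 - k * iqr | x > q3 + k * iqr)
}

# Pearson chi-square on a 2x2 table by explicit summation
oracle_chisq_2x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# one-sided Fisher by exhaustive hypergeometric summation
oracle_fisher_one_sided <- function(a, b, n_case, n_control) {
  K <- a + b; N <- n_case + n_control
  support <- max(0, K - n_control):min(K, n_case)
  probs <- dhyper(support, K, N - K, n_case)
  if (a / n_case <= b / n_control) {
    sum(probs[support <= a])
  } else {
    sum(probs[support >= a])
  }
}

# merge oracle: connect consecutive deleted STSs iff the gap rule holds and
# a linear scan of the records between them finds no non-deleted
# single-copy STS; runs are the connected components
oracle_merge <- function(deleted_sts, catalog, max_gap = 1e5) {
  cat_df <- as.data.frame(catalog)
  cat_df <- cat_df[order(cat_df$chrom, cat_df$start), ]
  out <- list()
  for (chr in unique(cat_df$chrom)) {
    cc <- cat_df[cat_df$chrom == chr, ]
    del <- which(cc$sts_id %in% deleted_sts)
    if (length(del) == 0) next
    connected <- rep(FALSE, length(del))
    if (length(del) > 1) {
      for (k in seq_len(length(del) - 1)) {
        i <- del[k]; j <- del[k + 1]
        gap <- cc$start[j] - cc$end[i]
        between <- cc[seq_len(nrow(cc)) > i & seq_len(nrow(cc)) < j, ]
        nondel_single <- between$sts_id[!(between$sts_id %in% deleted_sts) &
                                          between$copy_class == "single"]
        connected[k] <- gap < max_gap && length(nondel_single) == 0
      }
    }
    run_id <- cumsum(c(1, !connected[-length(connected)]))
    for (r in unique(run_id)) {
      out[[length(out) + 1]] <- cc$sts_id[del[run_id == r]]
    }
  }
  out
}

# --- memoized default-scenario pipeline ---------------------------------

.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (!is.null(.pipeline_cache$res)) return(.pipeline_cache$res)
  sim <- simulate_cohort(sim_scenario(seed = 7))
  qcres <- run_qc(sim$depth)
  feats <- compute_features(qcres$matrix)
  set.seed(18)
  training <- make_training_subset(sim, feats)
  model <- train_classifier(training)  # shipped operating point
  calls <- classify(model, feats, dm = qcres$matrix)
  .pipeline_cache$res <- list(sim = sim, qc = qcres, features = feats,
                              training = training, model = model,
                              calls = calls)
  .pipeline_cache$res
}
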