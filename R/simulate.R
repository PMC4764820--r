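#' Simulation scenario
#'
#' Describes a synthetic STS-capture cohort with planted deletions. The
#' generative model mirrors the structure the detector assumes: the depth
#' of STS `j` in sample `i` is negative-binomial noise around
#' `base_depth * scale_i * efficiency_j * copy_factor_ij *
#' (residual_depth_fraction if truly deleted else 1)`,
#' where `scale_i` (per-sample data production) and `efficiency_j`
#' (per-STS capture efficiency) are log-normal, multi-copy STSs run at 2x
#' efficiency and can silently lose one of two copies (halving depth
#' without counting as deleted), and a truly deleted STS retains a small
#' residual depth from non-specific capture and misalignment rather than
#' dropping to zero.
#'
#' The deletion architecture plants (i) a recurrent three-STS b2/b3-like
#' interval (`DYF155S1`, `RH102047`, `sY1191`) carried by every
#' haplogroup-N sample, (ii) rare long contiguous deletions in cases,
#' (iii) scattered singleton deletions in both groups and a short
#' recurrent two-STS deletion in controls. Control STSs `sY84` and `sY86`
#' are never deleted. Defaults give roughly 5% of (sample, STS) pairs
#' deleted across a 200-sample, 300-STS cohort at a 38.25x mean depth.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_sts catalog size.
#' @param multi_copy_fraction proportion of multi-copy STSs.
#' @param base_depth cohort-level mean depth (reads).
#' @param efficiency_sdlog,sample_scale_sdlog log-normal sdlog of per-STS
#'   capture efficiency and per-sample scale (meanlog chosen so the mean
#'   is 1).
#' @param nb_dispersion negative-binomial size parameter; the default 50
#'   gives a per-(sample, STS) depth coefficient of variation of about
#'   21% at the nominal 38x depth, the uniformity of a well-behaved
#'   capture panel. `Inf` gives noise-free depths equal to their means
#'   (degenerate, used for contract tests).
#' @param residual_depth_fraction depth fraction retained at a truly
#'   deleted STS.
#' @param case_long_deletion_prob,case_long_deletion_mean_sts probability
#'   and mean STS length of a long planted deletion per case.
#' @param singleton_rate Poisson rate of scattered single-STS deletions
#'   per sample.
#' @param control_recurrent_carriers number of controls carrying the
#'   recurrent short control deletion.
#' @param copy_loss_prob per-(sample, multi-copy STS) probability of
#'   silent single-copy loss.
#' @param haplogroup_freqs named lineage frequencies (normalized
#'   internally); defaults approximate an East-Asian cohort dominated by
#'   haplogroup O.
#' @param marker_dropout probability that a marker genotype is missing.
#' @param seed mandatory integer seed.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_cases = 100, n_controls = 100, n_sts = 300,
                         multi_copy_fraction = 0.2,
                         base_depth = 38.25,
                         efficiency_sdlog = 0.25,
                         sample_scale_sdlog = 0.15,
                         nb_dispersion = 50,
                         residual_depth_fraction = 0.05,
                         case_long_deletion_prob = 0.5,
                         case_long_deletion_mean_sts = 30,
                         singleton_rate = 2,
                         control_recurrent_carriers = 15,
                         copy_loss_prob = 0.02,
                         haplogroup_freqs = c("O3a" = 0.55, "O2a" = 0.06,
                                              "O2*" = 0.02, "O2b" = 0.01,
                                              "O1a2" = 0.01, "C" = 0.10,
                                              "N" = 0.07, "Q" = 0.04,
                                              "D" = 0.02, "R" = 0.01,
                                              "J" = 0.01, "T" = 0.005,
                                              "G" = 0.005),
                         marker_dropout = 0,
                         seed) {
  if (missing(seed)) ycm_stop("seed is mandatory", "ycm_config_error")
  props <- c(multi_copy_fraction, residual_depth_fraction,
             case_long_deletion_prob, copy_loss_prob, marker_dropout)
  stopifnot(all(props >= 0 & props <= 1),
            n_cases > 0, n_controls > 0, n_sts >= 20,
            base_depth > 0, all(haplogroup_freqs >= 0))
  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_sts = n_sts,
    multi_copy_fraction = multi_copy_fraction, base_depth = base_depth,
    efficiency_sdlog = efficiency_sdlog,
    sample_scale_sdlog = sample_scale_sdlog,
    nb_dispersion = nb_dispersion,
    residual_depth_fraction = residual_depth_fraction,
    case_long_deletion_prob = case_long_deletion_prob,
    case_long_deletion_mean_sts = case_long_deletion_mean_sts,
    singleton_rate = singleton_rate,
    control_recurrent_carriers = control_recurrent_carriers,
    copy_loss_prob = copy_loss_prob,
    haplogroup_freqs = haplogroup_freqs / sum(haplogroup_freqs),
    marker_dropout = marker_dropout,
    seed = as.integer(seed)
  ), class = "sim_scenario")
}

SIM_B2B3_STS <- c("DYF155S1", "RH102047", "sY1191")
SIM_CONTROL_STS <- c("sY84", "sY86")
SIM_AZFC_MARKERS <- c(SIM_B2B3_STS, "sY1192", "sY1291", "sY1189")

# log-normal with mean exactly 1
rlnorm_mean1 <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sim_catalog <- function(sc) {
  n <- sc$n_sts
  gaps <- rlnorm(n, meanlog = log(4000), sdlog = 1.5)
  big <- runif(n) < 0.02
  gaps[big] <- runif(sum(big), 150000, 300000)
  len <- round(runif(n, 150, 600))

  # region blocks along the index range
  frac <- seq_len(n) / n
  region <- rep("other", n)
  region[frac <= 0.22] <- "Yp"
  region[frac > 0.22 & frac <= 0.30] <- "AZFa"
  region[frac > 0.40 & frac <= 0.55] <- "AZFb"
  region[frac > 0.62 & frac <= 0.92] <- "AZFc"

  ids <- sprintf("STS_%04d", seq_len(n))
  azfa_idx <- which(region == "AZFa")
  ids[azfa_idx[1:2]] <- SIM_CONTROL_STS
  azfc_idx <- which(region == "AZFc")
  mk <- azfc_idx[floor(length(azfc_idx) / 2)] + 0:5
  ids[mk] <- SIM_AZFC_MARKERS
  gaps[mk[-1]] <- 3000  # keep the marker block tightly spaced

  start <- cumsum(c(2650000, (gaps + len)[-n]))
  end <- start + len

  copy_class <- rep("single", n)
  # multi-copy sites live in the ampliconic AZFb/AZFc blocks
  amplicon <- setdiff(which(region %in% c("AZFb", "AZFc")), mk)
  n_multi <- min(length(amplicon), round(sc$multi_copy_fraction * n))
  if (n_multi > 0) {
    copy_class[sample(amplicon, n_multi)] <- "multi"
  }

  annotation <- sample(STS_ANNOTATIONS, n, replace = TRUE,
                       prob = c(0.10, 0.05, 0.30, 0.55))
  gene_pool <- c("USP9Y", "DDX3Y", "UTY", "TSPY1", "PCDH11Y", "PRKY",
                 "RBMY1A1", "PRY", "DAZ1", "CDY1", "BPY2", "XKRY", "HSFY1")
  gene <- ifelse(annotation == "intergenic", NA_character_,
                 sample(gene_pool, n, replace = TRUE))

  sts_catalog(data.frame(chrom = "chrY", start = start, end = end,
                         sts_id = ids, copy_class = copy_class,
                         region = region, annotation = annotation,
                         gene = gene, stringsAsFactors = FALSE))
}

#' Simulate a full synthetic cohort
#'
#' Generates, under one seed, a coherent set of artifacts: STS catalog,
#' raw depth matrix, haplogroup marker genotypes, cohort metadata, and the
#' per-(sample, STS) deletion truth. The same seed yields identical
#' output. Every haplogroup-N sample carries the planted b2/b3-like
#' three-STS deletion.
#'
#' @param scenario a [sim_scenario()].
#' @return a `ycm_sim` list: `catalog`, `depth` (raw [depth_matrix()]),
#'   `genotypes`, `metadata`, `truth` (logical sample x STS matrix),
#'   `haplogroups` (named vector of planted lineages), `tree`, `scenario`.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(sc$seed)

  catalog <- sim_catalog(sc)
  # catalog rows are coordinate-sorted; index them in that order
  ids <- catalog$sts_id
  n_sts <- length(ids)
  n <- sc$n_cases + sc$n_controls
  samples <- c(sprintf("case_%03d", seq_len(sc$n_cases)),
               sprintf("ctrl_%03d", seq_len(sc$n_controls)))
  metadata <- data.frame(sample_id = samples,
                         group = rep(c("case", "control"),
                                     c(sc$n_cases, sc$n_controls)),
                         stringsAsFactors = FALSE)

  tree <- load_haplogroup_tree(system.file("extdata", "haplogroup_tree.json",
                                           package = "ycmscan"))
  lineages <- names(sc$haplogroup_freqs)
  bad <- setdiff(lineages, names(tree$nodes))
  if (length(bad) > 0) {
    ycm_stop(sprintf("haplogroup frequency lineage(s) not in tree: %s",
                     paste(bad, collapse = ", ")), "ycm_config_error")
  }
  haplogroups <- sample(lineages, n, replace = TRUE,
                        prob = sc$haplogroup_freqs)
  names(haplogroups) <- samples

  protected <- which(ids %in% SIM_CONTROL_STS)
  truth <- matrix(FALSE, n, n_sts, dimnames = list(samples, ids))

  # (i) founder b2/b3-like deletion riding on haplogroup N
  b2b3_idx <- which(ids %in% SIM_B2B3_STS)
  truth[haplogroups == "N", b2b3_idx] <- TRUE

  # (ii) rare long contiguous deletions in cases
  for (i in seq_len(sc$n_cases)) {
    if (runif(1) >= sc$case_long_deletion_prob) next
    for (try in 1:20) {
      L <- max(10, rpois(1, sc$case_long_deletion_mean_sts))
      L <- min(L, n_sts - 1)
      s0 <- sample.int(n_sts - L + 1, 1)
      if (!any(seq(s0, s0 + L - 1) %in% protected)) {
        truth[i, s0:(s0 + L - 1)] <- TRUE
        break
      }
    }
  }

  # (iii) scattered singletons in everyone + a short recurrent control run
  eligible <- setdiff(seq_len(n_sts), protected)
  for (i in seq_len(n)) {
    k <- rpois(1, sc$singleton_rate)
    if (k > 0) truth[i, sample(eligible, min(k, length(eligible)))] <- TRUE
  }
  other_idx <- which(catalog$region == "other" & catalog$copy_class == "single")
  rec <- other_idx[which(diff(other_idx) == 1)[1] + 0:1]
  if (!anyNA(rec) && sc$control_recurrent_carriers > 0) {
    carriers <- sc$n_cases +
      sample.int(sc$n_controls, min(sc$control_recurrent_carriers,
                                    sc$n_controls))
    truth[carriers, rec] <- TRUE
  }

  # depth model
  # multi-copy sites run at 2x efficiency relative to single-copy ones;
  # total efficiency is renormalized to mean 1 so base_depth remains the
  # cohort-level mean depth
  eff <- rlnorm_mean1(n_sts, sc$efficiency_sdlog) *
    ifelse(catalog$copy_class == "multi", 2, 1)
  eff <- eff / mean(eff)
  scale_i <- rlnorm_mean1(n, sc$sample_scale_sdlog)
  partial <- matrix(FALSE, n, n_sts)
  is_multi <- catalog$copy_class == "multi"
  partial[, is_multi] <- runif(n * sum(is_multi)) < sc$copy_loss_prob
  partial[truth] <- FALSE  # full deletion overrides silent copy loss

  mu <- outer(scale_i, sc$base_depth * eff)
  mu[partial] <- mu[partial] * 0.5
  mu[truth] <- mu[truth] * sc$residual_depth_fraction
  depth <- if (is.finite(sc$nb_dispersion)) {
    matrix(rnbinom(length(mu), mu = mu, size = sc$nb_dispersion),
           n, n_sts)
  } else {
    mu
  }
  dimnames(depth) <- dimnames(truth)

  # marker genotypes from the planted lineage paths
  markers <- tree_markers(tree)
  geno <- matrix(NA_character_, n, length(markers),
                 dimnames = list(samples, markers))
  anc <- derv <- setNames(character(length(markers)), markers)
  for (nd in tree$nodes) {
    for (m in nd$markers) {
      anc[m$marker] <- m$ancestral
      derv[m$marker] <- m$derived
    }
  }
  for (i in seq_len(n)) {
    path <- tree_path(tree, haplogroups[i])
    path_markers <- unlist(lapply(path, function(nm)
      vapply(tree$nodes[[nm]]$markers, `[[`, "", "marker")))
    row <- anc
    row[path_markers] <- derv[path_markers]
    geno[i, ] <- row[markers]
  }
  if (sc$marker_dropout > 0) {
    drop <- runif(length(geno)) < sc$marker_dropout
    geno[drop] <- NA_character_
  }
  genotypes <- data.frame(sample_id = samples, geno, check.names = FALSE,
                          stringsAsFactors = FALSE)

  structure(list(catalog = catalog,
                 depth = depth_matrix(depth, normalized = FALSE),
                 genotypes = genotypes, metadata = metadata,
                 truth = truth, haplogroups = haplogroups,
                 tree = tree, scenario = sc),
            class = "ycm_sim")
}

#' Draw a labeled training subset from simulation truth
#'
#' Emulates the PCR-validated training draw: `n_events` labeled
#' (sample, STS) events from at most `n_samples` distinct samples. The
#' default draw is stratified over the depth/RMD (f2) range — events are
#' spread across f2 deciles so the training set covers the whole predictor
#' range, which is how a validation set "covering different p values,
#' depth/RMD and depth/SMD values" behaves. `mix = "prevalence"` draws
#' uniformly instead, giving the cohort's observed class mix.
#'
#' @param sim a [simulate_cohort()] result (source of truth labels).
#' @param features a [compute_features()] result from the QC-passed
#'   matrix of the same simulation.
#' @param n_events number of labeled events (default 134).
#' @param n_samples maximum number of distinct samples drawn from
#'   (default 26).
#' @param mix `"feature_stratified"` (default) or `"prevalence"`.
#' @return a [training_set()].
#' @export
make_training_subset <- function(sim, features, n_events = 134,
                                 n_samples = 26,
                                 mix = c("feature_stratified", "prevalence")) {
  mix <- match.arg(mix)
  stopifnot(inherits(sim, "ycm_sim"))
  if (n_events <= 0) {
    ycm_stop("n_events must be positive", "ycm_domain_error")
  }
  truth_label <- function(df) {
    sim$truth[cbind(df$sample_id, df$sts_id)]
  }
  # restrict to <= n_samples samples, preferring samples that carry
  # deletions so both classes are represented
  avail <- unique(features$sample_id)
  n_del <- vapply(avail, function(s) {
    sum(sim$truth[s, unique(features$sts_id[features$sample_id == s])])
  }, 0)
  carriers <- avail[n_del > 0]
  carriers <- carriers[order(-n_del[carriers])]
  take_carriers <- head(carriers, ceiling(n_samples / 2))
  rest <- setdiff(avail, take_carriers)
  chosen <- c(take_carriers,
              sample(rest, min(length(rest), n_samples - length(take_carriers))))
  pool <- features[features$sample_id %in% chosen, , drop = FALSE]
  if (n_events > nrow(pool)) {
    ycm_stop(sprintf("requested %d events but only %d available",
                     n_events, nrow(pool)), "ycm_domain_error")
  }

  if (mix == "prevalence") {
    take <- pool[sample.int(nrow(pool), n_events), , drop = FALSE]
  } else {
    # hierarchical stratification spanning the predictor space: equal
    # quotas over depth/RMD (f2) deciles — so the sparse low-depth range
    # is as well represented as the bulk — and, within each decile, an
    # even spread over log-probability (f1) terciles (f3 tracks f2
    # closely and needs no bins of its own)
    qbin <- function(x, k) {
      qs <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1),
                            type = 7))
      cut(x, breaks = qs, include.lowest = TRUE)
    }
    draw_spread <- function(ii, k) {
      if (length(ii) <= k) return(ii)
      sub <- split(ii, qbin(pool$f1[ii], 3))
      sub <- sub[lengths(sub) > 0]
      quota <- ceiling(k / length(sub))
      out <- unlist(lapply(sub, function(jj)
        if (length(jj) <= quota) jj else sample(jj, quota)))
      if (length(out) > k) out <- sample(out, k)
      out
    }
    per_bin <- split(seq_len(nrow(pool)), qbin(pool$f2, 10))
    per_bin <- per_bin[lengths(per_bin) > 0]
    want <- ceiling(n_events / length(per_bin))
    idx <- unlist(lapply(per_bin, draw_spread, k = want))
    if (length(idx) > n_events) idx <- sample(idx, n_events)
    if (length(idx) < n_events) {
      idx <- c(idx, sample(setdiff(seq_len(nrow(pool)), idx),
                           n_events - length(idx)))
    }
    take <- pool[idx, , drop = FALSE]
  }
  labels <- data.frame(sample_id = take$sample_id, sts_id = take$sts_id,
                       deleted = truth_label(take),
                       stringsAsFactors = FALSE)
  training_set(features, labels)
}

#' Materialize a simulation as a demo workspace
#'
#' Writes the exact file formats consumed by the pipeline: catalog TSV,
#' raw depth TSV, genotype TSV, metadata TSV and truth TSV, plus a
#' scenario JSON recording every parameter and the seed.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_workspace <- function(sim, dir) {
  stopifnot(inherits(sim, "ycm_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog(sim$catalog, file.path(dir, "catalog.tsv"))
  write_depth_matrix(sim$depth, file.path(dir, "depth.tsv"))
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(sample_id = rownames(sim$truth),
                         sim$truth * 1L, check.names = FALSE)
  write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$scenario), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
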