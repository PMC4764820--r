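#' Per-group deletion summary
#'
#' Reproduces the shape of a case-control deletion summary table: per
#' group, the number of samples, deleted individuals (at least one deleted
#' STS), total deletion events, unique deleted STSs, unique merged
#' deletions, and three derived means reported half-up to one decimal:
#' total deletions per deleted individual, unique deleted STSs per deleted
#' individual, and individuals per unique deletion (recurrence). SDs
#' accompany the first and last of these (over the per-individual deletion
#' counts and the per-STS recurrence counts respectively); the middle one
#' is a ratio of group aggregates with no per-individual vector, so its SD
#' slot is `NA`.
#'
#' @param calls a `call_matrix`.
#' @param catalog an [sts_catalog()] (for merging).
#' @param metadata data frame with `sample_id`, `group`.
#' @param params a [merge_params()].
#' @return data frame, one row per group, with a `group_summary` class.
#' @export
summarize_groups <- function(calls, catalog, metadata,
                             params = merge_params()) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  census <- unique_deletion_census(calls, catalog, metadata, params)
  res <- lapply(unique(metadata$group), function(g) {
    samples <- metadata$sample_id[metadata$group == g]
    sub <- calls[calls$sample_id %in% samples & calls$state == "deleted", ]
    per_ind <- table(factor(sub$sample_id, levels = samples))
    per_ind_deleted <- as.integer(per_ind[per_ind > 0])
    recurrence <- as.integer(table(sub$sts_id))
    n_del_ind <- length(per_ind_deleted)
    n_total <- nrow(sub)
    n_unique <- length(unique(sub$sts_id))
    data.frame(
      group = g,
      n_samples = length(samples),
      n_deleted_individuals = n_del_ind,
      n_total_deletions = n_total,
      n_unique_deleted_sts = n_unique,
      n_post_merge_unique = census$post_merge[census$group == g],
      mean_deletions_per_deleted_individual =
        if (n_del_ind > 0) round_half_up(n_total / n_del_ind, 1) else NA_real_,
      sd_deletions_per_deleted_individual =
        if (n_del_ind > 1) sd(per_ind_deleted) else NA_real_,
      mean_unique_per_deleted_individual =
        if (n_del_ind > 0) round_half_up(n_unique / n_del_ind, 1) else NA_real_,
      sd_unique_per_deleted_individual = NA_real_,
      mean_individuals_per_unique_deletion =
        if (n_unique > 0) round_half_up(n_total / n_unique, 1) else NA_real_,
      sd_individuals_per_unique_deletion =
        if (n_unique > 1) sd(recurrence) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Fold increase between two rounded means
#'
#' Ratio of the two one-decimal rounded means, itself rounded half-up to
#' one decimal (this is the convention that turns 11.7 and 3.7 into a
#' 3.2-fold increase).
#'
#' @param mean_case,mean_control one-decimal means.
#' @return one-decimal fold change.
#' @export
fold_increase <- function(mean_case, mean_control) {
  round_half_up(mean_case / mean_control, 1)
}

#' Pearson chi-square on a 2x2 table
#'
#' Plain Pearson statistic without Yates continuity correction (the
#' package default; `correct = TRUE` switches the correction on).
#'
#' @param tab 2x2 integer matrix.
#' @param correct apply Yates correction.
#' @return `htest` object from [stats::chisq.test()].
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(all(dim(tab) == c(2, 2)))
  suppressWarnings(chisq.test(tab, correct = correct))
}

#' Case-control comparison tests
#'
#' The four headline tests of a deletion summary table:
#' \describe{
#'   \item{carriers}{chi-square on deleted vs non-deleted individual
#'     counts across groups.}
#'   \item{unique_sts}{chi-square on unique-deleted vs other qualified
#'     STS counts across groups (each group's unique deleted STSs against
#'     the rest of the qualified STS universe).}
#'   \item{deletions_per_individual}{Kruskal-Wallis on per-deleted-
#'     individual deletion counts.}
#'   \item{recurrence}{Kruskal-Wallis on per-unique-deletion recurrence
#'     counts.}
#' }
#' Degenerate tables (a zero margin) are skipped with a reason.
#'
#' @param calls a `call_matrix`.
#' @param metadata data frame with `sample_id`, `group` (two groups).
#' @param n_qualified_sts size of the qualified STS universe (defaults to
#'   the number of distinct STSs in `calls`).
#' @param correct Yates correction for the chi-square tests.
#' @return data frame: `test`, `statistic`, `p`, `note`.
#' @export
compare_groups <- function(calls, metadata, n_qualified_sts = NULL,
                           correct = FALSE) {
  groups <- unique(metadata$group)
  stopifnot(length(groups) == 2)
  if (is.null(n_qualified_sts)) {
    n_qualified_sts <- length(unique(calls$sts_id))
  }
  del <- calls[calls$state == "deleted", ]
  per_group <- lapply(groups, function(g) {
    samples <- metadata$sample_id[metadata$group == g]
    sub <- del[del$sample_id %in% samples, ]
    counts <- table(sub$sample_id)
    list(n = length(samples),
         carriers = length(counts),
         unique_sts = length(unique(sub$sts_id)),
         per_ind = as.integer(counts),
         recurrence = as.integer(table(sub$sts_id)))
  })
  names(per_group) <- groups

  row <- function(test, statistic, p, note = "") {
    data.frame(test = test, statistic = statistic, p = p, note = note,
               stringsAsFactors = FALSE)
  }
  run_chisq <- function(test, tab) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(row(test, NA_real_, NA_real_, "skipped: zero margin"))
    }
    ct <- chisq_2x2(tab, correct = correct)
    row(test, unname(ct$statistic), ct$p.value)
  }
  run_kw <- function(test, x1, x2) {
    if (length(x1) == 0 || length(x2) == 0) {
      return(row(test, NA_real_, NA_real_, "skipped: empty group"))
    }
    kt <- kruskal.test(list(x1, x2))
    row(test, unname(kt$statistic), kt$p.value)
  }

  g1 <- per_group[[1]]; g2 <- per_group[[2]]
  out <- rbind(
    run_chisq("carriers",
              matrix(c(g1$carriers, g1$n - g1$carriers,
                       g2$carriers, g2$n - g2$carriers), nrow = 2)),
    run_chisq("unique_sts",
              matrix(c(g1$unique_sts, n_qualified_sts - g1$unique_sts,
                       g2$unique_sts, n_qualified_sts - g2$unique_sts),
                     nrow = 2)),
    run_kw("deletions_per_individual", g1$per_ind, g2$per_ind),
    run_kw("recurrence", g1$recurrence, g2$recurrence)
  )
  rownames(out) <- NULL
  out
}

#' Deletion frequency and recurrence spectra
#'
#' Per group: the histogram of per-individual deletion counts (how many
#' STSs each deleted individual lost) and the recurrence histogram of
#' unique deleted STSs (how many individuals carry each). Cases carrying
#' more but rarer deletions show a right-shifted count spectrum and a
#' recurrence spectrum concentrated at 1.
#'
#' @param calls a `call_matrix`.
#' @param metadata data frame with `sample_id`, `group`.
#' @return list with data frames `per_individual` (`group`, `n_deleted_sts`,
#'   `n_individuals`, `proportion`) and `recurrence` (`group`,
#'   `n_individuals`, `n_sts`, `proportion`).
#' @export
deletion_spectra <- function(calls, metadata) {
  del <- calls[calls$state == "deleted", ]
  per_ind <- list(); recur <- list()
  for (g in unique(metadata$group)) {
    samples <- metadata$sample_id[metadata$group == g]
    sub <- del[del$sample_id %in% samples, ]
    ci <- table(table(sub$sample_id))
    if (length(ci) > 0) {
      per_ind[[g]] <- data.frame(group = g,
                                 n_deleted_sts = as.integer(names(ci)),
                                 n_individuals = as.integer(ci),
                                 proportion = as.integer(ci) / sum(ci),
                                 stringsAsFactors = FALSE)
    }
    cr <- table(table(sub$sts_id))
    if (length(cr) > 0) {
      recur[[g]] <- data.frame(group = g,
                               n_individuals = as.integer(names(cr)),
                               n_sts = as.integer(cr),
                               proportion = as.integer(cr) / sum(cr),
                               stringsAsFactors = FALSE)
    }
  }
  list(per_individual = do.call(rbind, c(per_ind, list(NULL))),
       recurrence = do.call(rbind, c(recur, list(NULL))))
}

#' Annotation-category enrichment of unique deleted STSs
#'
#' Per annotation category — coding, UTR, intron, the combined intragenic
#' category (coding + UTR + intron) and intergenic — counts the unique
#' deleted STSs of each group falling in the category and tests the 2x2
#' table (in-category vs not, crossed with group) by chi-square. Deletions
#' of gene-disrupting potential concentrate in the intragenic categories.
#'
#' @param calls a `call_matrix`.
#' @param catalog an [sts_catalog()] annotating every STS.
#' @param metadata data frame with `sample_id`, `group` (two groups).
#' @param correct Yates correction.
#' @return data frame: `category`, one count column per group, `statistic`,
#'   `p`, `note`.
#' @export
annotation_enrichment <- function(calls, catalog, metadata, correct = FALSE) {
  groups <- unique(metadata$group)
  stopifnot(length(groups) == 2)
  del <- calls[calls$state == "deleted", ]
  uniq <- lapply(groups, function(g) {
    samples <- metadata$sample_id[metadata$group == g]
    unique(del$sts_id[del$sample_id %in% samples])
  })
  names(uniq) <- groups
  unknown <- setdiff(unlist(uniq), catalog$sts_id)
  if (length(unknown) > 0) {
    ycm_stop(sprintf("deleted STS absent from catalog: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             "ycm_lookup_error")
  }
  anno_of <- setNames(catalog$annotation, catalog$sts_id)
  categories <- c(STS_ANNOTATIONS, "intragenic")
  in_cat <- function(ids, cat) {
    if (cat == "intragenic") {
      sum(anno_of[ids] %in% c("coding", "UTR", "intron"))
    } else {
      sum(anno_of[ids] == cat)
    }
  }
  res <- lapply(categories, function(cat) {
    a <- in_cat(uniq[[1]], cat); b <- in_cat(uniq[[2]], cat)
    n1 <- length(uniq[[1]]); n2 <- length(uniq[[2]])
    tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2)
    base <- data.frame(category = cat, stringsAsFactors = FALSE)
    base[[paste0("n_", groups[1])]] <- a
    base[[paste0("n_", groups[2])]] <- b
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      base$statistic <- NA_real_; base$p <- NA_real_
      base$note <- "skipped: zero margin"
    } else {
      ct <- chisq_2x2(tab, correct = correct)
      base$statistic <- unname(ct$statistic); base$p <- ct$p.value
      base$note <- ""
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Carrier frequency as a one-decimal percentage
#'
#' Convenience wrapper used for recurrent-deletion carrier rates (e.g.
#' b2/b3 carriers over group size).
#'
#' @param carriers carrier count.
#' @param n group size.
#' @return percentage on the 0-100 scale, one decimal.
#' @export
carrier_freq_pct <- function(carriers, n) pct1(carriers, n)
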