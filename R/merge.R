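#' Merge parameters
#'
#' @param max_gap maximum distance in bp between consecutive deleted STSs
#'   for them to be connected into one deletion (default 100,000; chosen
#'   well above the 95th percentile of inter-probe distances so that
#'   continuous deletions are rarely split).
#' @return a `merge_params` list.
#' @export
merge_params <- function(max_gap = 100000) {
  stopifnot(max_gap > 0)
  structure(list(max_gap = max_gap), class = "merge_params")
}

#' Merge one sample's deleted STSs into deletion intervals
#'
#' Walks the catalog in coordinate order and connects consecutive deleted
#' STSs into runs under two rules: (i) the gap (start of downstream minus
#' end of upstream deleted STS) must be below `max_gap`; (ii) every
#' catalog record between them must be either deleted or a non-deleted
#' multi-copy STS (a multi-copy site can lose copies without a depth
#' dropout, so it may be skipped; a non-deleted single-copy STS always
#' breaks the run). Each maximal run becomes one interval with a minimal
#' extent (`inner_*`, the outermost deleted STSs) and a maximal extent
#' (`outer_*`, bounded by the nearest flanking non-deleted STS, or by the
#' merge window edge `inner +/- max_gap` if none lies within it).
#'
#' @param deleted_sts character vector of deleted `sts_id`s for one
#'   sample.
#' @param catalog an [sts_catalog()] containing every deleted id.
#' @param params a [merge_params()].
#' @param sample_id optional id recorded in the output.
#' @return data frame of deletion intervals: `sample_id`, `chrom`,
#'   `inner_start`, `inner_end`, `outer_start`, `outer_end`,
#'   `member_sts` (comma-joined, coordinate order), `n_sts`.
#' @export
merge_sample <- function(deleted_sts, catalog, params = merge_params(),
                         sample_id = NA_character_) {
  stopifnot(inherits(catalog, "sts_catalog"))
  deleted_sts <- unique(as.character(deleted_sts))
  unknown <- setdiff(deleted_sts, catalog$sts_id)
  if (length(unknown) > 0) {
    ycm_stop(sprintf("deleted STS absent from catalog: %s",
                     paste(unknown, collapse = ", ")),
             "ycm_lookup_error")
  }
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      inner_start = numeric(0), inner_end = numeric(0),
                      outer_start = numeric(0), outer_end = numeric(0),
                      member_sts = character(0), n_sts = integer(0),
                      stringsAsFactors = FALSE)
  if (length(deleted_sts) == 0) return(empty)

  out <- list()
  for (chr in unique(catalog$chrom)) {
    cat_c <- catalog[catalog$chrom == chr, , drop = FALSE]
    is_del <- cat_c$sts_id %in% deleted_sts
    if (!any(is_del)) next
    del_idx <- which(is_del)

    runs <- list()
    run <- del_idx[1]
    if (length(del_idx) > 1) {
      for (k in 2:length(del_idx)) {
        prev <- run[length(run)]
        cur <- del_idx[k]
        gap <- cat_c$start[cur] - cat_c$end[prev]
        between <- if (cur - prev > 1) (prev + 1):(cur - 1) else integer(0)
        blocked <- any(!is_del[between] & cat_c$copy_class[between] == "single")
        if (gap < params$max_gap && !blocked) {
          run <- c(run, cur)
        } else {
          runs[[length(runs) + 1]] <- run
          run <- cur
        }
      }
    }
    runs[[length(runs) + 1]] <- run

    for (run in runs) {
      inner_start <- cat_c$start[run[1]]
      inner_end <- cat_c$end[run[length(run)]]
      # nearest flanking non-deleted STSs bound the maximal extent
      up <- which(!is_del & cat_c$end <= inner_start)
      down <- which(!is_del & cat_c$start >= inner_end)
      outer_start <- max(0, inner_start - params$max_gap,
                         if (length(up) > 0) max(cat_c$end[up]) else -Inf)
      outer_end <- min(inner_end + params$max_gap,
                       if (length(down) > 0) min(cat_c$start[down]) else Inf)
      out[[length(out) + 1]] <- data.frame(
        sample_id = sample_id, chrom = chr,
        inner_start = inner_start, inner_end = inner_end,
        outer_start = outer_start, outer_end = outer_end,
        member_sts = paste(cat_c$sts_id[run], collapse = ","),
        n_sts = length(run), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(empty), out))
  rownames(res) <- NULL
  res
}

#' Merge deletion calls for every sample
#'
#' Only STSs with an evaluated call state act as run members or blockers:
#' the catalog is restricted to the called universe, so a QC-removed or
#' degenerate STS (which carries no deletion evidence either way) neither
#' joins nor breaks a run.
#'
#' @param calls a `call_matrix` (see [classify()]).
#' @param catalog an [sts_catalog()].
#' @param params a [merge_params()].
#' @return row-bound [merge_sample()] output for all samples with at least
#'   one deleted STS.
#' @export
merge_calls <- function(calls, catalog, params = merge_params()) {
  evaluated <- unique(calls$sts_id[calls$state %in%
                                     c("deleted", "not_deleted")])
  catalog <- catalog[catalog$sts_id %in% evaluated, , drop = FALSE]
  class(catalog) <- c("sts_catalog", "data.frame")
  by_sample <- deleted_ids_by_sample(calls)
  res <- lapply(names(by_sample), function(s) {
    merge_sample(by_sample[[s]], catalog, params, sample_id = s)
  })
  out <- do.call(rbind, c(list(merge_sample(character(0), catalog, params)),
                          res))
  rownames(out) <- NULL
  out
}

#' Unique-deletion census before and after merging
#'
#' Per cohort group: the number of distinct STS ids deleted in at least one
#' sample of the group (pre-merge) and the number of distinct merged
#' deletions (post-merge; keyed by exact member-STS set) across the group.
#' A group whose deletions are long and contiguous shrinks strongly under
#' merging; scattered singleton deletions do not.
#'
#' @param calls a `call_matrix`.
#' @param catalog an [sts_catalog()].
#' @param metadata data frame with `sample_id`, `group`.
#' @param params a [merge_params()].
#' @return data frame: `group`, `pre_merge`, `post_merge`.
#' @export
unique_deletion_census <- function(calls, catalog, metadata,
                                   params = merge_params()) {
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  groups <- unique(metadata$group)
  unknown <- setdiff(unique(calls$sample_id), metadata$sample_id)
  if (length(unknown) > 0) {
    ycm_stop(sprintf("sample(s) missing from metadata: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             "ycm_lookup_error")
  }
  res <- lapply(groups, function(g) {
    samples <- metadata$sample_id[metadata$group == g]
    sub <- calls[calls$sample_id %in% samples, , drop = FALSE]
    pre <- length(unique(sub$sts_id[sub$state == "deleted"]))
    merged <- merge_calls(sub, catalog, params)
    post <- length(unique(merged$member_sts))
    data.frame(group = g, pre_merge = pre, post_merge = post,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export merged intervals as BED6+
#'
#' Columns: chrom, outer_start, outer_end, name (`sample:index`), score
#' (`n_sts`), strand `.`, then inner coordinates and member ids.
#'
#' @param intervals a [merge_calls()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
intervals_to_bed <- function(intervals, path) {
  name <- paste0(intervals$sample_id, ":", seq_len(nrow(intervals)))
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$outer_start, scientific = FALSE, trim = TRUE),
                    end = format(intervals$outer_end, scientific = FALSE, trim = TRUE),
                    name = name, score = intervals$n_sts, strand = ".",
                    inner_start = format(intervals$inner_start, scientific = FALSE, trim = TRUE),
                    inner_end = format(intervals$inner_end, scientific = FALSE, trim = TRUE),
                    member_sts = intervals$member_sts)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Match samples against known deletion patterns
#'
#' Catalog-driven lookup for naming recurrent deletions (b2/b3, b1/b3,
#' b1/b2, gr/gr, DAZ loss, ...): a sample matches a pattern when every
#' marker STS listed as `deleted` is called deleted and every marker
#' listed as `retained` is called not deleted. Pattern classification is
#' pattern matching against marker STSs, not computation; the pattern
#' table ships as an editable JSON config.
#'
#' @param calls a `call_matrix`.
#' @param patterns named list; each element a list with character vectors
#'   `deleted` and (optionally) `retained`, or a path to a JSON file of
#'   that shape.
#' @return data frame: `sample_id`, `pattern`, `match` (logical).
#' @export
match_deletion_patterns <- function(calls, patterns) {
  if (is.character(patterns) && length(patterns) == 1) {
    patterns <- jsonlite::read_json(patterns, simplifyVector = TRUE)
  }
  samples <- unique(calls$sample_id)
  res <- list()
  for (s in samples) {
    sub <- calls[calls$sample_id == s, , drop = FALSE]
    del <- sub$sts_id[sub$state == "deleted"]
    notdel <- sub$sts_id[sub$state == "not_deleted"]
    for (p in names(patterns)) {
      pat <- patterns[[p]]
      ok <- all(pat$deleted %in% del) &&
        all((pat$retained %||% character(0)) %in% notdel)
      res[[length(res) + 1]] <- data.frame(sample_id = s, pattern = p,
                                           match = ok,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
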