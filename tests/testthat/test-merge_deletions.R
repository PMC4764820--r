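test_that("gap rule joins below 100 kb and splits at or above it", {
  cat <- toy_catalog(c(10000, 60000), c(10200, 60200))
  iv <- merge_sample(c("S01", "S02"), cat)   # 49.8 kb gap
  expect_equal(nrow(iv), 1)
  expect_equal(iv$n_sts, 2)
  expect_equal(iv$inner_start, 10000)
  expect_equal(iv$inner_end, 60200)

  cat2 <- toy_catalog(c(10000, 160200), c(10200, 160400))  # gap = 150 kb
  iv2 <- merge_sample(c("S01", "S02"), cat2)
  expect_equal(nrow(iv2), 2)
})

test_that("multi-copy skip rule: only non-deleted multi-copy STSs are crossed", {
  # deleted - (non-deleted multi) - deleted within 80 kb
  cat_m <- toy_catalog(c(10000, 50000, 90000), c(10200, 50200, 90200),
                       copy_class = c("single", "multi", "single"))
  iv <- merge_sample(c("S01", "S03"), cat_m)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$member_sts, "S01,S03")
  expect_equal(iv$n_sts, 2)

  # same geometry with a single-copy blocker
  cat_s <- toy_catalog(c(10000, 50000, 90000), c(10200, 50200, 90200))
  iv2 <- merge_sample(c("S01", "S03"), cat_s)
  expect_equal(nrow(iv2), 2)

  # a deleted multi-copy STS is a full run member
  iv3 <- merge_sample(c("S01", "S02", "S03"), cat_m)
  expect_equal(iv3$member_sts, "S01,S02,S03")
})

test_that("outer boundaries come from flanking non-deleted STSs or the window", {
  cat <- toy_catalog(c(10000, 200000, 250000, 500000),
                     c(10200, 200200, 250200, 500200))
  iv <- merge_sample(c("S02", "S03"), cat)
  expect_equal(iv$outer_start, 100000)  # S01 end is outside the 100-kb window
  expect_equal(iv$outer_end, 350200)    # S04 start outside window too
  iv2 <- merge_sample(c("S03"), cat)
  expect_equal(iv2$outer_start, 200200) # S02 end, within window
  expect_equal(iv2$outer_end, 350200)
  expect_true(all(iv$outer_start <= iv$inner_start &
                    iv$inner_end <= iv$outer_end))
})

test_that("unknown deleted ids raise a lookup error", {
  cat <- toy_catalog(c(100, 300))
  expect_error(merge_sample("nope", cat), "nope",
               class = "ycm_lookup_error")
})

test_that("merge agrees with the brute-force oracle on random small catalogs", {
  set.seed(50)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    starts <- sort(sample.int(3e6, n))
    cat <- toy_catalog(starts, starts + sample(100:400, n, replace = TRUE),
                       copy_class = sample(c("single", "multi"), n,
                                           replace = TRUE, prob = c(0.7, 0.3)))
    deleted <- sample(cat$sts_id, sample.int(n, 1))
    got <- merge_sample(deleted, cat)
    want <- oracle_merge(deleted, cat)
    expect_equal(nrow(got), length(want))
    expect_setequal(got$member_sts,
                    vapply(want, paste, "", collapse = ","))
    # partition: every deleted STS in exactly one interval
    members <- unlist(strsplit(got$member_sts, ","))
    expect_setequal(members, deleted)
    expect_equal(anyDuplicated(members), 0)
    # order independence
    got2 <- merge_sample(rev(deleted), cat)
    expect_equal(got2, got)
  }
})

test_that("interval count is monotone non-increasing in max_gap", {
  set.seed(51)
  starts <- sort(sample.int(2e6, 25))
  cat <- toy_catalog(starts, starts + 200)
  deleted <- sample(cat$sts_id, 12)
  gaps <- c(1e4, 5e4, 1e5, 5e5, 2e6)
  counts <- vapply(gaps, function(g)
    nrow(merge_sample(deleted, cat, merge_params(max_gap = g))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("census counts unique deletions before and after merging", {
  starts <- seq(10000, by = 20000, length.out = 5)
  cat <- toy_catalog(starts, starts + 200)
  calls <- calls_from_sets(list(p1 = cat$sts_id), cat$sts_id)
  meta <- data.frame(sample_id = "p1", group = "case")
  cen <- unique_deletion_census(calls, cat, meta)
  expect_equal(cen$pre_merge, 5)
  expect_equal(cen$post_merge, 1)

  # identical single-STS deletions in two samples dedupe to one
  calls2 <- calls_from_sets(list(a = "S03", b = "S03"), cat$sts_id)
  meta2 <- data.frame(sample_id = c("a", "b"), group = "control")
  cen2 <- unique_deletion_census(calls2, cat, meta2)
  expect_equal(cen2$pre_merge, 1)
  expect_equal(cen2$post_merge, 1)

  expect_error(unique_deletion_census(
    calls_from_sets(list(zz = "S01"), cat$sts_id), cat, meta2),
    class = "ycm_lookup_error")
})

test_that("cases with long planted deletions shrink more under merging", {
  pl <- default_pipeline()
  cen <- unique_deletion_census(pl$calls, pl$sim$catalog, pl$sim$metadata)
  ratio <- cen$post_merge / cen$pre_merge
  expect_lt(ratio[cen$group == "case"], ratio[cen$group == "control"])
})

test_that("QC-removed STSs neither join nor break runs", {
  cat <- toy_catalog(c(10000, 50000, 90000), c(10200, 50200, 90200))
  # S02 was removed by QC: it has no call row at all
  calls <- data.frame(sample_id = "p", sts_id = c("S01", "S03"),
                      state = "deleted")
  class(calls) <- c("call_matrix", "data.frame")
  iv <- merge_calls(calls, cat)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$member_sts, "S01,S03")
})

test_that("deletion patterns match on marker states", {
  sts <- c("sY1191", "sY1192", "sY1291", "sY1189")
  calls <- calls_from_sets(list(b2b3 = "sY1191",
                                grgr = "sY1291",
                                none = character(0)), sts)
  pat <- system.file("extdata", "known_deletions.json", package = "ycmscan")
  res <- match_deletion_patterns(calls, pat)
  hit <- function(s) res$pattern[res$sample_id == s & res$match]
  expect_equal(hit("b2b3"), "b2/b3")
  expect_equal(hit("grgr"), "gr/gr")
  expect_length(hit("none"), 0)
})
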