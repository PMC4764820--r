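test_that("group summary derives the printed one-decimal means", {
  # ratios of published counts: 1020 deletions / 87 carriers etc.
  expect_equal(round_half_up(1020 / 87, 1), 11.7)
  expect_equal(round_half_up(264 / 71, 1), 3.7)
  expect_equal(round_half_up(481 / 87, 1), 5.5)
  expect_equal(round_half_up(98 / 71, 1), 1.4)
  expect_equal(round_half_up(1020 / 481, 1), 2.1)
  expect_equal(round_half_up(264 / 98, 1), 2.7)
  expect_equal(fold_increase(11.7, 3.7), 3.2)
})

test_that("summarize_groups reconciles counts and handles empty groups", {
  cat <- toy_catalog(seq(1e4, by = 2e5, length.out = 6))
  calls <- calls_from_sets(list(a = c("S01", "S02"), b = "S01",
                                c = character(0), d = character(0)),
                           cat$sts_id)
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     group = c("case", "case", "case", "control"))
  gs <- summarize_groups(calls, cat, meta)
  case <- gs[gs$group == "case", ]
  expect_equal(case$n_samples, 3)
  expect_equal(case$n_deleted_individuals, 2)
  expect_equal(case$n_total_deletions, 3)
  expect_equal(case$n_unique_deleted_sts, 2)
  expect_equal(case$mean_deletions_per_deleted_individual,
               round_half_up(3 / 2, 1))
  expect_equal(case$mean_individuals_per_unique_deletion,
               round_half_up(3 / 2, 1))
  ctrl <- gs[gs$group == "control", ]
  expect_equal(ctrl$n_total_deletions, 0)
  expect_true(is.na(ctrl$mean_deletions_per_deleted_individual))

  # self-consistency: reported means re-derive from integer counts
  expect_equal(case$mean_unique_per_deleted_individual,
               round_half_up(case$n_unique_deleted_sts /
                               case$n_deleted_individuals, 1))
})

test_that("chi-square without correction matches explicit summation", {
  set.seed(60)
  for (rep in 1:60) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- chisq_2x2(tab)
    expect_equal(unname(got$statistic), oracle_chisq_2x2(tab),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give a zero chi-square statistic", {
  cat <- toy_catalog(seq(1e4, by = 2e5, length.out = 4))
  calls <- calls_from_sets(list(a = "S01", b = character(0),
                                c = "S02", d = character(0)),
                           cat$sts_id)
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     group = c("case", "case", "control", "control"))
  res <- compare_groups(calls, meta)
  carriers <- res[res$test == "carriers", ]
  expect_equal(carriers$statistic, 0)
  expect_equal(carriers$p, 1)
})

test_that("Kruskal-Wallis matches the rank-arithmetic oracle", {
  x1 <- c(1, 1, 1, 2); x2 <- c(3, 3, 3, 3)
  # hand rank computation with tie correction:
  # ranks 2,2,2,4 | 6.5 x4; H = 12/(8*9)*(10^2/4 + 26^2/4) - 27 = 5.3333
  # tie factor 1 - (24 + 60)/504 -> H_corr = 6.4
  kt <- kruskal.test(list(x1, x2))
  expect_equal(unname(kt$statistic), 6.4, tolerance = 1e-10)

  cat <- toy_catalog(seq(1e4, by = 2e5, length.out = 8))
  calls <- calls_from_sets(
    list(a = c("S01", "S02"), b = "S03", c = "S04", d = "S05"),
    cat$sts_id)
  meta <- data.frame(sample_id = letters[1:4],
                     group = c("case", "case", "control", "control"))
  res <- compare_groups(calls, meta)
  kw <- res[res$test == "deletions_per_individual", ]
  manual <- kruskal.test(list(c(2, 1), c(1, 1)))
  expect_equal(kw$statistic, unname(manual$statistic))
})

test_that("simulated excess case burden is detected with power", {
  pl <- default_pipeline()
  res <- compare_groups(pl$calls, pl$sim$metadata,
                        n_qualified_sts = ncol(pl$qc$matrix$depth))
  expect_lt(res$p[res$test == "unique_sts"], 0.01)
  expect_lt(res$p[res$test == "deletions_per_individual"], 0.01)
})

test_that("annotation enrichment detects planted intragenic excess", {
  set.seed(61)
  n <- 200
  starts <- seq(1e4, by = 1.5e5, length.out = n)
  anno <- c(rep("coding", 30), rep("UTR", 20), rep("intron", 60),
            rep("intergenic", 90))
  cat <- toy_catalog(starts, annotation = sample(anno))
  intragenic <- cat$sts_id[cat$annotation != "intergenic"]
  intergenic <- cat$sts_id[cat$annotation == "intergenic"]
  case_del <- c(sample(intragenic, 80), sample(intergenic, 20))
  ctrl_del <- c(sample(intragenic, 10), sample(intergenic, 80))
  calls <- calls_from_sets(list(p1 = case_del, c1 = ctrl_del), cat$sts_id)
  meta <- data.frame(sample_id = c("p1", "c1"),
                     group = c("case", "control"))
  enr <- annotation_enrichment(calls, cat, meta)
  row <- enr[enr$category == "intragenic", ]
  expect_lt(row$p, 0.001)
  # oracle on the constructed 2x2
  tab <- matrix(c(80, 20, 10, 80), 2)
  expect_equal(row$statistic, oracle_chisq_2x2(tab), tolerance = 1e-12)
  # counts per category sum to the group's unique deleted STSs
  cats <- c("coding", "UTR", "intron", "intergenic")
  expect_equal(sum(enr$n_case[enr$category %in% cats]), 100)
  expect_equal(sum(enr$n_control[enr$category %in% cats]), 90)
})

test_that("all-intergenic deletions skip or null the gene categories", {
  starts <- seq(1e4, by = 1.5e5, length.out = 10)
  cat <- toy_catalog(starts, annotation = "intergenic")
  calls <- calls_from_sets(list(p1 = c("S01", "S02"), c1 = "S03"),
                           cat$sts_id)
  meta <- data.frame(sample_id = c("p1", "c1"),
                     group = c("case", "control"))
  enr <- annotation_enrichment(calls, cat, meta)
  gene_rows <- enr[enr$category %in% c("coding", "UTR", "intron",
                                       "intragenic"), ]
  expect_true(all(gene_rows$note == "skipped: zero margin" |
                    (!is.na(gene_rows$p) & gene_rows$p == 1)))
  expect_true(all(gene_rows$n_case == 0 & gene_rows$n_control == 0))
})

test_that("spectra conserve mass and ignore sample order", {
  pl <- default_pipeline()
  sp <- deletion_spectra(pl$calls, pl$sim$metadata)
  for (g in unique(pl$sim$metadata$group)) {
    sub <- sp$per_individual[sp$per_individual$group == g, ]
    expect_equal(sum(sub$proportion), 1)
    expect_equal(sum(sub$n_individuals * sub$n_deleted_sts),
                 sum(pl$calls$state == "deleted" &
                       pl$calls$sample_id %in%
                         pl$sim$metadata$sample_id[pl$sim$metadata$group == g]))
  }
  shuffled <- pl$calls[sample(nrow(pl$calls)), ]
  class(shuffled) <- class(pl$calls)
  sp2 <- deletion_spectra(shuffled, pl$sim$metadata)
  expect_equal(sp2, sp)
})
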