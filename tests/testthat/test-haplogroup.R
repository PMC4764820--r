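default_tree <- function() {
  load_haplogroup_tree(system.file("extdata", "haplogroup_tree.json",
                                   package = "ycmscan"))
}

geno_for <- function(tree, node, drop = character(0)) {
  markers <- ycmscan:::tree_markers(tree)
  g <- setNames(character(length(markers)), markers)
  for (nd in tree$nodes) {
    for (m in nd$markers) g[m$marker] <- m$ancestral
  }
  if (!is.na(node)) {
    for (nm in ycmscan:::tree_path(tree, node)) {
      for (m in tree$nodes[[nm]]$markers) g[m$marker] <- m$derived
    }
  }
  g[drop] <- NA_character_
  g
}

test_that("tree validation catches structural defects", {
  nodes <- list(list(name = "Y", parent = NULL, markers = list()),
                list(name = "A", parent = "Y",
                     markers = list(list(marker = "m1", ancestral = "A",
                                         derived = "G"))))
  expect_s3_class(load_haplogroup_tree(nodes), "haplogroup_tree")
  expect_error(load_haplogroup_tree(c(nodes, nodes[2])), "duplicate",
               class = "ycm_config_error")
  two_roots <- nodes; two_roots[[2]]$parent <- NULL
  expect_error(load_haplogroup_tree(two_roots), "one root",
               class = "ycm_config_error")
  cyc <- list(list(name = "Y", parent = NULL, markers = list()),
              list(name = "A", parent = "B", markers = list()),
              list(name = "B", parent = "A", markers = list()))
  expect_error(load_haplogroup_tree(cyc), class = "ycm_config_error")
})

test_that("assignment descends to the deepest derived node", {
  tree <- default_tree()
  # derived through O and O2* only -> assigned O2*, full path recorded
  a <- assign_haplogroup(tree, geno_for(tree, "O2*"))
  expect_equal(a$haplogroup, "O2*")
  expect_equal(a$path, c("Y", "O", "O2*"))

  # deeper lineage
  expect_equal(assign_haplogroup(tree, geno_for(tree, "O2a"))$haplogroup,
               "O2a")

  # ancestral everywhere -> unassigned at the root
  a0 <- assign_haplogroup(tree, geno_for(tree, NA))
  expect_true(is.na(a0$haplogroup))

  # missing marker on the frontier -> not confidently assignable
  am <- assign_haplogroup(tree, geno_for(tree, "N", drop = "MK_N"))
  expect_true(is.na(am$haplogroup))

  # tree marker absent from the genotype schema -> config error
  g <- geno_for(tree, "N")
  expect_error(assign_haplogroup(tree, g[names(g) != "MK_N"]),
               "MK_N", class = "ycm_config_error")
})

test_that("assignment is monotone under information loss", {
  tree <- default_tree()
  full <- assign_haplogroup(tree, geno_for(tree, "O2a"))
  markers <- names(geno_for(tree, "O2a"))
  for (m in markers) {
    red <- assign_haplogroup(tree, geno_for(tree, "O2a", drop = m))
    if (!is.na(red$haplogroup)) {
      expect_true(red$haplogroup %in% full$path)
      expect_lte(length(red$path), length(full$path))
    }
  }
})

test_that("simulated genotypes recover planted haplogroups", {
  sim <- simulate_cohort(sim_scenario(n_cases = 25, n_controls = 25,
                                      n_sts = 40, seed = 21))
  asg <- assign_haplogroups(sim$tree, sim$genotypes)
  expect_equal(setNames(asg$haplogroup, asg$sample_id),
               sim$haplogroups)

  # 10% marker dropout: assignments, when made, are ancestors of (or
  # equal to) the planted node
  simd <- simulate_cohort(sim_scenario(n_cases = 25, n_controls = 25,
                                       n_sts = 40, marker_dropout = 0.1,
                                       seed = 22))
  asgd <- assign_haplogroups(simd$tree, simd$genotypes)
  for (i in seq_len(nrow(asgd))) {
    h <- asgd$haplogroup[i]
    if (is.na(h)) next
    planted_path <- ycmscan:::tree_path(simd$tree,
                                        simd$haplogroups[asgd$sample_id[i]])
    expect_true(h %in% planted_path)
  }
})

test_that("one-sided Fisher matches exhaustive hypergeometric summation", {
  set.seed(23)
  for (rep in 1:50) {
    n1 <- sample(5:120, 1); n2 <- sample(5:80, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    got <- fisher_one_sided(a, b, n1, n2)$p
    expect_equal(got, oracle_fisher_one_sided(a, b, n1, n2),
                 tolerance = 1e-12)
  }
  # printed 2x2 for the protective O lineage: 0/589 cases vs 9/569 controls
  ft <- fisher_one_sided(0, 9, 589, 569)
  expect_equal(ft$direction, "depletion")
  expect_equal(ft$p, 0.0016164, tolerance = 1e-4)
  # proportional table keeps the point mass: p ~ 0.54
  expect_equal(fisher_one_sided(50, 50, 500, 500)$p, 0.5419, tolerance = 1e-3)
  # degenerate zero margin
  expect_equal(fisher_one_sided(0, 0, 10, 10)$p, 1.0)
})

test_that("haplogroup association builds the per-lineage table", {
  asg <- data.frame(sample_id = sprintf("s%03d", 1:60),
                    haplogroup = rep(c("O3a", "N", NA), times = c(40, 15, 5)))
  meta <- data.frame(sample_id = asg$sample_id,
                     group = rep(c("case", "control"), 30))
  res <- haplogroup_association(asg, meta)
  expect_setequal(res$haplogroup, c("O3a", "N"))
  manual <- fisher_one_sided(sum(asg$haplogroup == "N" & meta$group == "case",
                                 na.rm = TRUE),
                             sum(asg$haplogroup == "N" & meta$group == "control",
                                 na.rm = TRUE),
                             sum(!is.na(asg$haplogroup) & meta$group == "case"),
                             sum(!is.na(asg$haplogroup) & meta$group == "control"))
  expect_equal(res$p[res$haplogroup == "N"], manual$p)
})

test_that("deletion enrichment flags a founder deletion and calibrates on null", {
  # an STS deleted in every haplogroup-N sample and nowhere else
  hg <- rep(c("N", "O3a", "C"), times = c(12, 70, 18))
  asg <- data.frame(sample_id = sprintf("s%03d", seq_along(hg)),
                    haplogroup = hg)
  calls <- calls_from_sets(
    setNames(lapply(hg == "N", function(x) if (x) "sY1191" else character(0)),
             asg$sample_id),
    c("sY1191", "other1"))
  enr <- haplogroup_deletion_enrichment(calls, asg)
  pN <- enr$p[enr$haplogroup == "N" & enr$sts_id == "sY1191"]
  expect_lt(pN, 0.001)
  expect_equal(enr$observed[enr$haplogroup == "N" & enr$sts_id == "sY1191"],
               12)

  # single-haplogroup cohort: expected equals observed, p = 1
  asg1 <- data.frame(sample_id = c("a", "b"), haplogroup = "N")
  calls1 <- calls_from_sets(list(a = "sY1191", b = character(0)), "sY1191")
  enr1 <- haplogroup_deletion_enrichment(calls1, asg1)
  expect_equal(enr1$p, 1)
  expect_equal(enr1$observed, enr1$expected)

  # null calibration: proportional spread stays non-significant >= 90%
  set.seed(24)
  hits <- 0; sims <- 60
  for (k in seq_len(sims)) {
    hgk <- sample(rep(c("A1", "B1"), times = c(30, 30)))
    asgk <- data.frame(sample_id = sprintf("s%03d", 1:60), haplogroup = hgk)
    carriers <- sample(asgk$sample_id, 12)
    callsk <- calls_from_sets(
      setNames(lapply(asgk$sample_id %in% carriers,
                      function(x) if (x) "X1" else character(0)),
               asgk$sample_id), "X1")
    ek <- haplogroup_deletion_enrichment(callsk, asgk)
    if (any(ek$p < 0.05)) hits <- hits + 1
  }
  expect_lte(hits / sims, 0.10 + 2 * sqrt(0.1 * 0.9 / sims))
})

test_that("every simulated haplogroup-N chromosome carries the b2/b3 pattern", {
  pl <- default_pipeline()
  n_samples <- names(pl$sim$haplogroups)[pl$sim$haplogroups == "N"]
  b2b3 <- c("DYF155S1", "RH102047", "sY1191")
  expect_true(all(pl$sim$truth[n_samples, b2b3]))
})
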