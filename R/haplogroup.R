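#' Load and validate a haplogroup tree
#'
#' The tree is a rooted hierarchy of haplogroup nodes, each defined by one
#' or more SNP markers whose derived allele marks membership. It ships as
#' an editable JSON config (see
#' `system.file("extdata", "haplogroup_tree.json", package = "ycmscan")`,
#' which carries the nine major East-Asian haplogroups J, T, N, Q, C, D,
#' R, G, O and the O sub-lineages with placeholder marker ids; curating a
#' real marker set is the user's responsibility).
#'
#' @param x path to a JSON file, or a list of node records; each record
#'   has `name`, `parent` (`NA`/`NULL` for the root) and `markers`, a list
#'   of records with `marker`, `ancestral`, `derived`.
#' @return a `haplogroup_tree` object.
#' @export
load_haplogroup_tree <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- jsonlite::read_json(x, simplifyVector = FALSE)
  }
  nodes <- lapply(x, function(n) {
    list(name = n$name,
         parent = if (is.null(n$parent) || is.na(n$parent)) NA_character_ else n$parent,
         markers = lapply(n$markers %||% list(), function(m) {
           list(marker = m$marker, ancestral = m$ancestral,
                derived = m$derived)
         }))
  })
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes))) {
    ycm_stop("duplicate node names in haplogroup tree", "ycm_config_error")
  }
  roots <- names(nodes)[vapply(nodes, function(n) is.na(n$parent), TRUE)]
  if (length(roots) != 1) {
    ycm_stop("haplogroup tree must have exactly one root", "ycm_config_error")
  }
  for (n in nodes) {
    if (!is.na(n$parent) && !(n$parent %in% names(nodes))) {
      ycm_stop(sprintf("node '%s' has unknown parent '%s'", n$name, n$parent),
               "ycm_config_error")
    }
  }
  # acyclicity: every node must reach the root
  for (n in names(nodes)) {
    seen <- character(0)
    cur <- n
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) {
        ycm_stop("haplogroup tree contains a cycle", "ycm_config_error")
      }
      seen <- c(seen, cur)
      cur <- nodes[[cur]]$parent
    }
  }
  structure(list(nodes = nodes, root = roots), class = "haplogroup_tree")
}

tree_children <- function(tree, name) {
  names(tree$nodes)[vapply(tree$nodes, function(n)
    identical(n$parent, name), TRUE)]
}

tree_markers <- function(tree) {
  unique(unlist(lapply(tree$nodes, function(n)
    vapply(n$markers, `[[`, "", "marker"))))
}

tree_path <- function(tree, node) {
  path <- node
  while (!is.na(tree$nodes[[node]]$parent)) {
    node <- tree$nodes[[node]]$parent
    path <- c(node, path)
  }
  path
}

# status of one child node for one sample: "derived" (all defining markers
# present and derived), "missing" (no ancestral call but >=1 missing), or
# "ancestral" (>=1 ancestral call)
node_status <- function(node, geno) {
  st <- "derived"
  for (m in node$markers) {
    allele <- geno[[m$marker]]
    if (is.null(allele) || is.na(allele) || allele == "") {
      if (st == "derived") st <- "missing"
    } else if (allele == m$derived) {
      # consistent with membership
    } else {
      return("ancestral")
    }
  }
  st
}

#' Assign one sample to its haplogroup
#'
#' Depth-first descent from the root: a child node is entered iff all of
#' its defining markers are present and derived; the deepest entered node
#' is the assignment. If descent stops because a frontier child's markers
#' are missing (rather than ancestral), the sample cannot be confidently
#' placed and is returned unassigned; a sample ancestral at every
#' root-level branch is likewise unassigned.
#'
#' @param tree a [load_haplogroup_tree()] result.
#' @param genotypes named character vector or single-row data frame of
#'   marker calls (`A`/`C`/`G`/`T`, `NA` or `""` for missing) for one
#'   sample.
#' @return list with `haplogroup` (node name or `NA` for unassigned) and
#'   `path` (root-to-node names, `character(0)` if unassigned).
#' @export
assign_haplogroup <- function(tree, genotypes) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (is.data.frame(genotypes)) genotypes <- unlist(genotypes[1, ])
  geno <- as.list(genotypes)
  absent <- setdiff(tree_markers(tree), names(geno))
  if (length(absent) > 0) {
    ycm_stop(sprintf("tree marker(s) absent from genotype table: %s",
                     paste(absent, collapse = ", ")),
             "ycm_config_error")
  }
  cur <- tree$root
  repeat {
    kids <- tree_children(tree, cur)
    if (length(kids) == 0) break
    st <- vapply(kids, function(k) node_status(tree$nodes[[k]], geno), "")
    if (any(st == "derived")) {
      cur <- kids[which(st == "derived")[1]]
    } else if (any(st == "missing")) {
      # cannot rule the deeper branch in or out: not confidently assigned
      return(list(haplogroup = NA_character_, path = character(0)))
    } else {
      break
    }
  }
  if (cur == tree$root) {
    return(list(haplogroup = NA_character_, path = character(0)))
  }
  list(haplogroup = cur, path = tree_path(tree, cur))
}

#' Assign all samples of a genotype table
#'
#' @param tree a [load_haplogroup_tree()] result.
#' @param genotypes data frame, samples in rows (rownames or a
#'   `sample_id` column), markers in columns.
#' @return data frame: `sample_id`, `haplogroup` (`NA` = unassigned),
#'   `path` (slash-joined).
#' @export
assign_haplogroups <- function(tree, genotypes) {
  if ("sample_id" %in% names(genotypes)) {
    ids <- genotypes$sample_id
    genotypes <- genotypes[, setdiff(names(genotypes), "sample_id"),
                           drop = FALSE]
  } else {
    ids <- rownames(genotypes)
  }
  res <- lapply(seq_along(ids), function(i) {
    a <- assign_haplogroup(tree, genotypes[i, , drop = FALSE])
    data.frame(sample_id = ids[i], haplogroup = a$haplogroup,
               path = paste(a$path, collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Hypergeometric tail probability in the direction of the observed
#' imbalance: with `a` case carriers out of `n_case` cases and `b` control
#' carriers out of `n_control` controls, the lower tail `P(X <= a)` when
#' the case carrier rate is at or below the control rate, the upper tail
#' `P(X >= a)` otherwise (the point mass is always included).
#'
#' @param a,b carrier counts in cases and controls.
#' @param n_case,n_control group sizes.
#' @return list with `p`, `direction` (`"depletion"`/`"enrichment"`).
#' @export
fisher_one_sided <- function(a, b, n_case, n_control) {
  stopifnot(a >= 0, b >= 0, n_case >= a, n_control >= b)
  K <- a + b                       # total carriers
  N <- n_case + n_control
  if (n_case == 0 || n_control == 0) {
    ycm_stop("both groups must be non-empty", "ycm_domain_error")
  }
  rate_case <- a / n_case
  rate_ctrl <- b / n_control
  if (rate_case <= rate_ctrl) {
    list(p = phyper(a, K, N - K, n_case), direction = "depletion")
  } else {
    list(p = phyper(a - 1, K, N - K, n_case, lower.tail = FALSE),
         direction = "enrichment")
  }
}

#' Haplogroup-phenotype association
#'
#' Per haplogroup, a 2x2 table of carriers vs non-carriers crossed with
#' case vs control, tested with a one-sided Fisher exact test in the
#' direction of the observed imbalance (one p per haplogroup, mirroring a
#' per-lineage association table).
#'
#' @param assignments an [assign_haplogroups()] result; unassigned samples
#'   are excluded.
#' @param metadata data frame with `sample_id`, `group`.
#' @param case,control group labels to contrast.
#' @return data frame: `haplogroup`, `n_case`, `n_control`, `direction`,
#'   `p`.
#' @export
haplogroup_association <- function(assignments, metadata,
                                   case = "case", control = "control") {
  m <- merge(assignments, metadata, by = "sample_id")
  m <- m[!is.na(m$haplogroup) & m$group %in% c(case, control), ]
  if (length(unique(m$group)) < 2) {
    ycm_stop("need both groups among assigned samples", "ycm_domain_error")
  }
  n_case <- sum(m$group == case)
  n_control <- sum(m$group == control)
  res <- lapply(sort(unique(m$haplogroup)), function(h) {
    a <- sum(m$haplogroup == h & m$group == case)
    b <- sum(m$haplogroup == h & m$group == control)
    ft <- fisher_one_sided(a, b, n_case, n_control)
    data.frame(haplogroup = h, n_case = a, n_control = b,
               direction = ft$direction, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Haplogroup-deletion over/under-representation
#'
#' For each (haplogroup, STS) with at least one deletion among assigned
#' samples: the observed deletion count in the haplogroup, the expected
#' count under proportional allocation (total deletions of the STS times
#' haplogroup share of the cohort), and a two-sided exact binomial p-value
#' of the observed count against that expectation. A founder deletion
#' riding on one lineage (e.g. b2/b3 on haplogroup N) shows up as strong
#' over-representation.
#'
#' @param calls a `call_matrix`.
#' @param assignments an [assign_haplogroups()] result.
#' @return data frame: `haplogroup`, `sts_id`, `observed`, `expected`,
#'   `total`, `p`.
#' @export
haplogroup_deletion_enrichment <- function(calls, assignments) {
  asg <- assignments[!is.na(assignments$haplogroup), ]
  if (nrow(asg) == 0) {
    ycm_stop("no assigned samples", "ycm_domain_error")
  }
  calls <- calls[calls$sample_id %in% asg$sample_id, ]
  del <- calls[calls$state == "deleted", ]
  if (nrow(del) == 0) {
    return(data.frame(haplogroup = character(0), sts_id = character(0),
                      observed = integer(0), expected = numeric(0),
                      total = integer(0), p = numeric(0)))
  }
  N <- nrow(asg)
  hg_of <- setNames(asg$haplogroup, asg$sample_id)
  hg_sizes <- table(asg$haplogroup)
  res <- list()
  for (sts in unique(del$sts_id)) {
    carriers <- del$sample_id[del$sts_id == sts]
    total <- length(carriers)
    obs_by_hg <- table(hg_of[carriers])
    for (h in names(hg_sizes)) {
      obs <- if (h %in% names(obs_by_hg)) as.integer(obs_by_hg[[h]]) else 0L
      share <- as.integer(hg_sizes[[h]]) / N
      # as.numeric: binom.test returns a logical p.value when p is 0 or 1
      p <- as.numeric(binom.test(obs, total, p = share)$p.value)
      res[[length(res) + 1]] <- data.frame(
        haplogroup = h, sts_id = sts, observed = obs,
        expected = total * share, total = total, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read / write a marker genotype table
#'
#' TSV with a `sample_id` column and one column per marker; empty cells
#' are missing calls.
#'
#' @param path file path.
#' @param genotypes data frame as returned by [read_genotypes()].
#' @return data frame (read) or `path` invisibly (write).
#' @export
read_genotypes <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  write.table(genotypes, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
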