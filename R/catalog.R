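#' @useDynLib ycmscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile median sd dnorm pnorm phyper dhyper chisq.test
#'   kruskal.test binom.test rnbinom rlnorm rpois runif setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# Controlled vocabularies for catalog columns.
STS_COPY_CLASSES <- c("single", "multi")
STS_REGIONS <- c("AZFa", "AZFb", "AZFc", "Yp", "other")
STS_ANNOTATIONS <- c("coding", "UTR", "intron", "intergenic")

CATALOG_COLUMNS <- c("chrom", "start", "end", "sts_id",
                     "copy_class", "region", "annotation", "gene")

#' Construct an STS catalog
#'
#' An STS catalog is the coordinate frame every other module keys against:
#' one row per sequence-tagged site with its genomic interval (0-based
#' half-open, BED convention), copy class (`single` = unique mapping
#' location, `multi` = multiple alignment positions), region label
#' (AZFa/AZFb/AZFc/Yp/other) and exclusive gene-annotation category
#' (`coding` > `UTR` > `intron` > `intergenic` precedence upstream).
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `sts_id`,
#'   `copy_class`, `region`, `annotation` and optionally `gene`.
#' @return an `sts_catalog` object (a validated, coordinate-sorted data
#'   frame).
#' @export
sts_catalog <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(CATALOG_COLUMNS, "gene"), names(df))
  if (length(missing_cols) > 0) {
    ycm_stop(sprintf("catalog is missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "ycm_format_error")
  }
  if (!("gene" %in% names(df))) df$gene <- NA_character_
  df <- df[, CATALOG_COLUMNS]
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$sts_id <- as.character(df$sts_id)

  dup <- df$sts_id[duplicated(df$sts_id)]
  if (length(dup) > 0) {
    ycm_stop(sprintf("duplicate sts_id in catalog: %s",
                     paste(unique(dup), collapse = ", ")),
             "ycm_validation_error")
  }
  bad <- df$sts_id[!(df$start < df$end)]
  if (length(bad) > 0) {
    ycm_stop(sprintf("start must be < end; offending sts_id: %s",
                     paste(bad, collapse = ", ")),
             "ycm_validation_error")
  }
  if (!all(df$copy_class %in% STS_COPY_CLASSES)) {
    ycm_stop("copy_class must be 'single' or 'multi'", "ycm_validation_error")
  }
  if (!all(df$annotation %in% STS_ANNOTATIONS)) {
    ycm_stop(sprintf("annotation must be one of: %s",
                     paste(STS_ANNOTATIONS, collapse = ", ")),
             "ycm_validation_error")
  }
  if (!all(df$region %in% STS_REGIONS)) {
    ycm_stop(sprintf("region must be one of: %s",
                     paste(STS_REGIONS, collapse = ", ")),
             "ycm_validation_error")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sts_catalog", "data.frame")
  df
}

#' Load an STS catalog from a TSV file
#'
#' Expects a tab-separated file with header
#' `chrom start end sts_id copy_class region annotation gene`
#' (coordinates 0-based half-open).
#'
#' @param path path to the catalog TSV.
#' @return an [sts_catalog()] object.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    ycm_stop(sprintf("catalog file not found: %s", path), "ycm_format_error")
  }
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  sts_catalog(df)
}

#' Write an STS catalog to a TSV file
#'
#' @param catalog an [sts_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "sts_catalog"))
  write.table(as.data.frame(catalog), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export catalog intervals as 6-column BED
#'
#' @param catalog an [sts_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
catalog_to_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "sts_catalog"))
  bed <- data.frame(chrom = catalog$chrom,
                    start = format(catalog$start, scientific = FALSE, trim = TRUE),
                    end = format(catalog$end, scientific = FALSE, trim = TRUE),
                    name = catalog$sts_id,
                    score = 0L,
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

catalog_lookup <- function(catalog, id) {
  i <- match(id, catalog$sts_id)
  if (is.na(i)) {
    ycm_stop(sprintf("unknown sts_id: %s", id), "ycm_lookup_error")
  }
  i
}

#' STS records strictly between two catalog entries
#'
#' Returns every catalog record lying entirely within the gap between `a`'s
#' end and `b`'s start, in coordinate order. This is the support query for
#' deletion merging: a run of deleted STSs may only be connected if every
#' record between consecutive members is deleted or a non-deleted
#' multi-copy site.
#'
#' @param catalog an [sts_catalog()].
#' @param a,b `sts_id`s on the same chromosome with `a` upstream of `b`.
#' @return the interior records as an `sts_catalog` slice (possibly empty).
#' @export
neighbors_between <- function(catalog, a, b) {
  stopifnot(inherits(catalog, "sts_catalog"))
  ia <- catalog_lookup(catalog, a)
  ib <- catalog_lookup(catalog, b)
  ra <- catalog[ia, ]
  rb <- catalog[ib, ]
  if (ra$chrom != rb$chrom) {
    ycm_stop(sprintf("%s and %s lie on different chromosomes", a, b),
             "ycm_domain_error")
  }
  if (!(ra$start < rb$start)) {
    ycm_stop(sprintf("%s is not upstream of %s", a, b), "ycm_domain_error")
  }
  sel <- catalog$chrom == ra$chrom &
    catalog$start >= ra$end & catalog$end <= rb$start
  out <- catalog[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sts_catalog <- function(x, ...) {
  cat(sprintf("STS catalog: %d sites on %s (%d single-copy, %d multi-copy)\n",
              nrow(x), paste(unique(x$chrom), collapse = ","),
              sum(x$copy_class == "single"), sum(x$copy_class == "multi")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}
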