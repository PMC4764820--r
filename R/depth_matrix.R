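#' Construct a depth matrix
#'
#' Container for the per-sample, per-STS mean base depth `D[i, j]`: the mean
#' depth over all bases of STS `j` in sample `i`. Rows are samples, columns
#' are STSs. The `normalized` flag records whether each row has been divided
#' by its own mean (after which row means are exactly 1).
#'
#' @param depth numeric matrix with sample ids as rownames and STS ids as
#'   colnames; all entries finite and non-negative.
#' @param normalized logical; whether depths are per-sample normalized.
#' @return a `depth_matrix` object.
#' @export
depth_matrix <- function(depth, normalized = FALSE) {
  depth <- as.matrix(depth)
  if (is.null(rownames(depth)) || is.null(colnames(depth))) {
    ycm_stop("depth matrix needs sample rownames and STS colnames",
             "ycm_validation_error")
  }
  if (anyDuplicated(rownames(depth)) || anyDuplicated(colnames(depth))) {
    ycm_stop("duplicate sample or STS ids in depth matrix",
             "ycm_validation_error")
  }
  storage.mode(depth) <- "double"
  if (any(!is.finite(depth)) || any(depth < 0)) {
    ycm_stop("depth matrix entries must be finite and >= 0",
             "ycm_validation_error")
  }
  structure(list(depth = depth, normalized = isTRUE(normalized)),
            class = "depth_matrix")
}

#' @export
dim.depth_matrix <- function(x) dim(x$depth)

sample_ids <- function(dm) rownames(dm$depth)
sts_ids <- function(dm) colnames(dm$depth)

#' Read a depth matrix from TSV
#'
#' First column is the sample id; remaining columns are STS ids with
#' floating-point mean depths.
#'
#' @param path input TSV path.
#' @param normalized whether the stored values are already normalized.
#' @return a [depth_matrix()].
#' @export
read_depth_matrix <- function(path, normalized = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  depth_matrix(m, normalized = normalized)
}

#' Write a depth matrix to TSV
#'
#' @param dm a [depth_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "depth_matrix"))
  df <- data.frame(sample_id = rownames(dm$depth), dm$depth,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

subset_depth <- function(dm, keep_samples = NULL, keep_sts = NULL) {
  m <- dm$depth
  if (!is.null(keep_samples)) m <- m[keep_samples, , drop = FALSE]
  if (!is.null(keep_sts)) m <- m[, keep_sts, drop = FALSE]
  depth_matrix(m, normalized = dm$normalized)
}

#' Average per-base depth over catalog intervals
#'
#' Convenience I/O for one sample: consumes a `samtools depth`-style
#' three-column table (chrom, 1-based position, depth) and averages depth
#' over each catalog interval, counting uncovered bases as zero. Depth
#' extraction from alignments is upstream of this package; this helper only
#' adapts that standard text format to the matrix input.
#'
#' @param per_base data frame (or TSV path) with columns chrom, pos
#'   (1-based), depth.
#' @param catalog an [sts_catalog()].
#' @return named numeric vector of mean depths, one entry per catalog STS.
#' @export
mean_depth_from_per_base <- function(per_base, catalog) {
  stopifnot(inherits(catalog, "sts_catalog"))
  if (is.character(per_base)) {
    per_base <- read.delim(per_base, header = FALSE, sep = "\t",
                           col.names = c("chrom", "pos", "depth"))
  }
  out <- numeric(nrow(catalog))
  names(out) <- catalog$sts_id
  for (k in seq_len(nrow(catalog))) {
    rec <- catalog[k, ]
    # 0-based half-open interval [start, end) -> 1-based positions start+1 .. end
    sel <- per_base$chrom == rec$chrom &
      per_base$pos > rec$start & per_base$pos <= rec$end
    out[k] <- sum(per_base$depth[sel]) / (rec$end - rec$start)
  }
  out
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("depth matrix: %d samples x %d STSs (%s)\n",
              nrow(x$depth), ncol(x$depth),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}
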