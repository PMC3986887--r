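#' @importFrom GenomicRanges GRanges start end strand seqnames findOverlaps
#'   countOverlaps promoters resize width mcols
#' @importFrom S4Vectors mcols<-
#' @importFrom BiocGenerics start<-
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats complete.cases cor median pchisq pt qnorm rbinom
#'   rnorm rpois runif sd setNames t.test binom.test
#' @importFrom utils read.delim write.table
NULL

#' Average per-sample profiles into cell-type-class profiles
#'
#' Each class value is the arithmetic mean over that class's non-missing
#' sample values (missing only when all samples of the class are missing).
#' When a coverage matrix is supplied (methylation data), class coverage is
#' the sum of the sample coverages.
#'
#' @param values Numeric matrix, features x samples; `NA` marks missing.
#' @param map Sample-class map: data.frame with columns `sample_id`,
#'   `class_id` and logical `normal_flag`.
#' @param coverage Optional matrix of read coverages, same shape as `values`
#'   (`NA` treated as 0 reads).
#' @return With `coverage = NULL`, a features x classes matrix. Otherwise a
#'   list with elements `values` and `coverage`.
#' @export
average_by_class <- function(values, map, coverage = NULL) {
  samples <- colnames(values)
  if (is.null(samples)) stop("values must have sample column names")
  unknown <- setdiff(samples, map$sample_id)
  if (length(unknown) > 0)
    stop("samples not present in the sample-class map: ",
         paste(unknown, collapse = ", "))
  cls <- map$class_id[match(samples, map$sample_id)]
  classes <- unique(map$class_id)
  avg <- vapply(classes, function(k) {
    sub <- values[, cls == k, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) avg <- matrix(avg, nrow = 1L)
  dimnames(avg) <- list(rownames(values), classes)
  if (is.null(coverage)) return(avg)
  cov <- vapply(classes, function(k) {
    sub <- coverage[, cls == k, drop = FALSE]
    sub[is.na(sub)] <- 0
    rowSums(sub)
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) cov <- matrix(cov, nrow = 1L)
  dimnames(cov) <- dimnames(avg)
  list(values = avg, coverage = cov)
}

#' Relative log expression (RLE) normalization
#'
#' Median-of-ratios scaling: the size factor of a sample is the median, over
#' features with positive counts in every sample, of its count divided by the
#' feature's geometric mean across samples; normalized values are counts
#' divided by the sample's size factor.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return A list with `normalized` (same shape as `counts`) and
#'   `size_factors` (one per sample).
#' @export
rle_normalize <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("RLE normalization needs at least one feature with positive counts in every sample")
  geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) median(col / geo))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Filter lowly expressed TSS clusters
#'
#' A TSS cluster is retained iff at least one non-missing class value reaches
#' `min_value` (clusters with all values below 1 are considered non-robust to
#' sequencing noise and removed).
#'
#' @param values Class-level normalized expression matrix, clusters x classes.
#' @param min_value Retention threshold (default 1).
#' @return Logical vector over rows: `TRUE` for retained clusters.
#' @export
filter_tss <- function(values, min_value = 1) {
  apply(values, 1, function(v) any(!is.na(v) & v >= min_value))
}

#' Define promoter regions around TSS clusters
#'
#' Extends every cluster 1500 bp upstream and 500 bp downstream relative to
#' its strand; the resulting span exceeds the cluster span by exactly
#' 2000 bp unless clipped at the chromosome start. Overlapping promoters are
#' kept independent (no merging).
#'
#' @param clusters A stranded `GRanges` of TSS clusters (metadata column
#'   `cluster_id` is propagated if present).
#' @return A `GRanges` of promoter regions, parallel to `clusters`.
#' @export
define_promoters <- function(clusters) {
  str <- as.character(strand(clusters))
  if (any(str == "*")) stop("clusters must be stranded")
  up <- ifelse(str == "+", 1500L, 500L)
  down <- ifelse(str == "+", 500L, 1500L)
  prom <- GRanges(seqnames(clusters),
                  IRanges(pmax(start(clusters) - up, 1L), end(clusters) + down),
                  strand = strand(clusters))
  mcols(prom) <- mcols(clusters)
  names(prom) <- names(clusters)
  prom
}

#' Apply coverage and completeness filters to methylation profiles
#'
#' Class values supported by fewer than `min_cov` reads are masked as
#' missing; a cytosine is retained iff it has non-missing values in at least
#' `ceiling(min_frac * n_classes)` classes (25 of 50 classes; 18 of 36 when
#' restricted to normal cell types).
#'
#' @param values Class-level percent-methylation matrix, cytosines x classes.
#' @param coverage Matching class-level summed read-coverage matrix.
#' @param min_cov Minimum reads per class value (default 10).
#' @param min_frac Minimum fraction of classes with data (default 0.5).
#' @return A list with `values` (masked matrix) and `retained` (logical per
#'   row).
#' @export
filter_cytosines <- function(values, coverage, min_cov = 10, min_frac = 0.5) {
  stopifnot(identical(dim(values), dim(coverage)))
  vals <- values
  vals[is.na(coverage) | coverage < min_cov] <- NA_real_
  need <- ceiling(min_frac * ncol(vals))
  retained <- rowSums(!is.na(vals)) >= need
  list(values = vals, retained = retained)
}

#' Methylation profile amplitude and differential-methylation flag
#'
#' Amplitude is the difference between the highest and lowest non-missing
#' class value of a methylation profile, in percentage points. A profile is
#' differentially methylated when its amplitude strictly exceeds
#' `min_amplitude` (50% of the maximal possible value by default), which
#' guards the correlation analysis against low-level experimental noise.
#'
#' @param x Numeric vector of class-level percent methylation (single
#'   profile).
#' @return `amplitude()`: the amplitude in percentage points (errors with
#'   fewer than 2 non-missing values). `profile_amplitudes()`: a vector of
#'   amplitudes over matrix rows with `NA` where undefined.
#' @export
amplitude <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("amplitude needs at least 2 non-missing values")
  max(x) - min(x)
}

#' @rdname amplitude
#' @param values Cytosines x classes matrix.
#' @export
profile_amplitudes <- function(values) {
  apply(values, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else max(v) - min(v)
  })
}

#' @rdname amplitude
#' @param min_amplitude Strict lower bound for the differential flag
#'   (default 50).
#' @export
is_differential <- function(x, min_amplitude = 50) {
  amplitude(x) > min_amplitude
}

#' Pair cytosines with the promoters containing them
#'
#' Emits one pair for every containment; a cytosine inside several
#' (overlapping) promoters yields several pairs, each later receiving its own
#' methylation-expression correlation.
#'
#' @param cytosines `GRanges` of cytosine positions (width-1 ranges) with a
#'   metadata column `cytosine_id`.
#' @param promoters `GRanges` of promoter regions with metadata column
#'   `cluster_id`.
#' @return data.frame with columns `cytosine_id` and `cluster_id`.
#' @export
assign_cytosines_to_promoters <- function(cytosines, promoters) {
  ov <- findOverlaps(cytosines, promoters, type = "within",
                     ignore.strand = TRUE)
  data.frame(cytosine_id = cytosines$cytosine_id[queryHits(ov)],
             cluster_id = promoters$cluster_id[subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Collapse minus-strand CpG measurements onto the forward-strand C
#'
#' The CpG dyad is strand-symmetric: a measurement of the C on the minus
#' strand at position p is mapped to the forward-strand C at p-1, and
#' measurements of both strands of one dyad are combined by coverage-weighted
#' averaging of the percent methylation (coverages summed).
#'
#' @param meth Long-format methylation table with columns `chrom`, `pos`,
#'   `strand`, `sample`, `coverage`, `percent`.
#' @return The collapsed long-format table, all records on the `+` strand.
#' @export
collapse_strands <- function(meth) {
  pos <- ifelse(meth$strand == "-", meth$pos - 1L, meth$pos)
  key <- paste(meth$chrom, pos, meth$sample, sep = "\r")
  cov <- tapply(meth$coverage, key, sum)
  wsum <- tapply(meth$percent * meth$coverage, key, sum)
  parts <- strsplit(names(cov), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    strand = "+",
                    sample = vapply(parts, `[`, "", 3L),
                    coverage = as.vector(cov),
                    percent = as.vector(wsum / cov),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$sample), ]
}

#' Pivot a long methylation table into per-sample matrices
#'
#' @param meth Long-format table as produced by [simulate_methylation()] or
#'   [read_methylation_table()] (columns `chrom`, `pos`, `sample`,
#'   `coverage`, `percent`); absent records are missing values.
#' @param samples Sample universe (columns of the result); default the
#'   samples present.
#' @return A list with matrices `values` and `coverage` (cytosines x
#'   samples, rows named `chrom:pos`).
#' @export
methylation_matrices <- function(meth, samples = sort(unique(meth$sample))) {
  id <- paste0(meth$chrom, ":", meth$pos)
  ids <- sort(unique(id))
  ri <- match(id, ids)
  ci <- match(meth$sample, samples)
  if (anyNA(ci)) stop("methylation table contains samples outside the sample universe")
  vals <- matrix(NA_real_, length(ids), length(samples),
                 dimnames = list(ids, samples))
  cov <- vals
  vals[cbind(ri, ci)] <- meth$percent
  cov[cbind(ri, ci)] <- meth$coverage
  list(values = vals, coverage = cov)
}
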