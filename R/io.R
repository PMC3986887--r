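#' Read / write the tab-separated pipeline tables
#'
#' Plain-text interchange formats: a long methylation table (`chrom`,
#' `pos0`, `strand`, `sample`, `coverage`, `percent`; positions 0-based in
#' the file, converted to 1-based in memory), an expression count table
#' (`cluster_id`, `chrom`, `start0`, `end0`, `strand`, one column per
#' sample), and a sample-class map (`sample_id`, `class_id`,
#' `normal_flag`).
#'
#' @param path File path.
#' @return `read_methylation_table()`: a data.frame with columns `chrom`,
#'   `pos`, `strand`, `sample`, `coverage`, `percent`.
#' @export
read_methylation_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(chrom = d$chrom, pos = d$pos0 + 1L, strand = d$strand,
             sample = d$sample, coverage = d$coverage, percent = d$percent,
             stringsAsFactors = FALSE)
}

#' @rdname read_methylation_table
#' @param meth Long methylation table (1-based `pos`).
#' @export
write_methylation_table <- function(meth, path) {
  out <- data.frame(chrom = meth$chrom, pos0 = meth$pos - 1L,
                    strand = meth$strand, sample = meth$sample,
                    coverage = meth$coverage, percent = meth$percent)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname read_methylation_table
#' @return `read_expression_table()`: a list with `counts` (matrix) and
#'   `clusters` (`GRanges` with `cluster_id`).
#' @export
read_expression_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("cluster_id", "chrom", "start0", "end0", "strand")
  counts <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(counts) <- d$cluster_id
  gr <- GRanges(d$chrom, IRanges(d$start0 + 1L, d$end0), strand = d$strand)
  gr$cluster_id <- d$cluster_id
  names(gr) <- d$cluster_id
  list(counts = counts, clusters = gr)
}

#' @rdname read_methylation_table
#' @param counts Count matrix (clusters x samples).
#' @param clusters `GRanges` parallel to the rows of `counts`.
#' @export
write_expression_table <- function(counts, clusters, path) {
  out <- data.frame(cluster_id = clusters$cluster_id,
                    chrom = as.character(seqnames(clusters)),
                    start0 = start(clusters) - 1L, end0 = end(clusters),
                    strand = as.character(strand(clusters)),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname read_methylation_table
#' @export
read_sample_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$normal_flag <- as.logical(d$normal_flag)
  d
}

#' @rdname read_methylation_table
#' @param map Sample-class map data.frame.
#' @export
write_sample_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a motif alignment file (one sequence per line)
#'
#' Lines starting with `>` are treated as the TF identifier header.
#'
#' @param path File path.
#' @param tf_id TF id; default from the `>` header or the file name.
#' @return A `motif_alignment`.
#' @export
read_alignment <- function(path, tf_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (is.null(tf_id))
    tf_id <- if (any(hdr)) sub("^>\\s*", "", lines[hdr][1]) else
      sub("\\.[^.]*$", "", basename(path))
  motif_alignment(lines[!hdr], tf_id)
}

#' Read / write a position count matrix file
#'
#' The format is a `>TF` header followed by L rows of 4 whitespace-separated
#' counts (columns A, C, G, T).
#'
#' @param path File path.
#' @return A `pcm` matrix (4 x L, rows A,C,G,T) with attributes `N`, `tf`.
#' @export
read_pcm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  tf <- sub("^>\\s*", "", lines[1])
  rows <- lapply(strsplit(trimws(lines[-1]), "\\s+"), as.numeric)
  m <- t(do.call(rbind, rows))
  rownames(m) <- DNA_BASES
  structure(m, N = sum(m[, 1]), tf = tf, class = c("pcm", "matrix"))
}

#' @rdname read_pcm
#' @param pcm A `pcm` matrix.
#' @export
write_pcm <- function(pcm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", attr(pcm, "tf") %||% "TF"), con)
  utils::write.table(t(pcm), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write genomic ranges as BED
#'
#' Emits 6-column BED (0-based half-open) from a `GRanges`; the `name`
#' column is taken from `name_col` when present.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name_col Metadata column to use as the BED name field.
#' @export
write_bed <- function(gr, path, name_col = NULL) {
  nm <- if (!is.null(name_col) && name_col %in% names(mcols(gr)))
    as.character(mcols(gr)[[name_col]]) else "."
  out <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr), name = nm,
                    score = 0L, strand = as.character(strand(gr)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a BED (or narrowPeak) file into a GRanges
#'
#' Uses `rtracklayer` when available and otherwise falls back to a minimal
#' three-to-six-column reader; only the first three columns are required.
#'
#' @param path File path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      grepl("\\.bed$", path)) {
    return(rtracklayer::import(path, format = "BED"))
  }
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]),
                strand = if (ncol(d) >= 6) d[[6]] else "*")
  if (ncol(d) >= 4) gr$name <- d[[4]]
  gr
}
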