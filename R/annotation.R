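#' Co-localization of CpG classes with genomic feature tracks
#'
#' For each CpG class (e.g. traffic lights, positively correlated,
#' insignificant) and each feature track, the fraction of the class's CpGs
#' contained in at least one interval of the track. A CpG position is treated
#' as a 1-bp interval; fractions across tracks need not sum to 1 because
#' tracks overlap.
#'
#' @param cpg_sets Named list of `GRanges` (one per CpG class).
#' @param tracks Named list of `GRanges` feature tracks (CGI, promoters,
#'   gene bodies, repeats, conserved elements, SNPs, DNase clusters, ...).
#' @return Numeric matrix, classes x tracks, of fractions (`NA` for an empty
#'   class).
#' @export
colocalize <- function(cpg_sets, tracks) {
  out <- matrix(NA_real_, length(cpg_sets), length(tracks),
                dimnames = list(names(cpg_sets), names(tracks)))
  for (i in seq_along(cpg_sets)) {
    gr <- cpg_sets[[i]]
    if (length(gr) == 0L) next
    for (j in seq_along(tracks)) {
      out[i, j] <- mean(countOverlaps(gr, tracks[[j]],
                                      ignore.strand = TRUE) > 0)
    }
  }
  out
}

#' Derive promoter and gene-body tracks from gene models
#'
#' Per (stranded) transcript: promoter = 1500 bp upstream to 500 bp
#' downstream of the TSS; gene body = 500 bp downstream of the TSS to the
#' gene end (empty, and dropped, when the gene is shorter than 500 bp).
#' Unstranded records are skipped with a warning.
#'
#' @param genes Stranded `GRanges` of gene/transcript models.
#' @return A list with `promoter` and `gene_body` `GRanges` tracks.
#' @export
derive_gene_tracks <- function(genes) {
  str <- as.character(strand(genes))
  if (any(str == "*")) {
    warning("skipping ", sum(str == "*"), " unstranded gene record(s)")
    genes <- genes[str != "*"]
    str <- str[str != "*"]
  }
  prom <- promoters(genes, upstream = 1500L, downstream = 500L)
  start(prom) <- pmax(start(prom), 1L)
  long <- width(genes) > 500L
  g <- genes[long]
  s <- as.character(strand(g))
  body <- GRanges(seqnames(g),
                  IRanges(ifelse(s == "+", start(g) + 500L, start(g)),
                          ifelse(s == "+", end(g), end(g) - 500L)),
                  strand = strand(g))
  list(promoter = prom, gene_body = body)
}
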