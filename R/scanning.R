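#' Scan promoter sequences with a calibrated motif model
#'
#' Slides the model over every length-L window of each sequence on both
#' strands; reverse-strand windows are scored on the reverse complement and
#' reported in forward coordinates. Windows containing a non-ACGT character
#' are skipped. Every window with score >= threshold is emitted.
#'
#' @param model A calibrated `pwm_model` or `rdm_model`.
#' @param sequences Named `DNAStringSet` (or character vector) of
#'   forward-strand promoter sequences.
#' @param promoters Optional `GRanges` parallel to `sequences` (matched by
#'   name) used to lift hits to genome coordinates; when `NULL`, hits are
#'   reported in sequence-local coordinates with the sequence name as
#'   chromosome.
#' @param threshold Score threshold; default the model's calibrated
#'   threshold.
#' @return A `GRanges` of hits with metadata columns `tf`, `kind`
#'   (`"pwm"`/`"rdm"`) and `score`; hit strand is the matching orientation.
#' @export
scan_promoters <- function(model, sequences, promoters = NULL,
                           threshold = model$threshold) {
  if (is.null(threshold)) stop("model has no threshold; calibrate it first")
  nm <- names(sequences)
  seqs <- toupper(as.character(sequences))
  if (is.null(nm)) nm <- as.character(seq_along(seqs))
  kind <- if (inherits(model, "pwm_model")) "pwm" else "rdm"
  L <- model$L
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    code <- match(strsplit(seqs[i], "")[[1]], DNA_BASES)
    len <- length(code)
    if (len < L) next
    fwd <- window_scores(model, code)
    rc <- 5L - rev(code)
    rev_sc <- window_scores(model, rc)
    hf <- which(!is.na(fwd) & fwd >= threshold - 1e-9)
    hr <- which(!is.na(rev_sc) & rev_sc >= threshold - 1e-9)
    if (length(hf) + length(hr) == 0L) next
    rows[[i]] <- data.frame(
      seq = nm[i],
      offset = c(hf, len - hr - L + 2L),
      strand = rep(c("+", "-"), c(length(hf), length(hr))),
      score = c(fwd[hf], rev_sc[hr]),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  hits_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(), offset = integer(), strand = character(),
               score = numeric())
  if (is.null(promoters)) {
    gr <- GRanges(hits_df$seq, IRanges(hits_df$offset, width = L),
                  strand = hits_df$strand)
  } else {
    pn <- names(promoters)
    if (is.null(pn)) pn <- promoters$cluster_id
    idx <- match(hits_df$seq, pn)
    gr <- GRanges(seqnames(promoters)[idx],
                  IRanges(start(promoters)[idx] + hits_df$offset - 1L,
                          width = L),
                  strand = hits_df$strand)
  }
  gr$tf <- rep(model$tf, length(gr))
  gr$kind <- rep(kind, length(gr))
  gr$score <- hits_df$score
  gr
}

window_scores <- function(model, code) {
  L <- model$L
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  idx <- seq_len(nw)
  if (inherits(model, "pwm_model")) {
    s <- numeric(nw)
    for (j in seq_len(L)) s <- s + model$K[, j][code[idx + j - 1L]]
    s * model$delta
  } else {
    s <- numeric(nw)
    for (p in seq_len(nrow(model$pairs))) {
      d <- din_index(code[idx + model$pairs[p, 1] - 1L],
                     code[idx + model$pairs[p, 2] - 1L])
      s <- s + model$r[cbind(d, p)]
    }
    s
  }
}

#' Restrict motif hits to ChIP-seq peak regions
#'
#' A hit is retained iff its interval lies fully inside at least one peak —
#' a binding site must be contained in the experimentally bound region.
#'
#' @param hits `GRanges` of motif hits.
#' @param peaks `GRanges` of peak intervals (e.g. read from BED/narrowPeak,
#'   first three columns).
#' @param mode `"within"` (default, full containment) or `"any"` (any
#'   overlap).
#' @return The retained subset of `hits`.
#' @export
restrict_to_peaks <- function(hits, peaks, mode = c("within", "any")) {
  mode <- match.arg(mode)
  subsetByOverlaps(hits, peaks, type = mode, ignore.strand = TRUE)
}

#' Extract hit sequences in matching orientation
#'
#' @param hits `GRanges` of hits from [scan_promoters()].
#' @param sequences Named `DNAStringSet` of forward-strand promoter
#'   sequences.
#' @param promoters `GRanges` parallel to `sequences` (same names) giving
#'   their genomic positions.
#' @return Character vector of hit sequences (reverse-complemented for
#'   minus-strand hits).
#' @export
hit_sequences <- function(hits, sequences, promoters) {
  pn <- names(promoters)
  ov <- findOverlaps(hits, promoters, type = "within", ignore.strand = TRUE)
  out <- character(length(hits))
  q <- queryHits(ov)[!duplicated(queryHits(ov))]
  s <- subjectHits(ov)[!duplicated(queryHits(ov))]
  for (k in seq_along(q)) {
    i <- q[k]; j <- s[k]
    off <- start(hits)[i] - start(promoters)[j] + 1L
    sub <- substr(as.character(sequences[[pn[j]]]), off,
                  off + width(hits)[i] - 1L)
    if (as.character(strand(hits))[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    out[i] <- sub
  }
  out
}

#' GC content of motif hits versus the source alignment
#'
#' A consistency check on the scanner: the average G+C fraction of the
#' emitted hits should be indistinguishable from that of the binding sites
#' in the model's source alignment.
#'
#' @param hit_seqs Character vector of hit sequences (see
#'   [hit_sequences()]).
#' @param alignment The source `motif_alignment`.
#' @return A list with `gc_hits`, `gc_alignment` and `difference`.
#' @export
gc_content_comparison <- function(hit_seqs, alignment) {
  if (length(hit_seqs) == 0L) stop("no hits")
  gc <- function(s) {
    ch <- strsplit(paste(s, collapse = ""), "")[[1]]
    mean(ch %in% c("G", "C"))
  }
  g1 <- gc(hit_seqs)
  g2 <- gc(alignment$seqs)
  list(gc_hits = g1, gc_alignment = g2, difference = g1 - g2)
}
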