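# Fixtures and independent oracles shared across the test files.

make_pcm <- function(cols, tf = "TF", N = sum(cols[[1]])) {
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  structure(m, N = N, tf = tf, class = c("pcm", "matrix"))
}

# degenerate consensus ACCGGTAT, CpG pair at columns (3,4); depth 15
pcm_consensus_cg <- function(tf = "TF1") {
  base <- function(b) { v <- rep(0, 4); v[match(b, c("A","C","G","T"))] <- 15; v }
  make_pcm(lapply(c("A","C","C","G","G","T","A","T"), base), tf = tf)
}

# one core CpG pair (4,5) and one medium ("flanking") CpG pair (1,2); depth 15
pcm_core_flank <- function(tf = "TFCF") {
  make_pcm(list(c(2, 6, 5, 2),   # C major, medium information
                c(2, 5, 6, 2),   # G major, medium information
                c(15, 0, 0, 0),
                c(0, 15, 0, 0),  # C, core
                c(0, 0, 15, 0),  # G, core
                c(0, 0, 0, 15),
                c(15, 0, 0, 0),
                c(0, 0, 0, 15)), tf = tf)
}

random_pcm <- function(L, N = 20L, tf = "TFR", seed = 1L) {
  set.seed(seed)
  cols <- lapply(seq_len(L), function(j) {
    p <- as.vector(stats::rgamma(4, 1))
    as.vector(stats::rmultinom(1, N, p / sum(p)))
  })
  make_pcm(cols, tf = tf, N = N)
}

random_alignment <- function(L, N, seed, tf = "TFR") {
  set.seed(seed)
  motif_alignment(replicate(N, paste(sample(c("A","C","G","T"), L,
                                            replace = TRUE,
                                            prob = stats::runif(4, .1, 1)),
                                     collapse = "")), tf)
}

# Independent PWM tail oracle: enumerate all 4^L words on the integer score
# grid (exact; probabilities are dyadic rationals under a uniform background).
enum_pwm_tail <- function(pwm, threshold_units) {
  L <- pwm$L
  n <- 4L^L
  n0 <- 0:(n - 1L)
  units <- numeric(n)
  prob <- rep(1, n)
  q <- pwm$background
  for (i in seq_len(L)) {
    d <- (n0 %/% as.integer(4L^(L - i))) %% 4L + 1L
    units <- units + pwm$K[d, i]
    prob <- prob * q[d]   # exact for the dyadic uniform background
  }
  sum(prob[units >= threshold_units])
}

# enumerate all words of length L as character vector (small L only)
all_words <- function(L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                              stringsAsFactors = FALSE))
}

grs <- function(chrom, start, end, strand = "+", ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  args <- list(...)
  for (nm in names(args)) S4Vectors::mcols(gr)[[nm]] <- args[[nm]]
  gr
}

bed_coords <- function(gr) {
  data.frame(start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr))
}
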