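NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif alignment
#'
#' A motif alignment is a set of equal-length binding-site sequences for one
#' transcription factor, the raw material for position count matrices and
#' remote dependency models.
#'
#' @param seqs Character vector of equal-length sequences over A/C/G/T.
#' @param tf_id Transcription factor identifier.
#' @return An object of class `motif_alignment` with elements `tf`, `seqs`,
#'   `L` (site length) and `N` (number of sites).
#' @export
motif_alignment <- function(seqs, tf_id = "TF") {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("alignment sequences must have equal length")
  if (any(grepl("[^ACGT]", seqs))) stop("alignment sequences must be over A/C/G/T")
  structure(list(tf = tf_id, seqs = seqs, L = L, N = length(seqs)),
            class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat(sprintf("motif_alignment %s: %d sequences of length %d\n", x$tf, x$N, x$L))
  invisible(x)
}

#' Build a position count matrix from an alignment
#'
#' @param alignment A `motif_alignment`.
#' @return A 4 x L integer matrix with rows A, C, G, T; each column sums to
#'   the number of aligned sequences. Attributes `N` and `tf` are attached.
#' @export
build_pcm <- function(alignment) {
  stopifnot(inherits(alignment, "motif_alignment"))
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  pcm <- vapply(seq_len(alignment$L), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
  }, integer(4L))
  dimnames(pcm) <- list(DNA_BASES, NULL)
  structure(pcm, N = alignment$N, tf = alignment$tf, class = c("pcm", "matrix"))
}

#' Build a log-odds position weight matrix
#'
#' Weights follow the usual log-odds form with a background-proportional
#' pseudocount: `w[a,j] = log((x[a,j] + pc*q_a) / ((N + pc)*q_a))`. By default
#' the pseudocount scales as `log(N)`, which keeps the regularisation stable
#' across alignments of very different depth. Weights are snapped to a fixed
#' score grid (`delta`) so that the exact dynamic-programming score
#' distribution and window scanning operate on identical integers.
#'
#' @param pcm A position count matrix from [build_pcm()] (or a plain 4 x L
#'   matrix with rows A,C,G,T).
#' @param background Background nucleotide probabilities (A,C,G,T); must sum
#'   to 1.
#' @param pseudocount Total pseudocount mass; default `log(N)`.
#' @param delta Score discretisation step for exact P-value computation.
#' @return An object of class `pwm_model` with the real-valued matrix `w`,
#'   its integer grid image `K`, `background`, `delta`, and slots for the
#'   calibrated `threshold` (filled by [calibrate_threshold()]).
#' @export
build_pwm <- function(pcm, background = rep(0.25, 4), pseudocount = NULL,
                      delta = 1e-4) {
  if (is.null(attr(pcm, "N"))) attr(pcm, "N") <- sum(pcm[, 1])
  N <- attr(pcm, "N")
  if (N <= 0) stop("zero-depth position count matrix")
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-8)
  if (is.null(pseudocount)) pseudocount <- log(max(N, 2))
  q <- background
  w <- log(sweep(pcm + pseudocount * q, 1, (N + pseudocount) * q, "/"))
  K <- round(w / delta)
  w <- K * delta
  structure(list(tf = attr(pcm, "tf") %||% "TF", w = w, K = K,
                 background = q, pseudocount = pseudocount, delta = delta,
                 L = ncol(w), threshold = NULL, threshold_p = NULL),
            class = "pwm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score words with a PWM
#'
#' @param pwm A `pwm_model`.
#' @param words Character vector of words of length `L`.
#' @return Numeric scores (sum of per-column log-odds; `NA` for words with
#'   non-ACGT characters).
#' @export
pwm_score <- function(pwm, words) {
  codes <- encode_dna(words, pwm$L)
  units <- pwm_score_units(pwm$K, codes)
  units * pwm$delta
}

encode_dna <- function(words, L) {
  mat <- do.call(rbind, strsplit(toupper(words), ""))
  if (ncol(mat) != L) stop(sprintf("words must have length %d", L))
  matrix(match(mat, DNA_BASES), nrow = nrow(mat))
}

pwm_score_units <- function(K, codes) {
  n <- nrow(codes)
  s <- numeric(n)
  for (j in seq_len(ncol(K))) s <- s + K[, j][codes[, j]]
  unname(s)
}

#' Exact PWM score distribution by dynamic programming
#'
#' Convolves the per-column score distributions of i.i.d. background letters
#' on the integer score grid, yielding the exact distribution of the word
#' score (exact on the discretisation grid; with the default uniform
#' background all probabilities are dyadic rationals and the result is exact
#' in floating point as well).
#'
#' @param pwm A `pwm_model`.
#' @return A data.frame with columns `units` (integer grid score), `score`
#'   (`units * delta`) and `prob`.
#' @export
pwm_score_distribution <- function(pwm) {
  K <- pwm$K
  q <- pwm$background
  cur <- 1
  curlo <- 0L
  for (j in seq_len(ncol(K))) {
    kj <- K[, j]
    newlo <- curlo + min(kj)
    newhi <- curlo + length(cur) - 1L + max(kj)
    new <- numeric(newhi - newlo + 1L)
    for (a in 1:4) {
      idx <- (curlo + kj[a] - newlo) + seq_along(cur)
      new[idx] <- new[idx] + cur * q[a]
    }
    cur <- new
    curlo <- newlo
  }
  keep <- cur > 0
  units <- curlo + seq_along(cur) - 1L
  data.frame(units = units[keep], score = units[keep] * pwm$delta,
             prob = cur[keep])
}

#' Calibrate a motif-model score threshold at a target P-value
#'
#' Finds the smallest attainable score `s` such that the probability that a
#' random background word scores at least `s` is no more than `target_p`
#' (the "5 of 10,000 random words" reading of P < 0.0005). PWMs use the exact
#' dynamic-programming score distribution; RDMs use full enumeration of all
#' `4^L` words for `L <= max_enum_length` and otherwise Monte Carlo with at
#' least `n_mc` words plus a binomial confidence interval on the achieved
#' tail probability.
#'
#' @param model A `pwm_model` or `rdm_model`.
#' @param target_p Target tail probability (default 0.0005).
#' @param max_enum_length Maximum motif length for exhaustive RDM enumeration.
#' @param n_mc Monte Carlo sample size for long RDMs.
#' @return The model with `threshold` (score scale) and `threshold_p` (the
#'   exact or estimated tail probability at the threshold) filled in. For
#'   Monte Carlo calibration a 95% confidence interval is attached as
#'   attribute `ci` on `threshold_p`.
#' @export
calibrate_threshold <- function(model, target_p = 5e-4,
                                max_enum_length = 10L, n_mc = 2e6) {
  UseMethod("calibrate_threshold")
}

#' @export
calibrate_threshold.pwm_model <- function(model, target_p = 5e-4,
                                          max_enum_length = 10L, n_mc = 2e6) {
  dist <- pwm_score_distribution(model)
  tail_p <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail_p <= target_p)
  if (length(ok) == 0L)
    stop("degenerate model: no attainable score has tail probability <= target_p")
  i <- ok[1L]
  model$threshold <- dist$score[i]
  model$threshold_units <- dist$units[i]
  model$threshold_p <- tail_p[i]
  model
}

#' @export
calibrate_threshold.rdm_model <- function(model, target_p = 5e-4,
                                          max_enum_length = 10L, n_mc = 2e6) {
  if (model$L <= max_enum_length) {
    scores <- rdm_enumerate_scores(model)
    probs <- scores$prob
    o <- order(scores$score, decreasing = TRUE)
    s_sorted <- scores$score[o]
    tail_p <- cumsum(probs[o])
    # smallest attainable score whose tail <= target_p: walk from the top and
    # take the last score still within budget (ties share one tail value)
    grp_last <- !duplicated(s_sorted, fromLast = TRUE) # last index of each tied run
    cand <- which(grp_last & tail_p <= target_p)
    if (length(cand) == 0L)
      stop("degenerate model: no attainable score has tail probability <= target_p")
    i <- cand[length(cand)]
    model$threshold <- s_sorted[i]
    model$threshold_p <- tail_p[i]
  } else {
    scores <- rdm_mc_scores(model, n_mc)
    o <- order(scores, decreasing = TRUE)
    s_sorted <- scores[o]
    k <- floor(target_p * length(scores))
    if (k < 1L) stop("n_mc too small for target_p")
    grp_last <- !duplicated(s_sorted, fromLast = TRUE)
    tail_n <- seq_along(s_sorted)
    cand <- which(grp_last & tail_n <= k)
    if (length(cand) == 0L)
      stop("degenerate model: no attainable score has tail probability <= target_p")
    i <- cand[length(cand)]
    model$threshold <- s_sorted[i]
    phat <- i / length(scores)
    ci <- phat + c(-1.96, 1.96) * sqrt(phat * (1 - phat) / length(scores))
    model$threshold_p <- structure(phat, ci = pmax(ci, 0))
  }
  model
}

#' Filter an alignment by PWM score
#'
#' Sequences scoring below the calibrated PWM threshold are removed; if fewer
#' than `min_n` sequences remain the alignment is discarded (returns `NULL`),
#' mirroring the rule that remote-dependency models need at least 15
#' supporting binding sites.
#'
#' @param alignment A `motif_alignment`.
#' @param pwm A calibrated `pwm_model`.
#' @param threshold Score threshold; default the PWM's calibrated threshold.
#' @param min_n Minimum number of retained sequences (default 15).
#' @return The filtered `motif_alignment`, or `NULL` if discarded.
#' @export
filter_alignment <- function(alignment, pwm, threshold = pwm$threshold,
                             min_n = 15L) {
  stopifnot(inherits(alignment, "motif_alignment"))
  if (is.null(threshold)) stop("PWM has no threshold; calibrate it first")
  keep <- pwm_score(pwm, alignment$seqs) >= threshold - 1e-9
  retained <- alignment$seqs[keep]
  if (length(retained) < min_n) return(NULL)
  motif_alignment(retained, alignment$tf)
}

# ---- remote dependency model -------------------------------------------------

din_index <- function(ci, cj) (ci - 1L) * 4L + cj

DINUCLEOTIDES <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))

#' Build a remote dependency model (RDM)
#'
#' For every ordered position pair i < j the frequency `f[a,i,j]` of each of
#' the 16 ordered dinucleotides `a` is computed over the aligned binding
#' sites; the weights are jointly normalised by the sum over all pairs of the
#' per-pair maximal frequency:
#' `r[a,i,j] = f[a,i,j] / sum_{i<j} max_a f[a,i,j]`.
#' Consequently `sum_{i<j} max_a r[a,i,j] = 1` exactly.
#'
#' @param alignment A `motif_alignment` (after PWM filtering it should hold
#'   at least 15 sequences, but the constructor does not enforce this).
#' @param background Background nucleotide probabilities, kept with the model
#'   for threshold calibration.
#' @return An object of class `rdm_model` with the 16 x P weight matrix `r`
#'   (rows named by ordered dinucleotide, columns by position pair), the pair
#'   index matrix `pairs`, raw frequencies `f`, `L`, `N`, and empty threshold
#'   slots.
#' @export
build_rdm <- function(alignment, background = rep(0.25, 4)) {
  stopifnot(inherits(alignment, "motif_alignment"))
  L <- alignment$L
  if (L < 2L) stop("RDM needs motif length >= 2")
  codes <- encode_dna(alignment$seqs, L)
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  P <- nrow(pairs)
  f <- matrix(0, nrow = 16L, ncol = P,
              dimnames = list(DINUCLEOTIDES, NULL))
  for (p in seq_len(P)) {
    d <- din_index(codes[, pairs[p, 1]], codes[, pairs[p, 2]])
    f[, p] <- tabulate(d, nbins = 16L) / alignment$N
  }
  z <- sum(apply(f, 2, max))
  structure(list(tf = alignment$tf, r = f / z, f = f, pairs = pairs,
                 L = L, N = alignment$N, background = background,
                 threshold = NULL, threshold_p = NULL),
            class = "rdm_model")
}

#' Score words with a remote dependency model
#'
#' The score of a word is the sum over all ordered position pairs of the
#' normalised weight of the dinucleotide the word realises at that pair.
#' By the normalisation identity the consensus of a degenerate (single
#' sequence repeated) alignment scores exactly 1.
#'
#' @param rdm An `rdm_model`.
#' @param words Character vector of words of length `L`.
#' @return Numeric scores in `[0, 1]` for words over A/C/G/T; `NA` where the
#'   word contains other characters.
#' @export
rdm_score <- function(rdm, words) {
  codes <- encode_dna(words, rdm$L)
  s <- numeric(nrow(codes))
  for (p in seq_len(nrow(rdm$pairs))) {
    d <- din_index(codes[, rdm$pairs[p, 1]], codes[, rdm$pairs[p, 2]])
    s <- s + rdm$r[cbind(d, p)]
  }
  s
}

# Exhaustive score distribution of a random background word under an RDM.
# Words are enumerated as base-4 integers; returns scores and probabilities.
rdm_enumerate_scores <- function(rdm) {
  L <- rdm$L
  n <- 4L^L
  n0 <- 0:(n - 1L)
  digits <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(L)) {
    digits[, i] <- (n0 %/% as.integer(4L^(L - i))) %% 4L + 1L
  }
  score <- numeric(n)
  for (p in seq_len(nrow(rdm$pairs))) {
    d <- din_index(digits[, rdm$pairs[p, 1]], digits[, rdm$pairs[p, 2]])
    score <- score + rdm$r[cbind(d, p)]
  }
  lq <- log(rdm$background)
  logp <- numeric(n)
  for (i in seq_len(L)) logp <- logp + lq[digits[, i]]
  list(score = score, prob = exp(logp), digits_marginal = digits[, 1])
}

rdm_mc_scores <- function(rdm, n_mc) {
  L <- rdm$L
  n_mc <- as.integer(n_mc)
  digits <- matrix(sample.int(4L, n_mc * L, replace = TRUE,
                              prob = rdm$background), ncol = L)
  score <- numeric(n_mc)
  for (p in seq_len(nrow(rdm$pairs))) {
    d <- din_index(digits[, rdm$pairs[p, 1]], digits[, rdm$pairs[p, 2]])
    score <- score + rdm$r[cbind(d, p)]
  }
  score
}

# ---- discrete information content -------------------------------------------

#' Discrete information content of a motif column
#'
#' `DIC = (1/N) * (sum_a log(x_a!) - log(N!))` with natural logarithms and
#' log-gamma for fractional counts. The maximum, 0, is attained by a column
#' containing a single nucleotide; more uniform columns are more negative.
#'
#' @param counts Numeric vector of 4 non-negative nucleotide counts (may be
#'   fractional).
#' @param N Column total; default `sum(counts)`.
#' @return The DIC value (<= 0).
#' @export
dic <- function(counts, N = sum(counts)) {
  if (any(counts < 0)) stop("negative counts")
  if (N <= 0) stop("empty column")
  (sum(lgamma(counts + 1)) - lgamma(N + 1)) / N
}

#' Reference DIC thresholds separating core, medium and low information
#'
#' `Th` is the DIC of a column with three equally frequent nucleotides (and
#' one absent); `th` is the DIC of a column with two nucleotides at frequency
#' `f` and two at `2f`. Fractional counts are handled through log-gamma.
#' `Th > th` for every N >= 3.
#'
#' @param N Alignment depth.
#' @return A list with elements `Th` and `th`.
#' @export
dic_thresholds <- function(N) {
  if (N < 3) stop("N must be >= 3")
  Th <- dic(c(N / 3, N / 3, N / 3, 0), N)
  th <- dic(c(N / 6, N / 6, N / 3, N / 3), N)
  stopifnot(Th > th)
  list(Th = Th, th = th)
}

#' Locate and classify CpG-prone column pairs of a motif
#'
#' A column pair (j, j+1) is a CpG position when C is a major (maximal,
#' ties allowed) nucleotide at j and G at j+1. The pair is classified by the
#' discrete information content of its two columns against the reference
#' thresholds `Th` and `th`: `core` when both DICs exceed `Th`, `medium` when
#' both lie in `[th, Th]`, `low` when both fall below `th`, and `mixed`
#' otherwise.
#'
#' @param pcm A position count matrix from [build_pcm()].
#' @return A data.frame with columns `tf`, `j` (1-based column of the C),
#'   `dic_c`, `dic_g` and `class`; zero rows when the motif has no CpG pair.
#' @export
find_cpg_positions <- function(pcm) {
  N <- attr(pcm, "N")
  L <- ncol(pcm)
  thr <- dic_thresholds(N)
  out <- list()
  colmax <- apply(pcm, 2, max)
  for (j in seq_len(L - 1L)) {
    if (pcm["C", j] == colmax[j] && pcm["G", j + 1L] == colmax[j + 1L]) {
      dc <- dic(pcm[, j], N)
      dg <- dic(pcm[, j + 1L], N)
      cls <- if (dc > thr$Th && dg > thr$Th) "core"
        else if (dc >= thr$th && dc <= thr$Th && dg >= thr$th && dg <= thr$Th) "medium"
        else if (dc < thr$th && dg < thr$th) "low"
        else "mixed"
      out[[length(out) + 1L]] <- data.frame(
        tf = attr(pcm, "tf") %||% "TF", j = j, dic_c = dc, dic_g = dg,
        class = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(tf = character(), j = integer(), dic_c = numeric(),
                      dic_g = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
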