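#' Count analyzed CpGs and traffic lights inside each TF's binding sites
#'
#' A CpG counts at most once per TF per model kind regardless of how many
#' overlapping hits of that TF contain it; only cytosines with at least one
#' methylation-expression correlation (rows of `calls`) enter the analyzed
#' count.
#'
#' @param cytosines `GRanges` of cytosine positions with `cytosine_id`.
#' @param calls Per-cytosine call table from [call_traffic_lights()].
#' @param hits `GRanges` of motif hits with `tf` and `kind`.
#' @return data.frame with one row per (tf, kind): `n_cpg_in_tfbs`,
#'   `observed_negative`, `observed_positive`.
#' @export
count_tfbs_overlaps <- function(cytosines, calls, hits) {
  cyt <- cytosines[cytosines$cytosine_id %in% calls$cytosine_id]
  ov <- findOverlaps(cyt, hits, type = "within", ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.frame(tf = character(), kind = character(),
                      n_cpg_in_tfbs = integer(),
                      observed_negative = integer(),
                      observed_positive = integer()))
  df <- data.frame(cytosine_id = cyt$cytosine_id[queryHits(ov)],
                   tf = hits$tf[subjectHits(ov)],
                   kind = hits$kind[subjectHits(ov)],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  lab <- calls$label[match(df$cytosine_id, calls$cytosine_id)]
  key <- interaction(df$tf, df$kind, drop = TRUE)
  out <- data.frame(
    tf = tapply(df$tf, key, `[`, 1L),
    kind = tapply(df$kind, key, `[`, 1L),
    n_cpg_in_tfbs = as.integer(tapply(lab, key, length)),
    observed_negative = as.integer(tapply(lab == "negative_significant", key, sum)),
    observed_positive = as.integer(tapply(lab == "positive_significant", key, sum)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-square test of traffic-light depletion or enrichment within TFBSs
#'
#' One-sample chi-square of the observed traffic-light count among a TF's
#' in-TFBS CpGs against the expectation from the global traffic-light
#' fraction: `expected = global_fraction * n_in_tfbs`,
#' `chi2 = (o-e)^2/e + (o-e)^2/(n-e)` with 1 degree of freedom and no
#' continuity correction, Bonferroni-corrected over `m_tests`. An exact
#' two-sided binomial P-value is reported alongside (relevant when the
#' expected count is small).
#'
#' @param observed Observed traffic-light count(s) (vectorized).
#' @param n_in_tfbs Analyzed CpGs inside the TF's binding sites.
#' @param global_fraction Genome-wide traffic-light fraction among analyzed
#'   cytosines (in (0,1)).
#' @param m_tests Number of tests for the Bonferroni correction.
#' @param alpha Family-wise significance level for the direction call.
#' @return data.frame with columns `observed`, `n_in_tfbs`, `expected`,
#'   `ratio`, `chi2`, `p`, `p_bonferroni`, `p_binom`, `direction`.
#' @export
enrichment_test <- function(observed, n_in_tfbs, global_fraction,
                            m_tests = 1L, alpha = 0.05) {
  if (any(n_in_tfbs <= 0)) stop("n_in_tfbs must be positive")
  if (global_fraction <= 0 || global_fraction >= 1)
    stop("global_fraction must be in (0,1)")
  e <- global_fraction * n_in_tfbs
  if (any(e == 0) || any(n_in_tfbs - e == 0))
    stop("degenerate test: zero expected count")
  chi2 <- (observed - e)^2 / e + (observed - e)^2 / (n_in_tfbs - e)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_bonf <- pmin(1, p * m_tests)
  p_binom <- vapply(seq_along(observed), function(i)
    binom.test(observed[i], n_in_tfbs[i], global_fraction)$p.value,
    numeric(1))
  direction <- ifelse(p_bonf < alpha & observed < e, "under",
               ifelse(p_bonf < alpha & observed > e, "over", "none"))
  data.frame(observed = observed, n_in_tfbs = n_in_tfbs, expected = e,
             ratio = observed / e, chi2 = chi2, p = p,
             p_bonferroni = p_bonf, p_binom = p_binom,
             direction = direction, stringsAsFactors = FALSE)
}

#' Per-TF traffic-light enrichment table
#'
#' Runs [enrichment_test()] for every TF (and model kind) with at least
#' `min_observed` observed CpGs of the requested sign; the Bonferroni
#' denominator defaults to the number of TF/kind combinations entering the
#' test.
#'
#' @param overlap_counts Output of [count_tfbs_overlaps()].
#' @param global_fraction Genome-wide fraction of the requested sign among
#'   analyzed cytosines.
#' @param sign `"negative"` (traffic lights) or `"positive"`.
#' @param min_observed Inclusion rule: minimum observed count (default 1,
#'   i.e. TFs having at least one such CpG within their TFBSs).
#' @param m_tests Bonferroni denominator; default the number of included
#'   rows.
#' @return The overlap table augmented with the [enrichment_test()] columns.
#' @export
tf_enrichment <- function(overlap_counts, global_fraction,
                          sign = c("negative", "positive"),
                          min_observed = 1L, m_tests = NULL) {
  sign <- match.arg(sign)
  obs <- if (sign == "negative") overlap_counts$observed_negative
         else overlap_counts$observed_positive
  keep <- overlap_counts$n_cpg_in_tfbs > 0 & obs >= min_observed
  oc <- overlap_counts[keep, , drop = FALSE]
  obs <- obs[keep]
  if (nrow(oc) == 0L) return(cbind(oc, observed = integer()))
  if (is.null(m_tests)) m_tests <- nrow(oc)
  res <- enrichment_test(obs, oc$n_cpg_in_tfbs, global_fraction, m_tests)
  out <- cbind(oc[, c("tf", "kind")], res)
  rownames(out) <- NULL
  out
}

#' Compare observed/expected ratios between TF functional classes
#'
#' Computes the mean observed-to-expected ratio per functional class
#' (activator, repressor, both) and Welch two-sample t-tests of repressors
#' against each other class. Degenerate zero-variance configurations are
#' handled explicitly: identical distributions give p = 1, perfectly
#' separated constant groups give p = 0 with a flag.
#'
#' @param enrich Per-TF enrichment table (columns `tf`, `ratio`).
#' @param labels data.frame with columns `tf` and `fun`
#'   (activator/repressor/both).
#' @return A list with `means` (named vector), `tests` (data.frame of
#'   comparisons: `other`, `t`, `p`, `degenerate`) and `data` (ratios with
#'   labels, for plotting).
#' @export
compare_function_classes <- function(enrich, labels) {
  fun <- labels$fun[match(enrich$tf, labels$tf)]
  d <- data.frame(tf = enrich$tf, ratio = enrich$ratio, fun = fun,
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$fun), ]
  means <- tapply(d$ratio, d$fun, mean)
  rep_r <- d$ratio[d$fun == "repressor"]
  tests <- list()
  for (other in setdiff(unique(d$fun), "repressor")) {
    o_r <- d$ratio[d$fun == other]
    if (length(rep_r) < 2L || length(o_r) < 2L) {
      warning("class with < 2 members skipped: ", other)
      next
    }
    if (sd(rep_r) == 0 && sd(o_r) == 0) {
      same <- isTRUE(all.equal(mean(rep_r), mean(o_r)))
      tests[[length(tests) + 1L]] <- data.frame(
        other = other, t = if (same) 0 else Inf * sign(mean(rep_r) - mean(o_r)),
        p = if (same) 1 else 0, degenerate = TRUE)
      next
    }
    tt <- t.test(rep_r, o_r)
    tests[[length(tests) + 1L]] <- data.frame(
      other = other, t = unname(tt$statistic), p = tt$p.value,
      degenerate = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(other = character(), t = numeric(), p = numeric(),
               degenerate = logical())
  list(means = means, tests = tests, data = d)
}

#' Attribute in-TFBS CpGs to motif column pairs
#'
#' For every (cytosine, hit) containment, the motif column pair the CpG dyad
#' occupies is computed (strand-aware); pairs matching a C.G major-nucleotide
#' column pair of the model are labelled with its information-content class,
#' others are tallied as `non_cpg_column`.
#'
#' @param cytosines `GRanges` of cytosine C positions with `cytosine_id`.
#' @param hits `GRanges` of motif hits (`tf`, `kind`).
#' @param position_classes data.frame from [find_cpg_positions()] stacked
#'   over TFs (columns `tf`, `j`, `class`).
#' @return data.frame with columns `cytosine_id`, `tf`, `kind`, `j`,
#'   `class`.
#' @export
cpg_motif_positions <- function(cytosines, hits, position_classes) {
  ov <- findOverlaps(cytosines, hits, type = "within", ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.frame(cytosine_id = character(), tf = character(),
                      kind = character(), j = integer(),
                      class = character(), stringsAsFactors = FALSE))
  qi <- queryHits(ov); si <- subjectHits(ov)
  str <- as.character(strand(hits))[si]
  j <- ifelse(str == "-", end(hits)[si] - start(cytosines)[qi],
              start(cytosines)[qi] - start(hits)[si] + 1L)
  df <- data.frame(cytosine_id = cytosines$cytosine_id[qi],
                   tf = hits$tf[si], kind = hits$kind[si], j = j,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  key <- paste(df$tf, df$j)
  pk <- paste(position_classes$tf, position_classes$j)
  df$class <- position_classes$class[match(key, pk)]
  df$class[is.na(df$class)] <- "non_cpg_column"
  df
}

#' Position-class-stratified traffic-light enrichment
#'
#' Runs the depletion test separately for CpGs sitting on core, medium, low
#' (and mixed) information-content column pairs of each TF's motif, and
#' emits a cross-TF paired comparison of core versus flanking
#' (medium + low) ratios.
#'
#' @param cytosines,calls,hits As in [count_tfbs_overlaps()].
#' @param position_classes Stacked [find_cpg_positions()] table.
#' @param global_fraction Genome-wide traffic-light fraction.
#' @return A list with `table` (per tf x kind x class enrichment rows,
#'   including a combined `flanking` stratum) and `paired_test` (paired
#'   t-test of core vs flanking ratios across TFs, or `NULL` when fewer than
#'   2 TFs have both).
#' @export
positional_enrichment <- function(cytosines, calls, hits, position_classes,
                                  global_fraction) {
  pos <- cpg_motif_positions(
    cytosines[cytosines$cytosine_id %in% calls$cytosine_id], hits,
    position_classes)
  pos <- pos[pos$class != "non_cpg_column", , drop = FALSE]
  if (nrow(pos) == 0L) return(list(table = pos, paired_test = NULL))
  pos$stratum <- pos$class
  flank <- pos[pos$class %in% c("medium", "low"), , drop = FALSE]
  if (nrow(flank) > 0L) {
    flank$stratum <- "flanking"
    pos <- rbind(pos, flank)
  }
  pos$is_tl <- calls$label[match(pos$cytosine_id, calls$cytosine_id)] ==
    "negative_significant"
  dedup <- unique(pos[, c("cytosine_id", "tf", "kind", "stratum", "is_tl")])
  key <- interaction(dedup$tf, dedup$kind, dedup$stratum, drop = TRUE)
  tab <- data.frame(
    tf = tapply(dedup$tf, key, `[`, 1L),
    kind = tapply(dedup$kind, key, `[`, 1L),
    stratum = tapply(dedup$stratum, key, `[`, 1L),
    n_cpg = as.integer(tapply(dedup$is_tl, key, length)),
    observed = as.integer(tapply(dedup$is_tl, key, sum)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  res <- enrichment_test(tab$observed, tab$n_cpg, global_fraction,
                         m_tests = nrow(tab))
  tab <- cbind(tab, res[, c("expected", "ratio", "chi2", "p",
                            "p_bonferroni", "p_binom", "direction")])
  core <- tab[tab$stratum == "core", ]
  fl <- tab[tab$stratum == "flanking", ]
  key2 <- paste(core$tf, core$kind)
  m <- match(key2, paste(fl$tf, fl$kind))
  paired <- data.frame(tf = core$tf, kind = core$kind,
                       core_ratio = core$ratio, flank_ratio = fl$ratio[m])
  paired <- paired[!is.na(paired$flank_ratio), , drop = FALSE]
  ptest <- if (nrow(paired) >= 2L &&
               sd(paired$core_ratio - paired$flank_ratio) > 0) {
    t.test(paired$core_ratio, paired$flank_ratio, paired = TRUE)
  } else NULL
  list(table = tab, paired_test = ptest, paired = paired)
}

#' Permutation calibration of the per-TF enrichment ratios
#'
#' Randomly permutes the traffic-light labels across analyzed CpGs and
#' recomputes every TF's observed/expected ratio and Bonferroni-significant
#' count; under the permutation null the mean ratio is 1 and significant
#' calls are rare, providing a calibration check of the whole enrichment
#' stage.
#'
#' @param membership Logical matrix, TFs x CpGs: CpG belongs to the TF's
#'   binding sites.
#' @param labels Logical vector over CpGs: is a traffic light.
#' @param n_perm Number of permutations (default 200).
#' @param alpha Family-wise level for the significant-call count.
#' @return data.frame with one row per permutation: `mean_ratio`,
#'   `n_significant`.
#' @export
permutation_calibration <- function(membership, labels, n_perm = 200L,
                                    alpha = 0.05) {
  n_in <- rowSums(membership)
  stopifnot(all(n_in > 0))
  g <- mean(labels)
  m <- nrow(membership)
  out <- data.frame(mean_ratio = numeric(n_perm),
                    n_significant = integer(n_perm))
  for (b in seq_len(n_perm)) {
    lab <- sample(labels)
    obs <- as.vector(membership %*% lab)
    res <- enrichment_test(obs, n_in, g, m_tests = m)
    out$mean_ratio[b] <- mean(res$ratio)
    out$n_significant[b] <- sum(res$p_bonferroni < alpha)
  }
  out
}
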