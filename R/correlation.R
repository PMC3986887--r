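#' Spearman correlation of a methylation and an expression profile
#'
#' Restricts both profiles to classes where both values are present
#' (pairwise-complete), ranks with average-rank tie handling and returns the
#' Pearson correlation of the ranks. Fewer than `min_n` paired classes, or a
#' profile with zero rank variance, yields an undefined correlation (`NA`),
#' which downstream stages exclude.
#'
#' @param x,y Numeric vectors indexed by the same classes (`NA` = missing).
#' @param min_n Minimum number of paired classes (default 5).
#' @return A list with `scc` (the correlation, or `NA`) and `n` (paired
#'   classes).
#' @export
spearman_cc <- function(x, y, min_n = 5L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) return(list(scc = NA_real_, n = n))
  scc <- suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
  list(scc = scc, n = n)
}

#' Significance of a Spearman correlation via the t transformation
#'
#' `t = scc * sqrt(n - 2) / sqrt(1 - scc^2)` referred to a Student's t
#' distribution with `n - 2` degrees of freedom; the P-value is two-sided and
#' the sign of the effect is read from `scc` separately. A perfect
#' correlation (|scc| = 1) has infinite t and the P-value is reported as the
#' limit 0.
#'
#' @param scc Spearman correlation coefficient(s).
#' @param n Number of paired observations (vectorized).
#' @return A data.frame with columns `t` and `p`.
#' @export
scc_significance <- function(scc, n) {
  t <- ifelse(abs(scc) < 1, scc * sqrt(n - 2) / sqrt(1 - scc^2),
              sign(scc) * Inf)
  p <- 2 * pt(-abs(t), df = n - 2)
  data.frame(t = t, p = p)
}

#' Correlate methylation profiles with the expression of containing promoters
#'
#' Computes one Spearman correlation (and its t-based P-value) per
#' (cytosine, promoter) pair; a cytosine inside several overlapping promoters
#' receives several correlations.
#'
#' @param meth_values Class-level methylation matrix (cytosines x classes,
#'   rows named by cytosine id).
#' @param expr_values Class-level expression matrix (clusters x classes, rows
#'   named by cluster id). Column order must match `meth_values`.
#' @param pairs data.frame with columns `cytosine_id`, `cluster_id` (e.g.
#'   from [assign_cytosines_to_promoters()]).
#' @param min_n Minimum paired classes per correlation.
#' @return data.frame with columns `cytosine_id`, `cluster_id`, `scc`, `n`,
#'   `t`, `p`; pairs with undefined correlation are dropped.
#' @export
correlate_profiles <- function(meth_values, expr_values, pairs, min_n = 5L) {
  stopifnot(identical(colnames(meth_values), colnames(expr_values)))
  ri <- match(pairs$cytosine_id, rownames(meth_values))
  ci <- match(pairs$cluster_id, rownames(expr_values))
  keep <- !is.na(ri) & !is.na(ci)
  ri <- ri[keep]; ci <- ci[keep]
  sccs <- numeric(length(ri)); ns <- integer(length(ri))
  for (k in seq_along(ri)) {
    r <- spearman_cc(meth_values[ri[k], ], expr_values[ci[k], ], min_n)
    sccs[k] <- r$scc; ns[k] <- r$n
  }
  ok <- !is.na(sccs)
  sig <- scc_significance(sccs[ok], ns[ok])
  data.frame(cytosine_id = pairs$cytosine_id[keep][ok],
             cluster_id = pairs$cluster_id[keep][ok],
             scc = sccs[ok], n = ns[ok], t = sig$t, p = sig$p,
             stringsAsFactors = FALSE)
}

#' Call CpG traffic lights
#'
#' A cytosine is called `negative_significant` (a CpG "traffic light") when
#' it is differentially methylated and at least one of its correlations has
#' `scc < 0` with `p <= alpha`; `positive_significant` when differential, not
#' negative-significant, and at least one correlation has `scc > 0` with
#' `p <= alpha`; otherwise `insignificant`. Cytosines significant in both
#' directions (via different promoters) are labelled negative and tallied in
#' the `both_signs` column.
#'
#' @param results Correlation table from [correlate_profiles()].
#' @param differential Named logical vector (or data.frame with columns
#'   `cytosine_id`, `differential`) flagging differentially methylated
#'   cytosines.
#' @param alpha Significance level (default 0.01).
#' @return data.frame with one row per cytosine: `cytosine_id`, `label`,
#'   `best_neg_p`, `best_pos_p`, `differential`, `both_signs`.
#' @export
call_traffic_lights <- function(results, differential, alpha = 0.01) {
  if (is.data.frame(differential))
    differential <- setNames(differential$differential,
                             differential$cytosine_id)
  ids <- unique(results$cytosine_id)
  f <- factor(results$cytosine_id, levels = ids)
  neg <- results$scc < 0 & results$p <= alpha
  pos <- results$scc > 0 & results$p <= alpha
  has_neg <- tapply(neg, f, any)
  has_pos <- tapply(pos, f, any)
  best_neg <- suppressWarnings(tapply(ifelse(results$scc < 0, results$p, NA),
                                      f, min, na.rm = TRUE))
  best_pos <- suppressWarnings(tapply(ifelse(results$scc > 0, results$p, NA),
                                      f, min, na.rm = TRUE))
  diff_flag <- as.logical(differential[ids])
  diff_flag[is.na(diff_flag)] <- FALSE
  label <- ifelse(diff_flag & has_neg, "negative_significant",
           ifelse(diff_flag & has_pos, "positive_significant",
                  "insignificant"))
  data.frame(cytosine_id = ids, label = label,
             best_neg_p = ifelse(is.finite(best_neg), best_neg, NA),
             best_pos_p = ifelse(is.finite(best_pos), best_pos, NA),
             differential = diff_flag,
             both_signs = as.logical(has_neg & has_pos),
             stringsAsFactors = FALSE)
}

#' Count and fraction table of significant correlations by sign and level
#'
#' Summarises, for each significance level, how many analyzed cytosines have
#' at least one significantly negative (positive) correlation with a nearby
#' TSS, together with the fraction of the analyzed total — the per-sign
#' summary the study reports for levels 0.05, 0.01 and 0.001.
#'
#' @param results Correlation table from [correlate_profiles()].
#' @param alphas Significance levels (default `c(0.05, 0.01, 0.001)`).
#' @param total Total analyzed cytosines; default the number of distinct
#'   cytosines in `results`.
#' @return data.frame with columns `sign`, `alpha`, `count`, `fraction`.
#' @export
traffic_light_summary <- function(results, alphas = c(0.05, 0.01, 0.001),
                                  total = length(unique(results$cytosine_id))) {
  ids <- unique(results$cytosine_id)
  f <- factor(results$cytosine_id, levels = ids)
  rows <- list()
  for (sgn in c("negative", "positive")) {
    sel <- if (sgn == "negative") results$scc < 0 else results$scc > 0
    for (a in alphas) {
      cnt <- sum(tapply(sel & results$p <= a, f, any))
      rows[[length(rows) + 1L]] <- data.frame(sign = sgn, alpha = a,
                                              count = cnt,
                                              fraction = cnt / total)
    }
  }
  do.call(rbind, rows)
}

#' Fractions of significant cytosines from count data
#'
#' Pure arithmetic helper turning per-level significant counts and an
#' analyzed total into fractions (count / total), as used in the per-sign
#' summary table.
#'
#' @param counts Named or unnamed numeric vector of significant counts.
#' @param total Total number of analyzed cytosines.
#' @return Numeric vector of fractions, same length as `counts`.
#' @export
significant_fractions <- function(counts, total) {
  if (total <= 0) stop("total must be positive")
  counts / total
}
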