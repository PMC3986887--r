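calls_fixture <- function(ids, labels) {
  data.frame(cytosine_id = ids, label = labels,
             best_neg_p = NA, best_pos_p = NA,
             differential = TRUE, both_signs = FALSE,
             stringsAsFactors = FALSE)
}

test_that("CpGs count once per TF per model kind regardless of hit multiplicity", {
  cyt <- grs("chr1", c(100, 200, 300), c(100, 200, 300), "+",
             cytosine_id = c("a", "b", "c"))
  calls <- calls_fixture(c("a", "b"), c("negative_significant",
                                        "insignificant"))
  # three overlapping hits of TF1 around 100; one TF2 hit around 100 and 200
  hits <- grs("chr1", c(95, 96, 97, 95, 195), c(110, 111, 112, 110, 210),
              c("+", "+", "-", "+", "+"),
              tf = c("TF1", "TF1", "TF1", "TF2", "TF2"),
              kind = "pwm")
  oc <- count_tfbs_overlaps(cyt, calls, hits)
  expect_equal(oc$n_cpg_in_tfbs[oc$tf == "TF1"], 1)
  expect_equal(oc$observed_negative[oc$tf == "TF1"], 1)
  expect_equal(oc$n_cpg_in_tfbs[oc$tf == "TF2"], 2)
  expect_equal(oc$observed_negative[oc$tf == "TF2"], 1)
  # cytosine c has no correlation result: never counted
  expect_false(any(oc$n_cpg_in_tfbs > 2))
  # no hits at all
  expect_equal(nrow(count_tfbs_overlaps(cyt, calls, hits[0])), 0)
})

test_that("chi-square depletion test matches the closed form and an independent oracle", {
  # observed equals expected: chi2 = 0, p = 1
  r0 <- enrichment_test(20, 100, 0.2)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$direction, "none")

  # o=5, n=100, g=0.166
  r <- enrichment_test(5, 100, 0.166)
  expect_equal(r$expected, 16.6)
  expect_equal(r$ratio, 5 / 16.6, tolerance = 1e-12)
  chi2_hand <- (5 - 16.6)^2 / 16.6 + (95 - 83.4)^2 / 83.4
  expect_equal(r$chi2, chi2_hand, tolerance = 1e-12)
  # independent oracle: base R goodness-of-fit test without correction
  ref <- chisq.test(c(5, 95), p = c(0.166, 0.834), correct = FALSE)
  expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # exact binomial companion
  expect_equal(r$p_binom, binom.test(5, 100, 0.166)$p.value, tolerance = 1e-12)

  # Bonferroni arithmetic and direction gating
  r2 <- enrichment_test(5, 100, 0.166, m_tests = 5)
  expect_equal(r2$p_bonferroni, pmin(1, r2$p * 5))
  r3 <- enrichment_test(980, 1000, 0.5, m_tests = 2)
  expect_equal(r3$direction, "over")
  r4 <- enrichment_test(20, 1000, 0.5, m_tests = 2)
  expect_equal(r4$direction, "under")
  # p = 0.02-ish with m = 5 exceeds 0.05: direction none
  stopifnot(enrichment_test(72, 100, 0.6)$p < 0.05)
  expect_equal(enrichment_test(72, 100, 0.6, m_tests = 50)$direction, "none")

  expect_error(enrichment_test(5, 0, 0.2), "positive")
  expect_error(enrichment_test(5, 10, 0), "global_fraction")
})

test_that("chi-square p is close to the exact binomial tail at moderate counts", {
  # the 1-df chi-square is the large-sample approximation of the two-sided
  # binomial test; on small n they agree to the documented approximation error
  for (o in c(2, 5, 8)) {
    r <- enrichment_test(o, 30, 0.3)
    expect_lt(abs(r$p - r$p_binom), 0.2)
  }
})

test_that("adding traffic lights inside a TF's hits never decreases its ratio", {
  g <- 0.2
  r_low <- enrichment_test(4, 50, g)$ratio
  r_high <- enrichment_test(5, 50, g)$ratio
  expect_gt(r_high, r_low)
})

test_that("per-TF table applies the at-least-one-observed inclusion rule", {
  oc <- data.frame(tf = c("T1", "T2", "T3"), kind = "pwm",
                   n_cpg_in_tfbs = c(50, 40, 30),
                   observed_negative = c(5, 0, 3),
                   observed_positive = c(0, 1, 0))
  et <- tf_enrichment(oc, 0.2, sign = "negative")
  expect_setequal(et$tf, c("T1", "T3"))
  # Bonferroni m defaults to the number of included TFs
  expect_equal(et$p_bonferroni, pmin(1, et$p * 2))
})

test_that("function-class comparison: means, Welch test and degenerate paths", {
  enr <- data.frame(tf = paste0("T", 1:8),
                    ratio = c(0.5, 0.5, 0.5, 0.5, 0.7, 0.7, 0.7, 0.7))
  labels <- data.frame(tf = paste0("T", 1:8),
                       fun = rep(c("repressor", "activator"), each = 4))
  out <- compare_function_classes(enr, labels)
  expect_equal(unname(out$means["repressor"]), 0.5)
  expect_equal(unname(out$means["activator"]), 0.7)
  # zero variance with separated means: flagged p -> 0
  expect_true(out$tests$degenerate)
  expect_equal(out$tests$p, 0)

  # identical distributions: t = 0, p = 1
  enr2 <- enr; enr2$ratio <- rep(c(0.4, 0.6), 4)
  labels2 <- data.frame(tf = paste0("T", 1:8),
                        fun = rep(rep(c("repressor", "activator"), each = 2), 2))
  out2 <- compare_function_classes(enr2, labels2)
  expect_equal(out2$tests$t, 0)
  expect_equal(out2$tests$p, 1)

  # non-degenerate case agrees with stats::t.test (Welch)
  set.seed(2)
  enr3 <- data.frame(tf = paste0("T", 1:20),
                     ratio = c(rnorm(10, 0.5, 0.1), rnorm(10, 0.65, 0.15)))
  labels3 <- data.frame(tf = paste0("T", 1:20),
                        fun = rep(c("repressor", "activator"), each = 10))
  out3 <- compare_function_classes(enr3, labels3)
  ref <- t.test(enr3$ratio[1:10], enr3$ratio[11:20])
  expect_equal(out3$tests$p, ref$p.value)

  # class with < 2 members is skipped with a warning
  expect_warning(compare_function_classes(
    data.frame(tf = c("T1", "T2", "T3"), ratio = c(0.4, 0.5, 0.6)),
    data.frame(tf = c("T1", "T2", "T3"),
               fun = c("repressor", "repressor", "activator"))), "skipped")
})

test_that("function-class recovery: planted 0.5 vs 0.6 separation", {
  # power simulation: recovered means within 0.04 and p < 0.05 in most
  # replicates
  set.seed(4)
  hit_means <- 0; pow <- 0
  n_rep <- 100
  for (b in seq_len(n_rep)) {
    enr <- data.frame(tf = paste0("T", 1:60),
                      ratio = c(rnorm(30, 0.5, 0.1), rnorm(30, 0.6, 0.1)))
    labels <- data.frame(tf = paste0("T", 1:60),
                         fun = rep(c("repressor", "activator"), each = 30))
    out <- compare_function_classes(enr, labels)
    ok <- abs(out$means["repressor"] - 0.5) < 0.04 &&
      abs(out$means["activator"] - 0.6) < 0.04
    hit_means <- hit_means + ok
    pow <- pow + (out$tests$p < 0.05)
  }
  expect_gt(hit_means / n_rep, 0.8)
  expect_gt(pow / n_rep, 0.8)
})

test_that("CpGs are routed to the motif column pair they occupy, on both strands", {
  pc <- data.frame(tf = "TFCF", j = c(1, 4), class = c("medium", "core"))
  # forward hit at [1001,1008]; CpG C at 1004 -> pair (4,5): core
  hits <- grs("chr1", 1001, 1008, "+", tf = "TFCF", kind = "pwm")
  cyt <- grs("chr1", 1004, 1004, "+", cytosine_id = "a")
  pos <- cpg_motif_positions(cyt, hits, pc)
  expect_equal(pos$j, 4)
  expect_equal(pos$class, "core")
  # minus-strand hit: genomic C at p pairs with column end - p
  hitsm <- grs("chr1", 1001, 1008, "-", tf = "TFCF", kind = "pwm")
  cytm <- grs("chr1", 1004, 1004, "+", cytosine_id = "b")
  posm <- cpg_motif_positions(cytm, hitsm, pc)
  expect_equal(posm$j, 1008 - 1004)
  expect_equal(posm$class, "core")
  # offset not a C.G column pair of the model
  cyt2 <- grs("chr1", 1002, 1002, "+", cytosine_id = "c")
  expect_equal(cpg_motif_positions(cyt2, hits, pc)$class, "non_cpg_column")
  # model with no CpG pairs: everything non_cpg_column
  pos3 <- cpg_motif_positions(cyt, hits,
                              data.frame(tf = character(), j = integer(),
                                         class = character()))
  expect_equal(pos3$class, "non_cpg_column")
})

test_that("positional enrichment separates planted core-only depletion", {
  # enrichment-stage parameter recovery: labels planted with core-only
  # depletion 0.4, flanking left untouched
  pcm <- pcm_core_flank()
  cfg <- simulation_config(
    n_tss = 200, n_cpg_per_promoter = 14,
    motif_set = list(list(pcm = pcm, tf = "TFCF", label = "repressor")),
    plant_prob = 1, motif_cpg_weight = 10, frac_negative = 0.3,
    depletion_factor = 1, depletion_core = 0.4, depletion_flank = 1,
    seed = 17)
  e <- simulate_expression(cfg)
  p <- simulate_promoters(e$clusters, cfg)
  calls <- calls_fixture(p$truth$cytosine_id,
                         ifelse(p$truth$label == "negative",
                                "negative_significant", "insignificant"))
  hits <- p$occurrences
  hits$kind <- "pwm"
  g <- mean(calls$label == "negative_significant")
  pe <- positional_enrichment(p$cytosines, calls, hits,
                              find_cpg_positions(pcm), g)
  core <- pe$table[pe$table$stratum == "core", ]
  flank <- pe$table[pe$table$stratum == "flanking", ]
  expect_gt(core$n_cpg, 50)
  expect_gt(flank$n_cpg, 10)
  expect_lt(core$ratio, flank$ratio)
  # core ratio near the planted 0.4, flanking near 1
  expect_lt(core$ratio, 0.7)
  expect_gt(flank$ratio, 0.6)
})

test_that("permutation calibration: mean ratio 1 and rare significant calls", {
  set.seed(6)
  n_cpg <- 2000; n_tf <- 15
  membership <- matrix(runif(n_tf * n_cpg) < 0.15, n_tf)
  labels <- runif(n_cpg) < 0.166
  out <- permutation_calibration(membership, labels, n_perm = 50)
  expect_lt(abs(mean(out$mean_ratio) - 1), 0.05)
  expect_lte(mean(out$n_significant), 0.05 * n_tf)
})
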