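test_that("configuration invariants are enforced", {
  expect_error(simulation_config(frac_negative = 0.7, frac_positive = 0.4),
               "exceed 1")
  expect_error(simulation_config(depletion_factor = 0), "depletion_factor")
  expect_error(simulation_config(depletion_factor = 1.2), "depletion_factor")
  expect_error(simulation_config(n_normal = 60, n_classes = 50), "n_normal")
  expect_error(simulation_config(n_classes = 2, n_normal = 2), "3 classes")
  expect_error(simulation_config(n_tss = 0), "TSS")
})

test_that("expression simulation: shape, non-negativity, determinism", {
  cfg <- simulation_config(n_tss = 20, n_classes = 5, n_normal = 4, seed = 7)
  e1 <- simulate_expression(cfg)
  expect_true(all(e1$counts >= 0))
  expect_true(all(e1$counts == floor(e1$counts)))
  expect_equal(nrow(e1$counts), 20)
  expect_equal(ncol(e1$counts), 15)   # 5 classes x 3 samples
  expect_equal(sum(e1$sample_map$normal_flag), 12)
  # every class has at least one sample
  expect_setequal(unique(e1$sample_map$class_id),
                  sprintf("class_%02d", 1:5))
  # same seed -> bit-identical
  e2 <- simulate_expression(cfg)
  expect_identical(e1$counts, e2$counts)
  # different seed -> different draw
  e3 <- simulate_expression(simulation_config(n_tss = 20, n_classes = 5,
                                              n_normal = 4, seed = 8))
  expect_false(identical(e1$counts, e3$counts))
})

test_that("degenerate generator: equal class means, no dispersion", {
  cfg <- simulation_config(n_tss = 6, n_classes = 4, n_normal = 3,
                           sd_log_expr = 0, libsize_sd = 0,
                           frac_housekeeping = 0,
                           count_noise = "none", seed = 1)
  e <- simulate_expression(cfg)
  cls <- average_by_class(e$counts, e$sample_map)
  expect_true(all(apply(cls, 1, function(v) length(unique(v)) == 1)))
})

test_that("planted methylation profiles are monotone in expression rank", {
  cfg <- simulation_config(n_classes = 10, n_normal = 8, noise_sd = 0,
                           replica_sd = 0, frac_missing = 0, seed = 2)
  expr <- matrix(rlnorm(10), 1, dimnames = list("t1", sprintf("cl%02d", 1:10)))
  asg <- data.frame(cytosine_id = c("chrS1:100", "chrS1:200", "chrS1:300"),
                    cluster_id = "t1",
                    label = c("negative", "positive", "null"))
  m <- simulate_methylation(expr, cfg, assignments = asg)
  expect_equal(cor(m$class_values["chrS1:100", ], expr[1, ],
                   method = "spearman"), -1)
  expect_equal(cor(m$class_values["chrS1:200", ], expr[1, ],
                   method = "spearman"), 1)
  # amplitude > 50 by construction at zero noise
  expect_gt(amplitude(m$class_values["chrS1:100", ]), 50)
  expect_true(all(m$class_values >= 0 & m$class_values <= 100))
  expect_error(simulate_methylation(expr[, 1:2, drop = FALSE], cfg),
               "3 classes")
})

test_that("methylation simulation is seed-deterministic and honours coverage knobs", {
  cfg <- simulation_config(n_tss = 30, n_cpg_per_promoter = 5,
                           n_classes = 8, n_normal = 6,
                           frac_low_coverage = 0.3, frac_missing = 0.2,
                           seed = 9)
  expr <- matrix(rlnorm(40 * 8), 40,
                 dimnames = list(sprintf("t%02d", 1:40), sprintf("c%d", 1:8)))
  m1 <- simulate_methylation(expr, cfg)
  m2 <- simulate_methylation(expr, cfg)
  expect_identical(m1$meth, m2$meth)
  expect_true(all(m1$meth$coverage >= 1))
  # roughly the stated fraction of records has coverage below 10 reads
  expect_gt(mean(m1$meth$coverage < 10), 0.15)
  expect_lt(mean(m1$meth$coverage < 10), 0.45)
  # missing records: fewer rows than the full cytosine x sample grid
  full <- nrow(m1$class_values) * 24
  expect_lt(nrow(m1$meth), full * 0.9)
  expect_gt(nrow(m1$meth), full * 0.65)
})

test_that("promoter simulation plants occurrences within bounds and applies depletion", {
  pcm <- pcm_consensus_cg()
  cfg <- simulation_config(n_tss = 150, n_cpg_per_promoter = 12,
                           motif_set = list(list(pcm = pcm, tf = "TF1",
                                                 label = "repressor")),
                           plant_prob = 1, motif_cpg_weight = 6,
                           depletion_factor = 0.5, frac_negative = 0.3,
                           seed = 21)
  e <- simulate_expression(cfg)
  p <- simulate_promoters(e$clusters, cfg)
  # every occurrence lies inside its promoter
  ov <- GenomicRanges::findOverlaps(p$occurrences, p$promoters,
                                    type = "within", ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))),
               length(p$occurrences))
  # degenerate PCM: every occurrence is the consensus (possibly reverse
  # complemented)
  seqs <- hit_sequences(p$occurrences, p$sequences, p$promoters)
  expect_true(all(seqs == "ACCGGTAT"))
  # all cytosines sit on genuine CG dinucleotides
  cy <- hit_sequences(GenomicRanges::resize(p$cytosines, 2), p$sequences,
                      p$promoters)
  expect_true(all(cy == "CG"))
  # planted-negative rate inside occurrences is about half the outside rate
  t_in <- mean(p$truth$label[p$truth$in_motif] == "negative")
  t_out <- mean(p$truth$label[!p$truth$in_motif] == "negative")
  n_in <- sum(p$truth$in_motif)
  expect_gt(n_in, 40)
  se <- sqrt(t_out * (1 - t_out) / n_in)
  expect_lt(abs(t_in - 0.5 * t_out), 4 * se)
})

test_that("no depletion when the factor is 1", {
  pcm <- pcm_consensus_cg()
  cfg <- simulation_config(n_tss = 150, n_cpg_per_promoter = 12,
                           motif_set = list(list(pcm = pcm, tf = "TF1",
                                                 label = "both")),
                           plant_prob = 1, motif_cpg_weight = 6,
                           depletion_factor = 1, frac_negative = 0.3,
                           seed = 22)
  e <- simulate_expression(cfg)
  p <- simulate_promoters(e$clusters, cfg)
  t_in <- mean(p$truth$label[p$truth$in_motif] == "negative")
  t_out <- mean(p$truth$label[!p$truth$in_motif] == "negative")
  n_in <- sum(p$truth$in_motif)
  se <- sqrt(t_out * (1 - t_out) / n_in)
  expect_lt(abs(t_in - t_out), 4 * se)
})

test_that("motif longer than the promoter is rejected", {
  cfg <- simulation_config(n_tss = 5, seed = 1)
  e <- simulate_expression(cfg)
  long <- make_pcm(rep(list(c(15, 0, 0, 0)), 3000))
  cfg$motif_set <- list(list(pcm = long, tf = "LONG", label = "both"))
  expect_error(simulate_promoters(e$clusters, cfg), "longer than promoter")
})

test_that("alignment simulation converges to the PCM and is deterministic", {
  # degenerate PCM: identical sequences
  aln <- simulate_alignment(pcm_consensus_cg(), 15, seed = 1)
  expect_equal(unique(aln$seqs), "ACCGGTAT")
  expect_equal(aln$N, 15)
  # uniform PCM, large n: empirical frequencies within 0.01 of 0.25
  unif <- make_pcm(rep(list(c(1, 1, 1, 1)), 5))
  big <- simulate_alignment(unif, 40000, seed = 2)
  freq <- build_pcm(big) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))
  # determinism
  expect_identical(simulate_alignment(unif, 100, seed = 3)$seqs,
                   simulate_alignment(unif, 100, seed = 3)$seqs)
  expect_error(simulate_alignment(unif, 0), "n_seqs")
})

test_that("whole-dataset simulation is reproducible end to end", {
  cfg <- simulation_config(n_tss = 25, n_classes = 6, n_normal = 4,
                           n_cpg_per_promoter = 4,
                           motif_set = list(list(pcm = pcm_consensus_cg(),
                                                 tf = "TF1", label = "both")),
                           seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$methylation, d2$methylation)
  expect_identical(d1$expression$counts, d2$expression$counts)
  expect_identical(as.character(d1$sequences), as.character(d2$sequences))
  expect_identical(d1$truth, d2$truth)
})
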