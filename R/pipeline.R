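#' Pipeline run configuration
#'
#' Surfaces every tunable constant of the analysis with its standard default:
#' promoter window 1500/500 bp, coverage >= 10 reads, profile completeness
#' >= 50% of classes, amplitude > 50 percentage points, correlation
#' significance levels 0.05/0.01/0.001 (calls at 0.01), motif-model P-value
#' 0.0005, minimum 15 sequences per filtered alignment.
#'
#' @param sim A [simulation_config()] describing the synthetic inputs.
#' @param alphas Significance levels, sorted descending; calls use
#'   `alphas[2]`.
#' @param model_p Motif score threshold P-value.
#' @param min_cov Minimum reads per class-level methylation value.
#' @param min_frac Minimum fraction of classes with data.
#' @param min_amplitude Strict amplitude bound for differential methylation.
#' @param min_align_n Minimum sequences in a filtered alignment.
#' @param n_align Alignment depth simulated per motif.
#' @param normal_only Restrict the analysis to normal cell-type classes.
#' @param kinds Model kinds to scan with.
#' @param seed Seed for the model-alignment simulation stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), alphas = c(0.05, 0.01, 0.001),
                       model_p = 5e-4, min_cov = 10, min_frac = 0.5,
                       min_amplitude = 50, min_align_n = 15L, n_align = 60L,
                       normal_only = FALSE, kinds = c("pwm", "rdm"),
                       seed = sim$seed) {
  stopifnot(all(diff(alphas) < 0))
  structure(as.list(environment()), class = "run_config")
}

#' Run the whole analysis end to end
#'
#' Stages run in dependency order: simulate, prepare (class averaging, RLE
#' normalization, filters), correlate (traffic-light calling), build-models
#' (PWM/RDM with calibrated thresholds and CpG position classes), scan,
#' enrich (per-TF, per-function-class and positional), annotate. All stage
#' outputs are written under `outdir` and recorded with MD5 digests in a run
#' manifest; reruns with the same configuration and seed reproduce the
#' digests byte for byte.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return A list with all stage results plus `manifest` (data.frame of
#'   `stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  sim <- stage("simulate", {
    d <- simulate_dataset(config$sim)
    write_expression_table(d$expression$counts, d$expression$clusters,
                           file.path(outdir, "expression.tsv"))
    write_methylation_table(d$methylation, file.path(outdir, "methylation.tsv"))
    write_sample_map(d$expression$sample_map, file.path(outdir, "samples.tsv"))
    Biostrings::writeXStringSet(d$sequences,
                                file.path(outdir, "promoters.fa"))
    write_bed(d$occurrences, file.path(outdir, "occurrences.bed"), "tf")
    write_bed(d$cytosines, file.path(outdir, "cytosines.bed"), "cytosine_id")
    write.table(d$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (f in c("expression.tsv", "methylation.tsv", "samples.tsv",
                "promoters.fa", "occurrences.bed", "cytosines.bed",
                "truth.tsv"))
      note("simulate", file.path(outdir, f))
    d
  })

  smap <- sim$expression$sample_map
  if (config$normal_only) {
    keep_classes <- unique(smap$class_id[smap$normal_flag])
    smap <- smap[smap$normal_flag, , drop = FALSE]
  } else keep_classes <- unique(smap$class_id)

  # -- prepare ----------------------------------------------------------------
  prep <- stage("prepare", {
    counts <- sim$expression$counts[, smap$sample_id, drop = FALSE]
    norm <- rle_normalize(counts)
    expr_class <- average_by_class(norm$normalized, smap)
    keep_tss <- filter_tss(expr_class)
    expr_class <- expr_class[keep_tss, , drop = FALSE]
    meth_long <- sim$methylation[sim$methylation$sample %in% smap$sample_id, ]
    mm <- methylation_matrices(meth_long, samples = smap$sample_id)
    cls <- average_by_class(mm$values, smap, coverage = mm$coverage)
    fl <- filter_cytosines(cls$values, cls$coverage,
                           min_cov = config$min_cov,
                           min_frac = config$min_frac)
    meth_class <- fl$values[fl$retained, , drop = FALSE]
    amp <- profile_amplitudes(meth_class)
    diff_flag <- !is.na(amp) & amp > config$min_amplitude
    write.table(
      data.frame(cytosine_id = rownames(meth_class),
                 amplitude = amp, differential = diff_flag,
                 round(meth_class, 4), check.names = FALSE),
      file.path(outdir, "meth_class.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write.table(
      data.frame(cluster_id = rownames(expr_class),
                 round(expr_class, 4), check.names = FALSE),
      file.path(outdir, "expr_class.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    note("prepare", file.path(outdir, "meth_class.tsv"))
    note("prepare", file.path(outdir, "expr_class.tsv"))
    list(expr_class = expr_class, meth_class = meth_class,
         amplitude = amp, differential = diff_flag)
  })

  # -- correlate --------------------------------------------------------------
  corr <- stage("correlate", {
    cyt <- sim$cytosines[sim$cytosines$cytosine_id %in%
                           rownames(prep$meth_class)]
    proms <- sim$promoters
    proms$cluster_id <- sim$expression$clusters$cluster_id
    proms <- proms[proms$cluster_id %in% rownames(prep$expr_class)]
    pairs <- assign_cytosines_to_promoters(cyt, proms)
    results <- correlate_profiles(prep$meth_class, prep$expr_class, pairs)
    diff_flag <- setNames(prep$differential, rownames(prep$meth_class))
    calls <- call_traffic_lights(results, diff_flag,
                                 alpha = config$alphas[2])
    summ <- traffic_light_summary(results, alphas = config$alphas,
                                  total = nrow(prep$meth_class))
    write.table(within(results, { scc <- round(scc, 6); t <- round(t, 4)
                                  p <- signif(p, 6) }),
                file.path(outdir, "correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(outdir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summ, file.path(outdir, "summary_table1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("correlate", file.path(outdir, "correlations.tsv"))
    note("correlate", file.path(outdir, "calls.tsv"))
    note("correlate", file.path(outdir, "summary_table1.tsv"))
    list(results = results, calls = calls, summary = summ, cytosines = cyt)
  })

  # -- build-models -----------------------------------------------------------
  models <- stage("build-models", {
    out <- list()
    for (mi in seq_along(config$sim$motif_set)) {
      m <- config$sim$motif_set[[mi]]
      aln <- simulate_alignment(m$pcm, config$n_align,
                                seed = config$seed + 100L + mi, tf_id = m$tf)
      pcm <- build_pcm(aln)
      pwm <- calibrate_threshold(build_pwm(pcm), target_p = config$model_p)
      filt <- filter_alignment(aln, pwm, min_n = config$min_align_n)
      rdm <- if (!is.null(filt))
        calibrate_threshold(build_rdm(filt), target_p = config$model_p)
      else NULL
      out[[m$tf]] <- list(tf = m$tf, label = m$label, alignment = aln,
                          pcm = pcm, pwm = pwm, rdm = rdm,
                          cpg_positions = find_cpg_positions(pcm))
    }
    con <- file(file.path(outdir, "models.tsv"), "w")
    writeLines("tf\tkind\tL\tthreshold\tthreshold_p", con)
    for (mo in out) {
      writeLines(sprintf("%s\tpwm\t%d\t%.4f\t%.3g", mo$tf, mo$pwm$L,
                         mo$pwm$threshold, mo$pwm$threshold_p), con)
      if (!is.null(mo$rdm))
        writeLines(sprintf("%s\trdm\t%d\t%.6f\t%.3g", mo$tf, mo$rdm$L,
                           mo$rdm$threshold, mo$rdm$threshold_p), con)
    }
    close(con)
    note("build-models", file.path(outdir, "models.tsv"))
    out
  })

  # -- scan -------------------------------------------------------------------
  hits <- stage("scan", {
    all <- list()
    for (mo in models) {
      if ("pwm" %in% config$kinds)
        all[[length(all) + 1L]] <- scan_promoters(mo$pwm, sim$sequences,
                                                  sim$promoters)
      if ("rdm" %in% config$kinds && !is.null(mo$rdm))
        all[[length(all) + 1L]] <- scan_promoters(mo$rdm, sim$sequences,
                                                  sim$promoters)
    }
    h <- if (length(all)) do.call(c, all) else GRanges()
    df <- data.frame(chrom = as.character(seqnames(h)),
                     start0 = start(h) - 1L, end0 = end(h),
                     tf = h$tf, score = round(h$score, 6),
                     strand = as.character(strand(h)), kind = h$kind)
    write.table(df, file.path(outdir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("scan", file.path(outdir, "hits.tsv"))
    h
  })

  # -- enrich -----------------------------------------------------------------
  enr <- stage("enrich", {
    g <- mean(corr$calls$label == "negative_significant")
    oc <- count_tfbs_overlaps(corr$cytosines, corr$calls, hits)
    etab <- if (nrow(oc) > 0 && g > 0 && g < 1)
      tf_enrichment(oc, g) else NULL
    labels <- data.frame(
      tf = vapply(config$sim$motif_set, `[[`, "", "tf"),
      fun = vapply(config$sim$motif_set, `[[`, "", "label"),
      stringsAsFactors = FALSE)
    classes <- if (!is.null(etab) && nrow(etab) >= 4L)
      tryCatch(compare_function_classes(etab, labels),
               warning = function(w) NULL) else NULL
    pc <- do.call(rbind, lapply(models, `[[`, "cpg_positions"))
    postab <- if (g > 0 && g < 1 && length(hits) > 0)
      positional_enrichment(corr$cytosines, corr$calls, hits, pc, g)
    else NULL
    if (!is.null(etab)) {
      write.table(cbind(etab[, c("tf", "kind")],
                        round(etab[, c("observed", "n_in_tfbs", "expected",
                                       "ratio", "chi2")], 6),
                        p = signif(etab$p, 6),
                        p_bonferroni = signif(etab$p_bonferroni, 6),
                        direction = etab$direction),
                  file.path(outdir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      note("enrich", file.path(outdir, "enrichment.tsv"))
    }
    if (!is.null(postab) && nrow(postab$table) > 0) {
      write.table(postab$table, file.path(outdir, "positional.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrich", file.path(outdir, "positional.tsv"))
    }
    list(overlaps = oc, enrichment = etab, function_classes = classes,
         positional = postab, global_fraction = g)
  })

  # -- annotate ---------------------------------------------------------------
  ann <- stage("annotate", {
    genes <- GRanges(seqnames(sim$expression$clusters),
                     IRanges(start(sim$expression$clusters),
                             width = 3000L),
                     strand = strand(sim$expression$clusters))
    gtracks <- derive_gene_tracks(genes)
    tracks <- list(
      CGI = resize(sim$promoters, 600L, fix = "center"),
      gene_promoters = gtracks$promoter,
      gene_bodies = gtracks$gene_body)
    calls <- corr$calls
    sets <- list(
      traffic_light = corr$cytosines[
        corr$cytosines$cytosine_id %in%
          calls$cytosine_id[calls$label == "negative_significant"]],
      positive = corr$cytosines[
        corr$cytosines$cytosine_id %in%
          calls$cytosine_id[calls$label == "positive_significant"]],
      insignificant = corr$cytosines[
        corr$cytosines$cytosine_id %in%
          calls$cytosine_id[calls$label == "insignificant"]])
    mat <- colocalize(sets, tracks)
    write.table(data.frame(class = rownames(mat), round(mat, 4),
                           check.names = FALSE),
                file.path(outdir, "annotation_table2.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("annotate", file.path(outdir, "annotation_table2.tsv"))
    mat
  })

  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(sim = sim, prepared = prep, correlation = corr, models = models,
       hits = hits, enrichment = enr, annotation = ann, manifest = manifest)
}
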