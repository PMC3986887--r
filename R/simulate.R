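#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic methylome-transcriptome
#' generator. Defaults state the world the analysis assumes: 50 cell-type
#' classes of which 36 are normal, a 16.6% genome-wide rate of planted
#' negatively correlated cytosines and 0.8% positive, and a twofold
#' depletion of planted negatives inside motif occurrences.
#'
#' @param n_classes Number of cell-type classes (default 50).
#' @param n_normal Number of classes flagged normal (default 36).
#' @param n_tss Number of TSS clusters (default 200).
#' @param samples_per_class Samples per class (scalar or vector; default 3,
#'   emulating technical/biological replicas to be averaged away).
#' @param n_cpg_per_promoter Mean number of measured cytosines per promoter
#'   (default 10).
#' @param frac_negative Target fraction of planted negatively correlated
#'   cytosines outside motifs (default 0.166).
#' @param frac_positive Target fraction planted positive (default 0.008).
#' @param noise_sd Class-level methylation noise, percentage points
#'   (default 5).
#' @param replica_sd Per-sample jitter around the class value (default 3).
#' @param depletion_factor Multiplicative reduction (0, 1] of the planted
#'   negative probability inside planted motif occurrences (default 0.5).
#' @param depletion_core,depletion_flank Optional position-class-specific
#'   depletion factors; when set, a CpG inside a planted occurrence at a
#'   core (resp. non-core) CpG column pair uses these instead of
#'   `depletion_factor`.
#' @param motif_set List of motif entries, each a list with elements `pcm`
#'   (a [build_pcm()] matrix), `tf` and `label` (activator/repressor/both).
#' @param plant_prob Probability that a given motif is planted in a given
#'   promoter (default 0.6).
#' @param motif_cpg_weight Sampling weight multiplier for CpG dinucleotides
#'   inside planted occurrences when drawing measured cytosines (default 1;
#'   raising it concentrates the measured set on binding sites without
#'   biasing the per-position label probabilities).
#' @param background Background nucleotide composition of promoter sequence.
#' @param mean_log_expr,sd_log_expr Log-normal class-mean expression
#'   parameters.
#' @param frac_housekeeping Fraction of clusters simulated as stably,
#'   strongly expressed housekeeping-like TSSs (default 0.1). Real CAGE
#'   libraries always contain such clusters; they are the reference features
#'   the median-of-ratios normalization relies on.
#' @param hk_mean_log,hk_sd_log Log-scale mean and class-to-class SD of the
#'   housekeeping clusters.
#' @param libsize_sd SD of log library-size factors across samples
#'   (default 0.4; makes RLE normalization non-trivial).
#' @param count_noise `"poisson"` (default) or `"none"` (deterministic
#'   rounded means, for degenerate-generator checks).
#' @param null_mix Mixture weights (low, high, intermediate) of the
#'   expression-independent methylation levels of null cytosines.
#' @param cov_mean_high,cov_mean_low Mean read coverages of well- and
#'   poorly-covered measurements.
#' @param frac_low_coverage Fraction of measurements drawn from the
#'   low-coverage regime (default 0.1).
#' @param frac_missing Fraction of (cytosine, sample) records dropped
#'   entirely (default 0.1).
#' @param seed Random seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_classes = 50L, n_normal = 36L, n_tss = 200L,
                              samples_per_class = 3L,
                              n_cpg_per_promoter = 10L,
                              frac_negative = 0.166, frac_positive = 0.008,
                              noise_sd = 5, replica_sd = 3,
                              depletion_factor = 0.5,
                              depletion_core = NULL, depletion_flank = NULL,
                              motif_set = list(), plant_prob = 0.6,
                              motif_cpg_weight = 1,
                              background = c(0.25, 0.25, 0.25, 0.25),
                              mean_log_expr = 2, sd_log_expr = 1,
                              frac_housekeeping = 0.1,
                              hk_mean_log = 6, hk_sd_log = 0.25,
                              libsize_sd = 0.4,
                              count_noise = c("poisson", "none"),
                              null_mix = c(low = 0.4, high = 0.4, mid = 0.2),
                              cov_mean_high = 30, cov_mean_low = 5,
                              frac_low_coverage = 0.1, frac_missing = 0.1,
                              seed = 1L) {
  count_noise <- match.arg(count_noise)
  cfg <- as.list(environment())
  if (cfg$frac_negative + cfg$frac_positive > 1)
    stop("frac_negative + frac_positive must not exceed 1")
  if (cfg$depletion_factor <= 0 || cfg$depletion_factor > 1)
    stop("depletion_factor must be in (0, 1]")
  if (cfg$n_classes < 3L) stop("need at least 3 classes")
  if (cfg$n_normal > cfg$n_classes)
    stop("n_normal must not exceed n_classes")
  if (cfg$n_tss < 1L) stop("need at least one TSS cluster")
  stopifnot(abs(sum(cfg$background) - 1) < 1e-8, all(cfg$background > 0))
  cfg$null_mix <- cfg$null_mix / sum(cfg$null_mix)
  structure(cfg, class = "simulation_config")
}

class_ids <- function(n) sprintf("class_%02d", seq_len(n))

#' Simulate a CAGE-like raw count table
#'
#' Each TSS cluster gets log-normal class-mean expression levels; samples
#' within a class share the class mean, scaled by a per-sample library-size
#' factor, and counts are Poisson draws (or deterministic rounded means when
#' `count_noise = "none"`). Clusters are laid out on the synthetic chromosome
#' `chrS1` with alternating strands, spaced widely enough that neighbouring
#' promoters do not overlap.
#'
#' @param config A [simulation_config()].
#' @return A list with `counts` (clusters x samples integer matrix),
#'   `clusters` (`GRanges` with `cluster_id`), `sample_map` (data.frame
#'   `sample_id`, `class_id`, `normal_flag`), `class_means` (clusters x
#'   classes true means) and `lib_factors`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ncl <- config$n_classes
  classes <- class_ids(ncl)
  spc <- rep_len(config$samples_per_class, ncl)
  sample_map <- data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(spc))),
    class_id = rep(classes, times = spc),
    normal_flag = rep(seq_len(ncl) <= config$n_normal, times = spc),
    stringsAsFactors = FALSE)
  n <- config$n_tss
  cluster_id <- sprintf("tss_%04d", seq_len(n))
  clusters <- GRanges("chrS1",
                      IRanges(start = 2001L + (seq_len(n) - 1L) * 6000L,
                              width = 50L),
                      strand = rep(c("+", "-"), length.out = n))
  clusters$cluster_id <- cluster_id
  names(clusters) <- cluster_id
  mu <- matrix(exp(rnorm(n * ncl, config$mean_log_expr, config$sd_log_expr)),
               nrow = n, dimnames = list(cluster_id, classes))
  n_hk <- round(config$frac_housekeeping * n)
  if (n_hk > 0) {
    hk <- sample.int(n, n_hk)
    mu[hk, ] <- exp(rnorm(n_hk * ncl, config$hk_mean_log, config$hk_sd_log))
  }
  lib <- exp(rnorm(nrow(sample_map), 0, config$libsize_sd))
  names(lib) <- sample_map$sample_id
  lam <- mu[, sample_map$class_id, drop = FALSE] %*% diag(lib)
  counts <- if (config$count_noise == "poisson") {
    matrix(rpois(length(lam), lam), nrow = n)
  } else {
    round(lam)
  }
  dimnames(counts) <- list(cluster_id, sample_map$sample_id)
  list(counts = counts, clusters = clusters, sample_map = sample_map,
       class_means = mu, lib_factors = lib)
}

#' Simulate promoter sequences with planted motif occurrences and cytosines
#'
#' Promoter sequences are i.i.d. letters at the configured composition;
#' planted occurrences are independent draws from each motif's column
#' distributions, inserted without overlap on a random strand. Measured
#' cytosines are sampled from the actual CpG dinucleotides of the final
#' sequence, and each is assigned a planted label: the probability of the
#' negative label inside a planted occurrence is `depletion_factor` (or the
#' position-class-specific factor) times the outside probability.
#'
#' @param clusters `GRanges` of TSS clusters from [simulate_expression()].
#' @param config A [simulation_config()] with non-empty `motif_set` (an
#'   empty set yields promoters without occurrences).
#' @return A list with `promoters` (`GRanges`), `sequences` (forward-strand
#'   `DNAStringSet` named by cluster), `occurrences` (`GRanges` with `tf`),
#'   `cytosines` (`GRanges` width 1, with `cytosine_id`, `label`,
#'   `in_motif`), and `truth` (data.frame view of the cytosine labels).
#' @export
simulate_promoters <- function(clusters, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  promoters <- define_promoters(clusters)
  widths <- width(promoters)
  for (m in config$motif_set) {
    if (ncol(m$pcm) < 4L) stop("each motif must have length >= 4")
    if (any(ncol(m$pcm) > widths)) stop("motif longer than promoter")
  }
  bg <- config$background
  seqs <- vapply(widths, function(w)
    paste(sample(DNA_BASES, w, replace = TRUE, prob = bg), collapse = ""),
    character(1))
  occ <- list()
  # classify CpG column pairs once per motif for position-specific depletion
  cpg_tables <- lapply(config$motif_set, function(m) find_cpg_positions(m$pcm))
  for (i in seq_along(promoters)) {
    taken <- integer(0)
    for (mi in seq_along(config$motif_set)) {
      m <- config$motif_set[[mi]]
      L <- ncol(m$pcm)
      if (runif(1) > config$plant_prob) next
      for (try in 1:50) {
        s <- sample.int(widths[i] - L + 1L, 1L)
        if (!any((s:(s + L - 1L)) %in% taken)) break
        s <- NA_integer_
      }
      if (is.na(s)) next
      taken <- c(taken, s:(s + L - 1L))
      word <- vapply(seq_len(L), function(j)
        sample(DNA_BASES, 1L, prob = m$pcm[, j]), character(1))
      str <- sample(c("+", "-"), 1L)
      insert <- if (str == "+") paste(word, collapse = "") else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste(word, collapse = ""))))
      substr(seqs[i], s, s + L - 1L) <- insert
      occ[[length(occ) + 1L]] <- data.frame(
        prom = i, offset = s, L = L, tf = m$tf, strand = str,
        motif_index = mi, stringsAsFactors = FALSE)
    }
  }
  occ_df <- if (length(occ)) do.call(rbind, occ) else
    data.frame(prom = integer(), offset = integer(), L = integer(),
               tf = character(), strand = character(),
               motif_index = integer())
  occurrences <- GRanges(
    seqnames(promoters)[occ_df$prom],
    IRanges(start(promoters)[occ_df$prom] + occ_df$offset - 1L,
            width = occ_df$L),
    strand = occ_df$strand)
  occurrences$tf <- occ_df$tf
  occurrences$motif_index <- occ_df$motif_index
  names(seqs) <- clusters$cluster_id

  # sample measured cytosines from genuine CpG dinucleotides
  cyt <- list()
  for (i in seq_along(promoters)) {
    cg <- gregexpr("CG", seqs[i], fixed = TRUE)[[1]]
    if (cg[1] == -1L) next
    cg <- as.integer(cg)
    k <- min(length(cg), config$n_cpg_per_promoter)
    inocc <- occ_df$prom == i
    w <- rep(1, length(cg))
    if (any(inocc) && config$motif_cpg_weight != 1) {
      for (o in which(inocc)) {
        s <- occ_df$offset[o]
        inside <- cg >= s & cg + 1L <= s + occ_df$L[o] - 1L
        w[inside] <- config$motif_cpg_weight
      }
    }
    sel <- sort(sample(cg, k, prob = w))
    cyt[[length(cyt) + 1L]] <- data.frame(
      prom = i, offset = sel, stringsAsFactors = FALSE)
  }
  cyt_df <- do.call(rbind, cyt)
  gpos <- start(promoters)[cyt_df$prom] + cyt_df$offset - 1L
  cytosines <- GRanges(seqnames(promoters)[cyt_df$prom],
                       IRanges(gpos, width = 1L), strand = "+")
  cytosines$cytosine_id <- paste0("chrS1:", gpos)
  cytosines$cluster_id <- clusters$cluster_id[cyt_df$prom]

  # planted label with motif-occurrence depletion
  in_motif <- countOverlaps(cytosines, occurrences, type = "within",
                            ignore.strand = TRUE) > 0
  dep <- rep(1, length(cytosines))
  if (any(in_motif)) {
    ov <- findOverlaps(cytosines, occurrences, type = "within",
                       ignore.strand = TRUE)
    fac <- vapply(seq_along(queryHits(ov)), function(k) {
      hit <- occurrences[subjectHits(ov)[k]]
      base <- config$depletion_factor
      if (is.null(config$depletion_core) && is.null(config$depletion_flank))
        return(base)
      j <- cpg_column_of(start(cytosines)[queryHits(ov)[k]],
                         start(hit), end(hit), as.character(strand(hit)))
      tab <- cpg_tables[[hit$motif_index]]
      cls <- tab$class[match(j, tab$j)]
      if (!is.na(cls) && cls == "core")
        config$depletion_core %||% base
      else config$depletion_flank %||% base
    }, numeric(1))
    # a cytosine inside several occurrences takes the strongest depletion
    dep_tab <- tapply(fac, queryHits(ov), min)
    dep[as.integer(names(dep_tab))] <- dep_tab
  }
  p_neg <- config$frac_negative * dep
  p_pos <- config$frac_positive
  u <- runif(length(cytosines))
  label <- ifelse(u < p_neg, "negative",
           ifelse(u < p_neg + p_pos, "positive", "null"))
  cytosines$label <- label
  cytosines$in_motif <- in_motif
  truth <- data.frame(cytosine_id = cytosines$cytosine_id,
                      cluster_id = cytosines$cluster_id,
                      label = label, in_motif = in_motif,
                      depletion = dep, stringsAsFactors = FALSE)
  list(promoters = promoters,
       sequences = Biostrings::DNAStringSet(seqs),
       occurrences = occurrences, cytosines = cytosines, truth = truth)
}

# motif column index (the C of the pair) occupied by a genomic C position
# inside a hit; strand-aware so that the CG dyad maps onto the model's C,G
# column pair on either strand.
cpg_column_of <- function(cpos, hit_start, hit_end, hit_strand) {
  if (hit_strand == "-") hit_end - cpos else cpos - hit_start + 1L
}

#' Simulate class-level and per-sample methylation with planted correlations
#'
#' For a planted-negative cytosine the class-level methylation decreases
#' monotonically in the rank of the class's expression (amplitude 90
#' percentage points, so the amplitude > 50 filter passes by construction at
#' zero noise); planted-positive increases; null cytosines draw
#' i.i.d. expression-independent levels from a low/high/intermediate mixture.
#' Per-sample values jitter around the class value; coverage mixes a
#' well-covered and a low-coverage regime, and a fraction of records is
#' dropped so the downstream completeness filter has work to do.
#'
#' @param expr_class Class-level expression matrix (clusters x classes).
#' @param config A [simulation_config()].
#' @param assignments data.frame with columns `cytosine_id`, `cluster_id`,
#'   `label` (from [simulate_promoters()] truth, or generated i.i.d. when
#'   `NULL`).
#' @param sample_map Sample-class map; default regenerated from `config`.
#' @return A list with `meth` (long per-sample table: `chrom`, `pos`,
#'   `strand`, `sample`, `coverage`, `percent`), `class_values` (true
#'   class-level matrix) and `truth`.
#' @export
simulate_methylation <- function(expr_class, config, assignments = NULL,
                                 sample_map = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (ncol(expr_class) < 3L) stop("insufficient data: need >= 3 classes")
  set.seed(config$seed + 2L)
  classes <- colnames(expr_class)
  ncl <- length(classes)
  if (is.null(sample_map)) {
    spc <- rep_len(config$samples_per_class, ncl)
    sample_map <- data.frame(
      sample_id = sprintf("S%03d", seq_len(sum(spc))),
      class_id = rep(classes, times = spc),
      normal_flag = rep(seq_len(ncl) <= config$n_normal, times = spc),
      stringsAsFactors = FALSE)
  }
  if (is.null(assignments)) {
    n <- config$n_tss * config$n_cpg_per_promoter
    u <- runif(n)
    assignments <- data.frame(
      cytosine_id = paste0("chrS1:", seq_len(n) * 10L),
      cluster_id = sample(rownames(expr_class), n, replace = TRUE),
      label = ifelse(u < config$frac_negative, "negative",
              ifelse(u < config$frac_negative + config$frac_positive,
                     "positive", "null")),
      stringsAsFactors = FALSE)
  }
  n <- nrow(assignments)
  class_values <- matrix(NA_real_, n, ncl,
                         dimnames = list(assignments$cytosine_id, classes))
  for (k in seq_len(n)) {
    lab <- assignments$label[k]
    if (lab == "null") {
      comp <- sample(c("low", "high", "mid"), ncl, replace = TRUE,
                     prob = config$null_mix)
      v <- ifelse(comp == "low", runif(ncl, 0, 10),
           ifelse(comp == "high", runif(ncl, 90, 100), runif(ncl, 10, 90)))
    } else {
      y <- expr_class[assignments$cluster_id[k], ]
      r <- rank(y, ties.method = "average")
      g <- (r - 1) / (ncl - 1)
      base <- if (lab == "negative") 95 - 90 * g else 5 + 90 * g
      v <- base + rnorm(ncl, 0, config$noise_sd)
    }
    class_values[k, ] <- pmin(pmax(v, 0), 100)
  }
  # per-sample replicas with jitter, mixed coverage and missing records
  nsamp <- nrow(sample_map)
  ci <- match(sample_map$class_id, classes)
  pos <- as.integer(sub(".*:", "", assignments$cytosine_id))
  chrom <- sub(":.*", "", assignments$cytosine_id)
  vals <- class_values[, ci, drop = FALSE] +
    matrix(rnorm(n * nsamp, 0, config$replica_sd), n)
  vals <- pmin(pmax(vals, 0), 100)
  low <- matrix(runif(n * nsamp) < config$frac_low_coverage, n)
  lam <- ifelse(low, config$cov_mean_low, config$cov_mean_high)
  cov <- matrix(pmax(1L, rpois(n * nsamp, lam)), n)
  keep <- matrix(runif(n * nsamp) >= config$frac_missing, n)
  none <- which(rowSums(keep) == 0L)
  if (length(none)) keep[cbind(none, sample.int(nsamp, length(none),
                                                replace = TRUE))] <- TRUE
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  meth <- data.frame(chrom = chrom[idx[, 1]], pos = pos[idx[, 1]],
                     strand = "+",
                     sample = sample_map$sample_id[idx[, 2]],
                     coverage = cov[idx], percent = vals[idx],
                     stringsAsFactors = FALSE)
  list(meth = meth, class_values = class_values, truth = assignments,
       sample_map = sample_map)
}

#' Simulate a motif alignment from a position count matrix
#'
#' Draws `n_seqs` sequences column-wise from the PCM's empirical nucleotide
#' distributions; column-wise counts converge to the PCM frequencies as
#' `n_seqs` grows.
#'
#' @param pcm A [build_pcm()] matrix (or plain 4 x L matrix, rows A,C,G,T).
#' @param n_seqs Number of sequences to draw (>= 1).
#' @param seed Random seed.
#' @param tf_id TF identifier for the resulting alignment.
#' @return A `motif_alignment`.
#' @export
simulate_alignment <- function(pcm, n_seqs, seed = 1L,
                               tf_id = attr(pcm, "tf") %||% "TF") {
  if (n_seqs < 1L) stop("n_seqs must be >= 1")
  set.seed(seed)
  L <- ncol(pcm)
  cols <- lapply(seq_len(L), function(j)
    sample(DNA_BASES, n_seqs, replace = TRUE, prob = pcm[, j]))
  motif_alignment(do.call(paste0, cols), tf_id)
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates expression, promoter/sequence and methylation simulation so
#' that planted methylation-expression correlations refer to the class-level
#' RLE-normalized expression the pipeline will actually compute, and planted
#' negative labels are depleted inside motif occurrences.
#'
#' @param config A [simulation_config()].
#' @return A list bundling all generator outputs: `config`, `expression`
#'   (counts, clusters, sample_map), `expr_class` (normalized class-level
#'   matrix), `promoters`, `sequences`, `occurrences`, `cytosines`,
#'   `methylation` (long table), `class_values`, `truth`.
#' @export
simulate_dataset <- function(config) {
  expr <- simulate_expression(config)
  norm <- rle_normalize(expr$counts)
  expr_class <- average_by_class(norm$normalized, expr$sample_map)
  prom <- simulate_promoters(expr$clusters, config)
  meth <- simulate_methylation(expr_class, config,
                               assignments = prom$truth[, c("cytosine_id", "cluster_id", "label")],
                               sample_map = expr$sample_map)
  list(config = config, expression = expr, expr_class = expr_class,
       promoters = prom$promoters, sequences = prom$sequences,
       occurrences = prom$occurrences, cytosines = prom$cytosines,
       methylation = meth$meth, class_values = meth$class_values,
       truth = prom$truth)
}
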