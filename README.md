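# cpgtraffic

Promoter DNA methylation is classically associated with gene repression, but
whether methylation of *individual* CpG dinucleotides causes repression — for
example by blocking transcription factor (TF) binding — or merely records a
repressed state is unresolved. `cpgtraffic` implements, as a tested and
reusable R pipeline, an analysis that addresses this question from two sides:

1. **CpG "traffic lights".** For every measured cytosine in a promoter, the
   Spearman correlation *SCC<sub>M/E</sub>* between its methylation profile
   and the expression profile of the hosting TSS cluster across cell-type
   classes is computed and tested via the transformation
   *t = SCC<sub>M/E</sub> √(n−2) / √(1−SCC<sub>M/E</sub>²)* against a
   Student's t distribution with *n−2* degrees of freedom. A differentially
   methylated cytosine (profile amplitude > 50 percentage points) with at
   least one significantly negative correlation (two-sided *P* ≤ 0.01) is a
   CpG traffic light.
2. **Selection against traffic lights in TF binding sites.** Promoters are
   scanned with two motif models built from binding-site alignments: additive
   log-odds position weight matrices (PWMs) and remote dependency models
   (RDMs), which score all ordered position pairs
   (*RDM<sub>a,i,j</sub> = f<sub>a,i,j</sub> / Σ<sub>i&lt;j</sub> max<sub>a</sub> f<sub>a,i,j</sub>*).
   Both are calibrated to an exact random-word tail probability
   (*P* &lt; 0.0005, i.e. at most 5 of 10,000 random words reach the
   threshold). Per TF, the observed number of traffic lights inside predicted
   sites is compared with the expectation from the genome-wide traffic-light
   fraction (one-sample chi-square, Bonferroni corrected), stratified further
   by TF function class (activator / repressor / both, Welch t test) and by
   the information content of the CpG-containing motif columns: discrete
   information content *DIC<sub>j</sub> = (1/N)(Σ<sub>a</sub> log x<sub>a,j</sub>! − log N!)*
   separates *core* (both columns above the three-equal-nucleotide threshold
   *Th*) from *flanking* (medium/low) CpG positions.

Because the original data sources (RRBS methylomes, CAGE expression,
curated motif collections) cannot be redistributed, the package ships a
first-class synthetic-data module that generates every input with the
statistical structure the analysis assumes — planted negative/positive
methylation-expression correlations, planted motif occurrences, and a
controllable depletion of traffic lights inside binding sites — so that every
stage, and the pipeline end to end, is testable offline.

## Worked example

Simulate a small cohort (50 cell-type classes, 36 normal; 150 TSS clusters;
two planted motifs with a twofold traffic-light depletion inside their
occurrences) and run every stage:

```r
library(cpgtraffic)

consensus_pcm <- function(word, tf) {
  base <- function(b) { v <- rep(0, 4); v[match(b, c("A","C","G","T"))] <- 15; v }
  m <- do.call(cbind, lapply(strsplit(word, "")[[1]], base))
  rownames(m) <- c("A","C","G","T")
  structure(m, N = 15, tf = tf, class = c("pcm", "matrix"))
}

cfg <- run_config(sim = simulation_config(
  n_tss = 150, n_cpg_per_promoter = 10,
  motif_set = list(
    list(pcm = consensus_pcm("ACCGGTAT", "TF1"), tf = "TF1", label = "repressor"),
    list(pcm = consensus_pcm("TACCGGTA", "TF2"), tf = "TF2", label = "activator")),
  plant_prob = 0.8, motif_cpg_weight = 4, depletion_factor = 0.5, seed = 11))

res <- run_pipeline(cfg, "demo_run")
res$correlation$summary
#>      sign alpha count    fraction
#>  negative 0.050   280 0.186666667
#>  negative 0.010   256 0.170666667
#>  negative 0.001   249 0.166000000
#>  positive 0.050    43 0.028666667
#>  positive 0.010    17 0.011333333
#>  positive 0.001    11 0.007333333
```

Of the 1,500 analyzed cytosines, 17.1% have a significantly negative
correlation at *P* ≤ 0.01, recovering the planted 16.6% rate; the positive
fraction is an order of magnitude smaller, as planted. The per-TF depletion
table recovers the planted twofold depletion:

```r
res$enrichment$enrichment[, c("tf","kind","observed","n_in_tfbs","expected",
                              "ratio","p","p_bonferroni","direction")]
#>   tf kind observed n_in_tfbs expected ratio      p p_bonferroni direction
#>  TF1  pwm        7        78     13.3 0.526 0.0575        0.230      none
#>  TF2  pwm        7        71     12.1 0.578 0.1065        0.426      none
#>  TF1  rdm        7        78     13.3 0.526 0.0575        0.230      none
#>  TF2  rdm        7        71     12.1 0.578 0.1065        0.426      none
```

Observed/expected ratios of 0.53–0.58 against the planted factor 0.5; at
this desk scale the per-TF counts are small, so individual chi-square tests
are not Bonferroni-significant — the acceptance suite demonstrates recovery
at larger *n*. `res$annotation` holds the feature-track co-localization
fractions and `res$manifest` the MD5 digests of every written stage output.

All thresholds (promoter window 1500/500 bp, ≥ 10 reads, ≥ 50% of classes,
amplitude > 50, α levels, model *P*-value, minimum 15 aligned sites) are
named arguments of `run_config()` / `simulation_config()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline on the reference synthetic configuration (5 TFs, 200
promoters, 50 classes) against the installed package and writes the JSON
report to `--out`; `--seed` controls every source of randomness in the run.
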