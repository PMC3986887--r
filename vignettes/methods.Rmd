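---
title: "Methods: single-CpG methylation-expression correlation and selection against methylation-sensitive CpGs in TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpgtraffic)
```

# The analysis

`cpgtraffic` links two measurements made across a panel of cell-type
classes — per-cytosine percent methylation (RRBS-like, CCGG context) and
per-TSS-cluster expression (CAGE-like tag counts) — and asks whether
individual CpGs whose methylation anticorrelates with the expression of
their promoter ("traffic lights") are avoided by transcription factor
binding sites.

## Profiles

Raw per-sample tables are first collapsed to the class level: replicas,
donors and related cell types mapped to the same class are arithmetically
averaged (`average_by_class()`), with methylation read coverages summed per
class. Expression counts are normalized by relative log expression
(`rle_normalize()`): a sample's size factor is the median, over clusters
with positive counts in every sample, of its count over the cluster's
geometric mean. Clusters whose normalized expression never reaches 1 in any
class are removed — they are non-robust to sequencing noise. Promoters span
1500 bp upstream to 500 bp downstream of the cluster ends, strand-aware,
and overlapping promoters are kept independent.

On the methylation side, a class value supported by fewer than 10 summed
reads is treated as missing, and a cytosine must have data in at least half
the classes (25 of 50; 18 of 36 when the analysis is restricted to normal
classes). Because low but nonzero methylation can reflect experimental
error, only differentially methylated cytosines — profile amplitude
(max − min) strictly greater than 50 percentage points — can become traffic
lights.

Coverage filtering operates per class *after* summing sample coverages;
whether the original 10-read rule was per sample or per class is not
determinable from the source description, so the class-level reading (which
matches the class-level profile definition) was adopted and the threshold
is exposed as an argument.

## Correlation and traffic-light calling

For every (cytosine, containing promoter) pair, `spearman_cc()` computes
the Spearman correlation over pairwise-complete classes with average-rank
tie handling; pairs with fewer than 5 complete classes, or with zero rank
variance, are excluded. Significance comes from the transformation
$t = \mathrm{SCC}\sqrt{n-2}/\sqrt{1-\mathrm{SCC}^2}$ with $n-2$ degrees of
freedom, two-sided, with the effect sign read from the correlation itself.
The minimum of 5 paired classes and the tie-handling variant are package
decisions (the method description leaves both open); $n \ge 5$ keeps the
rank statistic non-degenerate and is configurable.

A cytosine inside overlapping promoters has several correlations; it is
considered to affect transcription if *at least one* is significant. A
differentially methylated cytosine with at least one significantly negative
correlation at $\alpha = 0.01$ is a traffic light; positive calls are made
the same way among the remainder. The rare cytosine significant in both
directions through different promoters is labelled negative — the
phenomenon under study — and tallied in a `both_signs` column so the
ambiguity is never silent. No multiple-testing correction is applied at
this stage; correction enters only in the enrichment stage, mirroring the
two-stage design of the original analysis. The per-sign summary table
(counts and fractions at $\alpha \in \{0.05, 0.01, 0.001\}$) counts
significant correlations among all analyzed cytosines without the
amplitude filter, which is how the published summary of this analysis is
constructed; the amplitude filter gates only the traffic-light *calls*
used downstream.

## Motif models

`build_pwm()` uses the standard log-odds form with a background-proportional
pseudocount, $w_{a,j} = \log\frac{x_{a,j} + pq_a}{(N+p)q_a}$, defaulting to
$p = \log N$ so regularisation is stable across alignment depths (the
source collection provides ready-made matrices without printing its
formula; this convention is documented rather than inherited). Weights are
snapped to a $10^{-4}$ score grid: the exact score distribution of a random
background word is then a convolution of per-column integer distributions
(`pwm_score_distribution()`), and `calibrate_threshold()` picks the
smallest attainable score whose tail probability is at most the target
($5 \times 10^{-4}$; the "5 in 10,000 random words" reading). With the
default uniform background all probabilities are dyadic rationals, so the
dynamic program agrees with full $4^L$ enumeration exactly, which the test
suite asserts. Note a target of $5\times10^{-4}$ is attainable only for
$L \ge 6$ under a uniform background (the smallest nonzero tail is
$4^{-L}$); shorter models raise a degenerate-model error, as does any model
whose words all tie.

The remote dependency model drops the positional-independence assumption:
for every ordered column pair $i < j$ the frequency $f_{a,i,j}$ of each of
the 16 ordered dinucleotides is normalised jointly,
$r_{a,i,j} = f_{a,i,j} / \sum_{i<j}\max_a f_{a,i,j}$, so the per-pair
maxima sum to exactly 1. Binding-site alignments are first filtered by the
calibrated PWM threshold, and filtered alignments with fewer than 15
sequences are discarded (RDMs have many more parameters than PWMs). Two
points the source leaves open are decided here: the word score is the
natural additive analogue of PWM scoring, $\sum_{i<j} r_{w_i w_j, i, j}$
(so a degenerate alignment's consensus scores exactly 1), and the
$f_{a,i,j}$ are frequencies (the normalisation cancels the
counts-versus-frequencies distinction). RDM thresholds are calibrated by
full enumeration of all $4^L$ words for $L \le 10$ and otherwise by Monte
Carlo with at least $2\times10^6$ words and a binomial confidence interval
attached to the achieved tail.

Column information is measured by discrete information content,
$\mathrm{DIC}_j = \frac{1}{N}\left(\sum_a \log x_{a,j}! - \log N!\right)$
(natural logarithm, log-gamma for fractional counts), read with the outer
$1/N$ applying to the whole bracket — the only parenthesisation under which
larger DIC means more information, as the core/flanking definitions
require. DIC is 0 for a single-nucleotide column and decreases toward
uniformity. The reference thresholds are the DIC of a three-equal-nucleotide
column ($Th$) and of an $(f, f, 2f, 2f)$ column ($th$); $Th > th$ for all
$N \ge 3$. A column pair $(j, j+1)$ is a CpG position when C is a major
nucleotide at $j$ and G at $j+1$ — ties count as major, a permissive choice
reported in the output. Both DICs above $Th$ makes the pair *core*; both in
$[th, Th]$ *medium*; both below $th$ *low*; discordant pairs are reported
as *mixed* and excluded from the core-versus-flanking contrast rather than
silently merged.

## Scanning and enrichment

`scan_promoters()` slides a calibrated model over every window of both
strands (reverse-strand windows scored on the reverse complement, reported
in forward coordinates); windows containing non-ACGT characters are skipped
— deterministic and conservative. Hits may optionally be restricted to
ChIP-seq peaks; full containment is required (a binding site must lie
within the bound region), with any-overlap available behind an argument.

A CpG counts at most once per TF per model kind no matter how many
overlapping hits contain it, and only cytosines with at least one
correlation enter the analyzed count. The depletion test is a one-sample
chi-square of the observed traffic-light count against
$e = g \cdot n_{\mathrm{inTFBS}}$, where $g$ is the genome-wide
traffic-light fraction among analyzed cytosines:
$\chi^2 = (o-e)^2/e + (o-e)^2/(n-e)$, 1 df, no continuity correction,
Bonferroni-corrected over the TFs entering the test (those with at least
one observed CpG of the tested sign — the inclusion rule is configurable).
The one-sample form follows the stated construction of the expectation
("based on the overall fraction"); a 2×2 inside/outside variant would
asymptotically agree when in-TFBS CpGs are a small minority of all CpGs.
Because the chi-square approximation degrades at small expected counts, an
exact two-sided binomial P-value is always reported alongside. Function
classes are compared by Welch's unequal-variance t test (class variances
differ visibly in this kind of data; the source states only "t-test"), with
degenerate zero-variance configurations handled explicitly. Positional
enrichment routes every in-hit CpG to the motif column pair it occupies
(strand-aware) and repeats the test per core/medium/low stratum, plus a
combined flanking stratum and a cross-TF paired t contrast of core versus
flanking ratios.

## The synthetic world

The generator states the cohort the analysis assumes: 50 cell-type classes,
36 normal, 3 samples per class (emulating the replica structure that class
averaging removes), a 16.6% planted rate of negatively correlated cytosines
and 0.8% positive — the genome-wide rates reported for this analysis — and
a default twofold depletion of planted negatives inside motif occurrences
(the observed-to-expected ratios in the source concentrate around 0.45–0.7,
with repressors near 0.5).

Expression: per-cluster class means are log-normal (meanlog 2, sdlog 1)
with per-sample log-normal library-size factors (sd 0.4) so RLE has real
work to do, and Poisson counts. One cluster in ten is simulated as a
housekeeping-like TSS (meanlog 6, class sd 0.25): stably expressed
reference features are a structural property of real CAGE libraries and
are what the median-of-ratios estimator conditions on; without them RLE is
undefined.

Methylation: for a planted-negative cytosine the class-level value falls
linearly from 95 to 5 with the rank of the class's expression (amplitude 90,
so the >50 filter passes by construction at zero noise), plus truncated
Gaussian noise on the percent scale, clipped to [0, 100] — the simplest
model reproducing the observed mostly-0-or-100-with-intermediates shape.
Null cytosines draw i.i.d. expression-independent levels from a
low/high/intermediate mixture whose weights are exposed as parameters (the
empirical distribution beyond its bimodality is not described anywhere
authoritative). Per-sample records jitter around the class value; coverage
mixes a Poisson(30) and a Poisson(5) regime (10% low) and 10% of records
are dropped outright, so the coverage and completeness filters are
exercised. Missing values are absent records, not sentinels, forcing the
pairwise-complete logic.

Sequences are i.i.d. uniform nucleotides; occurrences are drawn from the
motif's column distributions and inserted without overlap on a random
strand; measured cytosines are sampled from genuine CG dinucleotides of
the final sequence (`motif_cpg_weight` can bias sampling toward binding
sites without affecting per-position label probabilities). The probability
that an in-occurrence CpG is planted negative equals `depletion_factor`
(or a core/flanking-specific factor) times the outside probability.

What a green test does *not* establish: the generator has no chromatin-
domain autocorrelation of methylation, no read-level bisulfite errors, no
sequence evolution and no dependence structure between neighbouring CpGs,
so passing recovery tests demonstrate correctness of the estimators on the
stated world, not robustness to those real-data features.

Class-level simulation happens first and per-sample replicas are jittered
from it, so class averaging is testable against known class means; all
coordinates are emitted on the synthetic chromosome `chrS1`.

## Numerical and representational choices

* Intervals are held in `GRanges` (1-based, closed) — the native
  Bioconductor convention — with 0-based half-open BED conversion confined
  to the readers and writers. This replaces a fully 0-based internal
  convention considered early on: with `findOverlaps()` doing every
  containment query, a single conversion boundary at I/O is the smaller
  off-by-one surface.
* RLE is implemented directly (median of linear-space ratios). The DESeq2
  estimator is used as an independent oracle in the test suite; it takes
  the median of *log* ratios, which averages the two middle values in log
  space when the reference set has even size, so agreement is asserted at
  5e-3 rather than bitwise.
* PWM score discretisation is 1e-4, matching the precision/speed trade-off
  of published exact-P-value scanners; thresholds are reported on the real
  score scale.
* Minus-strand CpG measurements are collapsed onto the forward-strand C of
  the dyad by coverage-weighted averaging: the CCGG context is
  strand-symmetric and the strands are not analysed separately.
* Perfect correlations (|SCC| = 1) have infinite t; the P-value is reported
  as the limit 0 rather than an error.

## Known limitations

Per-pair Spearman correlations are computed in an R-level loop; at the
scales used here (tens of thousands of pairs) this is a few seconds, but a
genome-scale run would want a compiled path. RDM Monte Carlo calibration
for long motifs carries sampling error (reported as a confidence interval)
rather than the exact tail the enumerated path provides. The enrichment
stage treats CpGs as exchangeable under permutation; clustering of CpGs
within CGIs violates this mildly in real data.
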