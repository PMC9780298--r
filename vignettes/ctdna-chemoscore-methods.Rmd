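---
title: "Methods: instability metrics and response scores from ctDNA panel sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instability metrics and response scores from ctDNA panel sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaChemoScore)
```

## The problem

Locally advanced rectal cancer is commonly treated with neoadjuvant
chemotherapy (nCT) before surgery, but only part of the patients respond
(graded CR/PR, collapsed here into a "better" group, versus SD/PD, the
"poor" group). Liquid biopsy — targeted panel sequencing of circulating
tumor DNA (ctDNA) from plasma — offers a non-invasive window on the tumor
genome before treatment. This package implements, end to end and on
synthetic data with known ground truth, the analytical machinery such a
study needs: somatic variant filtering, three per-sample genomic
instability statistics (CNI, MATH, TMB), PCA-based discrimination of the
response groups with ROC/AUC, a two-component PCA expression signature
(nCTPS) with survival stratification, and a multi-omics gene-screening
funnel.

Everything operates on plain tabular inputs (variant tables, per-bin read
counts, gene-level CNV states, expression matrices, clinical tables), so
the same functions apply to real cohorts where such tables are available.

## Somatic filtering

Somatic calls are eliminated in a fixed three-step order, each removal
attributed to the first rule violated so per-rule counts are well defined:

1. **R1 (annotation)** — synonymous SNVs, or calls in intergenic/intronic
   regions;
2. **R2 (population frequency)** — population allele frequency
   $\geq 0.002$ (the maximum over the ExAC and gnomAD fields; a missing
   value counts as 0, i.e. presumed rare);
3. **R3 (quality)** — strand bias, support reads $< 5$, or VAF below the
   sample-type floor: $0.05$ in tumor tissue, $0.01$ in plasma. The floors
   are strict, so equality survives.

All thresholds are arguments of `filter_somatic()` with these defaults.
The strand-bias flag is consumed as a precomputed boolean: its definition
belongs to the upstream caller.

## Instability metrics

**CNI (copy-number instability).** Per-bin read counts are corrected for
GC content and target length (`gc_correct_and_normalize()`): counts are
divided by `length / median length` and by a rolling-median trend of count
versus GC fraction (window: 30 % of bins ordered by GC, rescaled to mean
1). A rolling median was chosen over a spline because it is deterministic,
robust to CNV-carrying bins, and trivially invertible by construction.
Corrected counts are median-centered per sample — so CNI measures
*regional* instability, not global depth — and turned into
$\log_2(\text{sample}/\text{baseline})$ ratios against the mean centered
baseline profile. Each bin's ratio is standardized by the baseline
cohort's per-bin mean and SD ("Gaussian transformation versus a baseline
group"); bins with zero baseline SD are masked with a warning. The
unstable-region threshold is computed from the pooled baseline Z values as
$T = P_{95} + 2\,\mathrm{SD}$; since the pooled Z values are already
centered, the "absolute standard deviation" is read as their SD. The
threshold is one-sided (gains) by default with a two-sided $|z|$ option,
and both the percentile and the SD multiplier are exposed. CNI is the sum
of the Z-scores of bins exceeding $T$ — zero when no bin does, hence
always non-negative. Whether the threshold should come from the baseline
pool or from the test sample's own Z vector is genuinely ambiguous; the
baseline-pool reading is the default and `threshold_scope = "per_sample"`
selects the alternative.

**MATH (mutant-allele tumor heterogeneity).** VAFs are restricted to the
inclusion window $[2\%, 100\%]$ (both bounds inclusive) and
$\mathrm{MATH} = \mathrm{MAD}/\mathrm{median}$, with MAD the plain median
absolute deviation — the literal form of the defining ratio. The MATH
literature's convention (the 1.4826 Gaussian-consistency constant and a
$\times 100$ percentage scale) is available as
`convention = "mroz"`. An empty inclusion window yields `NA` (undefined),
never 0.

**TMB (tumor mutational burden).**
$\mathrm{TMB} = \text{mutations} \times 10^6 / \text{panel exonic bases}$,
with the numerator the *post-filter* retained count — the coupling to the
filter is explicit in `compute_instability_metrics()`.

Group comparisons of all three metrics use the two-sided Mann–Whitney U
test (exact when small and tie-free, normal approximation with tie
correction otherwise).

## Response discrimination

`build_alteration_matrix()` encodes either SNV presence (0/1 per
gene × sample) or signed gene-level CNV values, orders genes by descending
alteration frequency (the heatmap ordering of panel studies), and drops
constant rows — they carry no PCA signal. PCA (`fit_pca()`) is
column-centered SVD with a deterministic sign convention (the
largest-magnitude loading of each component is positive), so results are
reproducible across platforms without seeds. "Principal-component genes"
are those whose absolute loading on components 1–2 reaches a configurable
quantile (default top 25 %); the originating analysis never states its
cutoff, so it is a parameter, not a constant. Discrimination is
quantified by the pairwise-probability (Mann–Whitney) form of the ROC AUC
with "better" fixed as the positive class, and by deterministic 2-means
clustering (farthest-pair initialization, Lloyd refinement) cross-tabulated
against the response groups. PC1 is the default ROC score; which PCA
quantity fed the original ROC is not stated, so this is a documented
choice.

## nCTPS signature and survival

`compute_nctps()` runs PCA on the centered expression submatrix of the
therapeutic-relevant gene list and scores each sample as
$\mathrm{nCTPS}(s) = \mathrm{PC1}(s) + \mathrm{PC2}(s)$ — the only reading
of a "sum of the two component scores" that yields one number per patient.
Genes are centered but not scaled by default (`scale. = TRUE` is
available), since the defining analysis does not state a scaling step.

The survival cutoff (`maxstat_cutoff()`) follows the maximally selected
rank statistics approach: candidate cutoffs are midpoints between
consecutive sorted unique scores within the 10–90 % quantile window, and
each split is scored by the *standardized linear log-rank statistic* built
from Nelson–Aalen residual scores with permutation (hypergeometric)
variance. This is the statistic of the dedicated cutpoint-selection
literature and differs from maximizing the summed-over-event-times
log-rank chi-square: the two can select different cutoffs on small data,
and the standardized form is the one whose selection behaviour the package
reproduces. The p-value at the selected cutoff is reported as
*uncorrected* — maximal selection inflates significance — and a
permutation-adjusted p-value (`n_perm`) is available; `selected_under_null`
flags selections whose maximal statistic is within the two-sided normal
95 % bound.

Kaplan–Meier curves and log-rank tests are delegated to the `survival`
package (`survfit`/`survdiff`) behind `km_estimate()`/`logrank_test()`;
events precede censorings at tied times. `stratified_prognosis()` crosses
the nCTPS factor with a TMB high/low factor (dichotomized by its own
maximally selected cutoff when numeric, since no TMB threshold is given by
the source analyses) and runs the k-group log-rank over the non-empty
cross-classes.

## Multi-omics screen

`cnv_chisquare_screen()` compares CNV states between tumor and normal
samples per gene with Pearson's chi-square (no continuity correction) on a
2 × 2 condition × {altered, neutral} collapse by default (`"full"` keeps
all five states); genes with a zero marginal are *untestable*, not
significant, and Benjamini–Hochberg adjustment runs across the testable
genes. `dosage_association()` groups samples into deletion (deep deletion
merged in — the four-group scheme has no separate deep-deletion class),
normal, gain and amplification; two usable groups are compared by the
Wilcoxon rank-sum test, more by Kruskal–Wallis; completely tied expression
returns statistic 0 and p 1 (the rank statistics are 0/0 there, but the
null is trivially retained). `intersect_screens()` reports all seven Venn
regions of the three gene sets, and `drug_sensitivity_correlation()`
computes Pearson (or Spearman) expression–response correlations across
shared cell lines with BH adjustment; the orientation of the response
score is recorded explicitly rather than guessed.

## The synthetic cohort generator

The generator exists so that every stage is testable with known ground
truth; its defaults define the study conditions used throughout the tests.

* **Panel**: non-overlapping 200-bp bins on one contig, GC drawn uniformly
  from $[0.3, 0.7]$ — the working range of hybrid-capture designs.
* **Counts**: expected count = depth × length factor × GC bias ×
  copy-ratio multiplier; the GC bias is the smooth unimodal curve
  $\exp(-s\,(gc-0.5)^2)$ peaking at GC 0.5, mimicking library-prep bias;
  counts are negative binomial with mild dispersion 0.02 (variance
  $\mu + 0.02\mu^2$; dispersion 0 selects Poisson). Baseline samples never
  carry events.
* **Variants**: per-sample true counts are `rate × panel bases / 1e6`;
  VAFs follow Beta(2, 8) truncated at the sample-type filter floor so
  uncontaminated cohorts pass the filter exactly, making TMB recovery an
  identity. Contaminants each violate exactly one filter rule, so per-rule
  behaviour is attributable.
* **Expression/survival**: linear dosage model
  $\mathrm{expr} = \mathrm{baseline}_g + \beta\,\mathrm{state} +
  \mathcal N(0, \sigma)$; exponential survival with a group hazard ratio;
  independent censoring with the stated probability (censored subjects are
  observed at a uniform fraction of their latent time). Exponential
  survival keeps the log-rank and KM contracts checkable in closed form.

What the generator does **not** emulate: read-level artifacts (FASTQ/BAM),
subclonal phylogenies beyond the VAF law, segmentation noise,
gene-correlated expression structure, and non-proportional hazards.
Passing tests therefore demonstrate the correctness of the computations
and their statistical calibration, not clinical performance on real
cohorts.

## Problem sizes and numerical choices

The bundled demo pipeline (`run_pipeline(pipeline_config(seed = 42))`)
uses a deliberately compact cohort chosen to mirror the 16-patient
setting: 16 test samples (8 better / 8 poor), 12 baseline samples, a
24-kb / 120-bin panel, with mutation rates scaled up (350 and 650 per Mb
for better and poor) so per-sample call counts (~8 and ~16) stay in a
realistic range on the scaled-down panel; responders carry recurrent
multi-bin copy gains and non-responders a higher mutational burden,
reproducing the direction of the cohort findings (higher CNI in
responders, higher TMB in non-responders, MATH uninformative). Power and
calibration properties in the tests use 100 replicates (200 for the
stratified null) at $n = 8+8$ or $n = 150$, and tolerance $10^{-9}$
against brute-force oracles for deterministic quantities.

Degenerate inputs are defined, not silent: all-zero count vectors,
baselines with zero variance, empty VAF inclusion windows, single-class
label vectors, identical clustering points, and constant score vectors
all either raise informative errors or return flagged `NA`s, as documented
on each function.

## Known limitations

* CNI operates on the bins as given; multi-bin segmentation belongs to an
  upstream caller.
* The maximally selected cutoff's uncorrected p-value is optimistic by
  construction; use `n_perm` when an honest selection-adjusted p is
  needed.
* The chi-square screen's binary collapse discards gain/loss direction;
  use `collapse = "full"` when direction matters and counts allow.
* Interfaces are function-level: the pipeline is driven from R
  (`run_pipeline()` plus a YAML-round-tripping `pipeline_config()`), not
  from a shell.
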