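---
title: "Methods: copy-number-driven miRNA deregulation analysis with mirdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-driven miRNA deregulation analysis with mirdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The scientific problem

MicroRNAs are frequently located in genomic regions affected by somatic
copy-number variation (CNV), and a change in the DNA dosage of a miRNA
locus can propagate into a change in its expression — and from there into
derepression or repression of the miRNA's target genes. `mirdose`
implements an integrative analysis that follows this causal chain in
myeloid leukemia data:

1. **CNV calling** on SNP-array copy-number profiles of a cell-line
   panel (`classify_cn()`, `segment_profile()`, `assign_locus_cn()`,
   `recurrent_regions()`);
2. **association testing** of each miRNA's qPCR expression against the
   copy-number state of its locus (`cnv_expression_screen()`);
3. **target nomination** by intersecting predicted miRNA targets with
   anti-correlated differential mRNA expression
   (`moderated_diff_expr()`, `coherent_targets()`);
4. **patient-cohort quantification** of the downstream event — here,
   downregulation of the tumor suppressor NF1 — and attribution of its
   mechanism per patient (locus deletion, miR-370 overexpression, both,
   or unknown) (`cohort_analysis()`, `attribute_mechanism()`);
5. a **synthetic data generator** (`gen_cell_line_data()`,
   `gen_cohort_data()`) that emulates the full study design so every
   stage is testable end to end without access to raw arrays or patient
   material.

## Copy-number model

Copy number is carried on the linear scale with diploid = 2. The state
classification uses fixed thresholds: amplification for CN strictly
above 3; deletion for CN strictly below 1.5, subdivided into homozygous
(CN < 0.5) and hemizygous (0.8 ≤ CN < 1.5). The band 0.5 ≤ CN < 0.8
falls between the named deletion classes; we expose it as
`deletion_unclassified`, which still satisfies the operative deletion
predicate `is_deleted()` (CN < 1.5), so no deleted value is ever dropped
from a deletion analysis for lack of a name. Boundaries are strict on 3
and 1.5 ("over 3", "below 1.5") and inclusive at 0.8.

**Coordinates.** All in-memory intervals are 1-based and closed, the
R/Bioconductor convention (IRanges, GenomicRanges); BED input is shifted
at the read boundary (`read_mirna_loci(..., bed = TRUE)`). Keeping the
internal representation in the ecosystem's native convention avoids a
second conversion layer between this package and the interval machinery
it calls. Strand is ignored throughout: copy number is strand-agnostic.

**Segmentation.** Vendor segmentation algorithms for SNP arrays are
proprietary and unpublished, so the package ships a transparent
stand-in: recursive binary splitting in which each candidate breakpoint
is scored by the pooled two-sample t-statistic between the two flanks,
the maximal |t| position is chosen (leftmost on ties), and the split is
accepted when its p-value is below `alpha` (default 0.01) with both
flanks retaining `min_markers` markers (default 5). Because the test
statistic is the *maximum* over all scanned breakpoints, the pointwise
p-value is anti-conservative; it is Bonferroni-adjusted by the number of
candidates scanned, which keeps the per-segment false-split rate at
approximately `alpha`. Zero-variance segments with equal flank means are
never split; unequal means with zero variance split with p = 0. Segment
means are arithmetic means of member markers, so the segmentation
conserves the per-marker grand mean exactly — a property the test suite
asserts to 1e-9.

**Locus calls.** A miRNA locus inside a single segment takes that
segment's mean CN; a locus straddling a segment boundary takes the
coverage-weighted mean over the overlapped bases (equivalent to per-base
averaging, which is how the test oracle computes it). Loci over
uncovered gaps or absent chromosomes are reported `neutral` with a
`no_data` flag rather than being invented or dropped. Recurrently
altered regions are maximal intervals where at least `min_samples`
(default 4) samples are altered in the same direction, computed with
IRanges coverage; the reported `n_samples` is the peak per-base count
within the interval.

## Relative quantification (2^−ΔΔCt)

Expression and genomic copy number from qPCR both use the 2^−ΔΔCt
model with amplification efficiency fixed at exactly 2 (no efficiency
correction): ΔΔCt = (Ct_target − Ct_reference)_sample −
(Ct_target − Ct_reference)_calibrator, fold = 2^−ΔΔCt. Replicate wells
are averaged arithmetically on the Ct scale before differencing, with
the replicate SD kept as a QC flag (default threshold 0.5 cycles;
flagged, never rejected). When several normal controls act as the
calibrator their ΔCt values are averaged before differencing.

Deregulation is called against per-assay cutoffs fit on normal
controls: mean ± 3·SD of the normal expression values, with the
(n−1)-denominator SD and the lower cutoff clipped at 0. Calls are
strict: a value exactly on a cutoff is `normal`. Under the fitted
normal model the two-sided 3-SD rule flags ≈ 0.27% of held-out normal
draws; the suite asserts ≤ 1%.

For genomic qPCR the same arithmetic yields a copy-number ratio
(diploid ≈ 1, hemizygous ≈ 0.5). No community-standard ratio threshold
exists for calling a deletion from such assays; the package defaults to
0.75 — the midpoint between the diploid and one-copy expectations — and
exposes it as `deletion_threshold` everywhere it is used. **Review this
value for your assay.**

## The association screen

For each miRNA, samples are grouped by locus state: amplified vs
neutral for the amplification analysis, deleted vs neutral for the
deletion analysis; samples carrying the opposite alteration are
excluded from that analysis, and `no_data` samples from both. Expression
enters the test as log2(fold change): raw fold changes are
multiplicative and right-skewed, so t-tests on the linear scale would be
dominated by skew. Welch's test is the default for robustness; the
pooled-variance test is available (`test = "pooled"`) for the classic
two-sample t. Groups need at least 2 samples each; smaller analyses are
reported as untested with a reason, never dropped.

Significance follows the dosage-effect rule: raw p < 0.05 *and*
direction consistency (amplified → higher mean, deleted → lower mean).
Benjamini–Hochberg adjusted p-values are always reported alongside but
do not drive the flag — the screen is a hypothesis-generating step whose
hits proceed to orthogonal validation, which is why the raw-p rule is
retained as primary.

## Differential expression and coherent targets

The mRNA contrast uses a moderated two-group t with empirical-Bayes
variance shrinkage authored in this package: posterior variance
(d₀·s₀² + d·s²)/(d₀ + d) with s₀² the mean gene-wise variance and d₀
estimated by method of moments from the spread of log sample variances
(var(log s²) ≈ trigamma(d/2) + trigamma(d₀/2), inverted by Newton
iteration; homogeneous variances give d₀ = ∞, i.e. fully shared
variance). With `prior_df = 0` the procedure reduces exactly to the
ordinary pooled t-test — asserted to 1e-9 — and the suite cross-checks
the moderated statistics against limma's on simulated matrices
(rank correlation > 0.99).

The B statistic is the log odds of differential expression under a
two-component mixture: a proportion `prior_prop` (default 0.01) of genes
are differentially expressed with prior effect SD `effect_sd` (default
1 log2 unit), under which the moderated t is inflated by
k = sqrt(1 + effect_sd²/(s²_post·(1/n₁+1/n₂))). B is a monotone
transform of |t| for fixed posterior variance. Because B's calibration
depends on these hyperparameters, the p < 0.001 selection route is
always available (`rule = "p"`); the default `rule = "either"` selects
by B > 0 or p < 0.001. Probesets are collapsed to genes by maximum |t|
(`collapse_probesets()`).

A candidate target is a (miRNA, gene) pair that is (i) predicted in at
least `min_sources` databases, (ii) selected as differentially
expressed, and (iii) opposite in direction to the miRNA (coherence).
Candidates are ranked by supporting-database count, then |t|.
Predictions are consumed as plain TSV; no live database access.

## Cohort analysis

Patient-level analysis is pairwise-complete: each prevalence uses the
patients with that assay measured, mirroring the varying denominators
of real cohorts (e.g. expression in 68, miRNA in 50, genomic qPCR
in 55). Prevalences come with Wilson 95% intervals. The association
between miR-370 overexpression and NF1 downregulation is tested by
Fisher's exact test (small cells make asymptotic tests unreliable), with
a Haldane-corrected sample odds ratio when a zero cell occurs.

Mechanism attribution partitions the expression-down patients into
`both`, `deletion_only`, `mir370_only` and `unknown`; patients missing
either measurement form an explicit `unevaluable` bucket so the
categories always sum to the down-called count. Applied to the worked
cohort totals (21 down-called; 5 deleted, 6 miR-370-up, 1 with both)
this yields 4 / 5 / 1 / 11 by inclusion–exclusion.

## The synthetic data generator

`gen_cell_line_data()` emulates the cell-line study design: 16 lines,
a 250-miRNA panel, and five planted copy-number events over four
synthetic 1.5-Mb chromosomes — two small amplified clusters (CN 3.365
in 8 lines; CN 3.099 in 5 lines), a 12-miRNA amplified cluster
(CN 3.671 in 4 lines), and two deleted loci (CN 0.96 in 5 lines;
CN 1.071 in 2 lines) — 19 dosage miRNAs in all (16 up, 3 down), with
the event CN levels and line counts taken from the published cell-line
panel. Expression follows fold = (CN/2)^γ with γ = 1 by default (γ = 0
gives a null panel) and log-normal noise of 0.25 log2 units; marker
noise is Gaussian with SD 0.15, typical array probe-level scatter.
Ct tables are back-computed so that 2^−ΔΔCt against the normal-control
calibrator returns the planted folds exactly when noise is zero
(asserted to 1e-9). Every planted event is recorded in a truth ledger
keyed by miRNA id.

`gen_cohort_data()` plants, independently per patient, NF1 locus
deletion (probability 0.24, genomic ratio ≈ 0.5) and miR-370
overexpression (probability 0.12, 8-fold). MiR-370-up patients have NF1
repressed by `repression_strength` (default 0.15, ≈ 6.7-fold down — the
paper's patients called down had no detectable protein, so strong
repression is the realistic regime); additional unknown-mechanism
downregulation is injected among the remaining patients at the rate
needed to reach the overall planted prevalence of 0.31. Deletion is
modelled as transcriptionally compensated: it moves the genomic ratio
but not expression. This reflects the observed data structure —
deletion status and expression-down status are nearly independent in
the real cohort (5/21 ≈ 13/55) — and keeps the planted prevalences
individually recoverable; a literal (CN/2) multiplicative expression
term would park every hemizygous patient exactly on the 3-SD call
boundary and make the planted "down" prevalence unrecoverable by
construction. Cohort qPCR noise is 0.15 log2 units (replicate-level
technical error), genomic-ratio noise 0.1. Missingness is MCAR at rates
18/68 (miR-370) and 13/68 (genomic qPCR), reproducing the real
denominators in expectation.

What the generator does **not** emulate: array waves and GC bias,
clonal heterogeneity and subclonal CN states, probe cross-hybridisation,
amplification-efficiency departures from 2, and informative (non-MCAR)
missingness. Passing tests therefore demonstrate correctness of the
statistical machinery under the declared generative model, not
robustness to every artifact of real arrays and clinical sampling.

## Calibration experiments and problem sizes

The test suite runs the screen on 1000 null replicate panels (expression
independent of CN) and requires the raw p < 0.05 rate among tested
miRNAs to sit within 3 binomial SEs of 5%, and on 10 dosage panels run
through the full marker → segmentation → locus-call → screen path,
requiring ≥ 95% of planted miRNAs recovered as significant with the
correct direction. These sizes give the calibration check ≈ 19,000
tested null miRNAs and the power check 190 planted events — enough for
the stated tolerances without excess runtime.

Cohort parameter recovery is checked at n = 2000 patients. For that
experiment the normal-control pool is scaled with the cohort at the
study's design ratio (10 normals per 68 patients, ≈ 294 normals):
with only 10 normals the sampling error of the fitted 3-SD cutoffs —
not the pipeline under test — dominates the prevalence estimates (the
marginal false-call rate of a mean ± 3·SD rule estimated from 10 draws
is ≈ 1% per side with a heavy right tail across seeds). The 68-patient
default keeps 10 normals, as in the emulated study; the held-out
specificity check also uses exactly 10 normals and draws its held-out
samples from the fitted normal model.

## Known limitations

- The segmenter is a documented stand-in, not a reimplementation of any
  vendor algorithm; breakpoint placement near small events (< 2·`min_markers`
  markers) is limited by the flank constraint.
- The 0.75 genomic-deletion ratio threshold is a package default with no
  external standard behind it.
- The B statistic's absolute calibration depends on `prior_prop` and
  `effect_sd`; use the p-value route when replicability across tools
  matters.
- The screen treats copy number as a binary label (altered vs neutral);
  continuous dosage–response models are out of scope.
- No survival or treatment-response modelling is included; clinical
  covariates are carried through for stratified reporting only.
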