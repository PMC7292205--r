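---
title: "Methods behind the qPCR cell-of-origin assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the qPCR cell-of-origin assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coodx)
```

## The classification problem

Diffuse large B-cell lymphoma separates into two cell-of-origin subtypes,
germinal center B-cell-like (GCB) and activated B-cell-like (ABC), defined
by global expression profiling on fresh tissue. `coodx` implements the
qPCR route to the same call on FFPE material: measure 32 informative genes
plus three housekeeping genes, normalize, and score the sample with a
calibrated linear classifier. Samples whose class probability does not
clear a confidence threshold are reported as unclassified (UNC) rather
than forced into a subtype — in clinical use a wrong subtype is worse than
no subtype.

## qPCR preprocessing

Raw input is a triplicate of cycle-threshold (Ct) values per sample and
gene. Two rules turn these into expression values:

1. **Replicate concordance** (`aggregate_replicates()`). If the spread of
   the available replicates exceeds `max_spread` cycles (default 0.5, the
   order of magnitude of a pipetting mishap against a replicate SD of
   roughly 0.1–0.2 cycles on a well-run TaqMan plate), the replicate
   farthest from the median is dropped and the remaining pair re-tested;
   a pair still discordant fails the measurement. "Undetermined" wells
   count as missing, not as failures of the whole triplicate. The
   numeric criterion is an acceptance setting of the laboratory, not a
   biological constant, so it is exposed as a parameter and recorded in
   the QC output.
2. **Normalization** (`delta_ct()`). ΔCt of a target gene is its mean Ct
   minus the unweighted mean of the three housekeeping mean Cts (IPO8,
   PGK1, TFRC); the value carried forward is −ΔCt, which rises with
   transcript abundance. Because every target is referenced to the same
   per-sample housekeeping mean, any constant per-sample offset — plate,
   input amount, global degradation — cancels exactly; the test suite
   asserts this invariance on random tables. A sample whose housekeeping
   genes are not all measurable is failed wholesale: without the
   normalizer no target value on that sample means anything.

Sample-level QC (`sample_qc()`) tolerates up to `max_failed_genes = 3`
failed targets per sample. Published FFPE panels of this size report
success rates around 99%; the exact tolerance is again configuration, not
a claim about biology, and both settings travel in the QC report.

No PCR-efficiency correction or 2^−ΔΔCt fold-change arithmetic is applied;
the classifier consumes −ΔCt directly.

## Signature selection

`run_rfe()` is standard SVM-driven recursive feature elimination: fit a
linear soft-margin SVM (cost `C = 1`) on genes standardized to zero mean
and unit variance using training-set statistics only, score each gene by
the squared weight it receives in the decision function, drop the
lowest-scoring `step_fraction` (default 10%, at least one gene, never
below `target_size`), refit, repeat. Squared weight is the canonical
elimination criterion for linear SVM-RFE; the elimination fraction is a
speed/stability trade-off with no single right value, so it is a logged
parameter. Ties in score are broken by dropping the lexicographically last
gene identifier, which makes the whole procedure deterministic and
invariant to sample and feature order — both properties are asserted in
the tests. The trace records every round, so the selection is auditable
after the fact.

## The classifier and its calibration

`coo_fit()` freezes per-gene standardization statistics from the training
data, fits the linear SVM at `C = 1`, and orients the decision function so
a positive margin means GCB. Margins are mapped to probabilities with a
Platt-style sigmoid, P(GCB) = plogis(a·m + b), fitted by minimizing
cross-entropy against Platt's smoothed targets on **out-of-fold** margins
from stratified 5-fold cross-validation — calibrating on resubstitution
margins would be optimistically steep. The slope is constrained
non-negative so the probability is monotone in the margin even on
degenerate (no-signal) training data. Which sigmoid family produced the
original assay's probabilities is not documented anywhere we know of;
Platt scaling is the field default for margin-to-probability maps, and the
calibration method is recorded as metadata in the model artifact so
alternatives remain distinguishable.

The call rule is strict: GCB if P(GCB) > 0.75, ABC if P(ABC) > 0.75,
otherwise UNC, and a probability of exactly 0.75 is UNC. For comparison
with IHC surrogates, which only resolve GCB vs non-GCB, calls collapse
deterministically: GCB stays GCB; ABC and UNC become non-GCB.

Missing or non-finite panel-gene values are a hard error at prediction
time. Imputing expression for a clinical call would silently change the
assay's input space, so the package refuses instead.

The model file (JSON) carries panel order, standardization, weights, bias,
calibration and threshold together; a call is reproducible from that one
artifact, and serialization round trips are tested to 1e−12.

## Hans surrogate

`hans_call()` applies the CD10/BCL6/MUM1 decision tree with positivity at
≥ 30% of tumor cells staining. The published description sets the cutoff
"at 30%" without fixing the boundary case; we count exactly 30% as
positive (≥), document it, and expose the cutoff. The full 8-pattern truth
table is asserted against a hand-coded oracle in the tests.

## Agreement statistics

`overall_agreement()`, `ppa_npa()` and `wilson_ci()` reproduce the
diagnostic-agreement toolkit: overall percent agreement is the confusion
diagonal over the samples callable by both assays (samples missing in
either set are dropped and logged, never silently); PPA/NPA treat the
reference method as the standard with GCB as the positive class. Intervals
are Wilson score intervals: among the common "asymptotic" binomial
intervals, Wilson reproduces the printed fresh-tissue interval
(0.94–0.99 for 209/215) where the Wald interval does not. One printed
upper bound elsewhere (0.957 for 422/451) is matched by neither Wilson
(0.955) nor Wald (0.958); we keep Wilson and flag the discrepancy rather
than reverse-engineering a rounding.

`compare_paired_agreement()` is the exact McNemar construction on
per-sample correctness indicators against a shared reference: conditioning
on discordant pairs, the count is Binomial(b + c, ½) under the null and
the p-value is the two-sided exact tail. The original comparison's test
statistic is unnamed in the source material and its sample-level
cross-tabulation is not printed, so no specific p-value is treated as a
reference value.

## Clustering and survival

`pearson_distance()` computes d = 1 − r on −ΔCt values as stored; no
re-centering or scaling is applied before correlation, since display
scaling of heatmaps is cosmetic and any per-gene affine rescaling leaves
Pearson correlation unchanged anyway. Constant profiles have no defined
correlation and are rejected by name. `complete_linkage()` wraps
agglomerative clustering with max-linkage (heights verified against a
brute-force agglomerator on small random instances), and `km_curve()` /
`logrank_test()` wrap the standard product-limit estimator and k-group
log-rank test with hypergeometric tie handling (verified against hand
tabulation).

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable with known ground
truth and no external data. Its generative model is deliberately the
simplest structure under which the pipeline's assumptions hold:

- **Expression**: class-conditional Gaussians with unit variance; each of
  the 32 panel genes is shifted by `effect_size` (default 2 SD) in its
  overexpressing class; noise genes are standard normal everywhere; an
  optional constant batch offset can be added to alternating samples.
  Defaults mirror the assay's training cohort: 167 ABC + 183 GCB samples
  and 468 noise genes alongside the 32-gene panel.
- **Ct values**: base Ct 25 (a typical qPCR midrange; the value cancels in
  ΔCt) minus expression, plus Normal(0, `replicate_sd` = 0.2) replicate
  noise, in triplicate; housekeeping genes have expression 0 by
  construction, so noise-free Ct inverts exactly back to the planted
  expression — asserted to 1e−9.
- **IHC**: CD10 centered at 60% in GCB vs 10% in ABC, MUM1 the reverse,
  BCL6 high in both, with Gaussian noise (SD `ihc_noise` = 10 points,
  clamped to [0, 100]) driving crossover; at zero noise the Hans tree
  reproduces the true binary labels exactly.
- **Survival**: exponential event times at class hazards (defaults
  0.030/month for ABC vs 0.015/month for GCB — medians near 23 vs 46
  months, the direction and rough magnitude of outcome separation in
  R-CHOP-treated cohorts) with independent Uniform(0, 84 months)
  censoring, matching a several-year accrual window. The censoring
  mechanism is a modeling choice; real follow-up is administrative, not
  uniform.

Identical specs (including seed) produce byte-identical cohorts.

What the generator does **not** emulate: microarray probe effects,
FFPE-specific RNA degradation and its dependence on storage time,
correlated gene–gene structure within a subtype, PCR efficiency drift, or
label noise in the reference diagnosis. Passing tests on this generator
therefore demonstrate that the machinery is correct and self-consistent —
planted signal is recovered, calibration behaves, null data yields chance
accuracy — not that the assay achieves any particular accuracy on real
tissue; the published validation counts, which the agreement module
reproduces exactly, are the evidence on real material.

## Numerical choices and degenerate inputs

- Standardization with zero variance: constant genes are centered and
  left at zero; they receive zero weight and zero elimination score.
- Platt fitting uses L-BFGS-B with the slope bounded below at 0; on
  no-signal data the slope collapses toward 0 and probabilities sit near
  0.5, which the strict call rule turns into UNC.
- Display rounding is half-up to one decimal in percent (base R's
  `round()` is half-even), applied only at reporting time; internal values
  are never rounded.
- Expression matrices are genes-in-rows, samples-in-columns, and a
  transposed file fails validation (duplicate/invalid identifiers) rather
  than being silently auto-corrected — silent transposition is the classic
  expression-matrix bug.

## Problem sizes used in the checks

The test suite and the acceptance script run the selection benchmark at
the training scale (350 samples, 500 genes, five seeds), classifier
recovery on independent 200-sample cohorts, null calibration at 200
samples, and oracle comparisons on fixtures of at most 20 subjects or 12
leaves — sizes at which the brute-force oracles are exact and the
stochastic checks have comfortable margins around their thresholds.

## Known limitations

- The selection benchmark recovers *planted* genes; deriving the actual
  published 32-gene panel requires the original microarray compendium and
  its normalization stack (SCAN, BrainArray, ComBat), which are out of
  scope here. The published panel ships as the package default instead.
- Only the ABC/GCB axis is modeled; genetic subtypes (MYD88/CD79B and
  friends), alternative IHC algorithms (Choi, Tally), and Cox-adjusted
  survival modeling are not implemented.
- The unweighted housekeeping mean assumes the three reference genes are
  equally stable; the package does not test that assumption on the data.
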