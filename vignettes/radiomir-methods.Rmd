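---
title: "Methods: the miR-200a/b/-429 radioresistance analysis pipeline"
author: "radiomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miR-200a/b/-429 radioresistance analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiomir)
```

This vignette documents the statistical models behind each stage of the
pipeline, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where conventions were genuinely open.

## The expression score

Small-RNA-seq counts are normalized to reads per million annotated mature
miRNAs and log2-transformed; a pseudocount of 1 is added inside the log so
zero counts map to zero (`normalize_rpm(counts, pseudocount = 1)`). The
pseudocount is configurable because normalization conventions differ on
how zeros are handled; 1 is the common default and keeps the scale
interpretable.

The miR-200a/b/-429 score is the per-patient arithmetic mean of the
median-centered, log2-scale expression of the five cluster members.
Median centering is strictly **per cohort**: the centered values, and
hence the scores, are not comparable across cohorts that were profiled
separately. When cohorts are merged for a pooled analysis (as in the
site-specific recurrence models), each cohort is centered on its own
medians first and the centered scores are then pooled. This mirrors how
cohorts profiled on different platforms can only be combined after
within-cohort standardization.

For RT-qPCR cohorts, expression is −ΔCt: the Ct of each miRNA minus the
mean Ct of the reference miRNAs in the same sample, negated so that
higher values mean higher abundance and "low score = low expression"
matches the sequencing variant. One cycle equals one log2 unit, so −ΔCt
is on the same scale family as log2 RPM. The reference normalization is
the mean of the reference Cts; the three-member score variant
(miR-200a-3p, miR-200b-3p, miR-429) serves assays where only the dominant
strands were profiled.

Heteroscedasticity of expression over the measured range is checked with
the White test: the squared residuals of a fit are regressed on the
fitted values and their squares, and n·R² is referred to χ²(2). When the
squared residuals carry no variation at all the statistic is defined as 0
(p = 1) rather than relying on an ill-conditioned auxiliary fit.

## Survival analysis

**Endpoints.** `build_endpoint()` constructs central pelvic control,
lateral pelvic control, distal control, and progression-free survival.
The censoring convention for site endpoints had to be fixed by design: a
recurrence at a *different* site censors the target endpoint at the
recurrence time (the patient leaves the risk set for the target site once
salvage treatment begins), and patients without recurrence are censored
at the end of follow-up. All times are truncated at a 60-month
administrative horizon (configurable), matching the follow-up window of
the clinical analyses.

**Cox models** use the partial likelihood with Efron tie handling (the
standard default of modern survival software; ties are rare with
continuous follow-up anyway) via the survival package. Stepwise selection
first screens candidates at univariate p ≤ 0.1, then adds terms at
likelihood-ratio p ≤ 0.05 and removes at p ≥ 0.10 — conventional
statistical-package entry/removal defaults; the result records whether
forward and backward searches agree. Proportional hazards are inspected
with log-minus-log plots (`log_minus_log()`), on which exponential
survival is a line of slope 1 in log time and proportional hazards appear
as a constant vertical offset.

**Optimal cutoff.** Biomarker dichotomization uses an exhaustive scan:
every distinct score value whose split leaves at least 10% of patients in
each group is scored by the two-group log-rank χ², and the maximizer is
reported together with *both* the uncorrected log-rank p and a corrected
p. The default correction permutes scores against outcomes and re-runs
the entire scan (1000 permutations), giving the null distribution of the
scan maximum; a Bonferroni bound over the number of candidate cutoffs is
available as a cheaper alternative. The corrected p is never smaller than
the uncorrected one. The log-rank statistic itself is computed directly
from the hypergeometric observed-minus-expected sums in vectorized form
(validated against `survival::survdiff` to 1e-10) because the scan
evaluates it across all cutoffs and permutations at once.

**Multiplicity.** Pairwise group comparisons use the Holm–Šidák step-down
adjustment, 1 − (1 − p)^(m − i + 1) over the ordered p-values with a
running maximum.

The hypoxia classifier score is dichotomized at its predefined cutoff of
zero; the boundary value 0 is assigned to the "less hypoxic" class (the
convention had to be fixed on one side; ties at exactly zero are
measure-zero for a continuous score).

## Target network inference

For each (miRNA, candidate gene) pair, Spearman correlation (average
ranks for ties) is computed per cohort with the two-sided t
approximation for p. Benjamini–Hochberg q-values are computed **per
miRNA, per cohort** — the adjustment family is that miRNA's candidate
list, matching how per-miRNA candidate sets are retrieved from target
databases; a global family is available as an option. Pairs with a
constant expression vector have no defined correlation and are excluded
from the family rather than assigned p = 1 (assigning 1 would dilute the
FDR family with non-tests).

The inclusion rule is: ρ < 0 in both cohorts, nominal p < 0.05 in both,
and q < 0.1 in at least one. Network edges use the same q rule
(configurable to "both"). Multiple probes per gene should be collapsed to
the most variable probe before correlation; the synthetic generator emits
one probe per gene, so the collapse is not exercised there.

## Enrichment

Over-representation uses the one-sided hypergeometric tail within a
finite background, with fold enrichment
(overlap/list)/(set/background). Both study backgrounds are supported:
the global gene universe and the candidate-target list from which the
query was filtered. BH families are per gene-set category
(process/component/function/pathway), mirroring per-category annotation
output, with significance at q < 0.01. The conservative EASE variant
(overlap reduced by one) is available but off by default, since the
standard Fisher/hypergeometric form is the base statistic.

## ADC quantification

The mono-exponential diffusion model ln S(b) = c − b·ADC is fitted per
voxel by ordinary least squares on the log signals. Normalizing by S0
only shifts the intercept, so the fit is run on ln S directly. Voxels
with any non-positive signal are flagged invalid and excluded. b-values
always come from the input metadata (the package never hard-codes an
acquisition protocol), necrosis is ADC > 0.0011 mm²/s with strict
inequality, and the per-tumor summary is the median over all valid ROI
voxels *including* necrosis — excluding it would make the summary depend
on the classification threshold.

A note on noise: at a signal-to-noise ratio of 20 with four b-values
spanning 200–1000 s/mm² and ADC ≈ 1e-3 mm²/s, straightforward error
propagation through the log-linear fit gives per-voxel relative errors on
the order of 10%. Voxel-wise maps at this SNR are therefore noisy by
nature; the per-tumor **median** ADC — the quantity all downstream
analyses use — is accurate to well under 1% over a few thousand voxels.
The test suite asserts exactly this: machine-precision recovery on
noiseless phantoms, sub-2% recovery of the median at SNR 20, and a 20%
sanity bound on the per-voxel median error.

## Histology quantification

Stain unmixing uses Ruifrok–Johnston optical-density deconvolution with
the standard H-DAB vector set (configurable; the residual channel is the
normalized cross product). The synthetic renderer uses the same matrix as
a forward model, so deconvolution is an exact inverse for float renders
and within quantization error for 8-bit ones.

Nucleus segmentation thresholds the DAB channel, labels 8-connected
components (implemented over the pixel adjacency graph; the underlying
image library's labelling is 4-connected), and splits components larger
than 200 px — taken to be clusters of touching cells — by watershed on
the Euclidean distance transform with 1-px h-maxima suppression to
prevent oversegmentation of pixelated discs. Nuclei are attributed to
regions by **centroid membership**: centroids in necrosis are removed,
and only centroids inside the parenchyma (GFP-positive) mask are kept.
Fractions follow their definitions: necrotic area over ROI; hypoxic and
GFP-positive area over the viable ROI (ROI minus necrosis); cell density
is nuclei per mm² of GFP-positive area at 0.46 µm/px by default.

Manual steps of the original workflow (ROI outlining, threshold choice)
are explicit inputs — masks and thresholds are passed in, never guessed
from the data — and masks from adjacent sections are assumed
pre-aligned.

## Radiation response

Clonogenic survival: PE = colonies/seeded at 0 Gy;
SF = (colonies/seeded)/PE, so SF(0 Gy) = 1 identically. γH2Ax intensities
are normalized to the spiked-in REH reference population per sample and
then to the unirradiated condition. Doubling time is ln 2 over the slope
of log volume vs time within a caller-specified exponential-phase window
(the window is an input, matching how the growth phase is chosen by
inspection); non-positive slopes are flagged non-growing. T₁.₅ₓ is the
first crossing of 1.5× the day-0 volume, linearly interpolated between
bracketing measurements, censored at the last observation when never
reached. TGD is the difference of group means of uncensored T₁.₅ₓ
(censored values still enter the Kaplan–Meier comparison; a flag is
raised when censoring exceeds 20%), and EF is the TGD ratio between the
miRNA-overexpressing and control lines — the standard radiobiology
definition of a response enhancement factor.

## What the synthetic data emulate

The generator defaults reproduce the study conditions: cohorts of 90 and
110 patients; five miRNAs drawn from a multivariate Gaussian on the log2
scale with pairwise correlation 0.85 (within the observed 0.74–0.93
range); exponential proportional-hazards outcomes with hazard
exp(log(0.40)·score) and a baseline rate set to a 30% event probability
by 60 months; recurrence sites drawn 21/20/59%
central/lateral/distant, independently of time, one site per patient;
planted target genes as negative linear transforms of their miRNA with
noise calibrated via the bivariate-normal identity
ρ_S = (6/π)·asin(ρ_P/2) to an expected Spearman correlation of −0.5,
among 2000 candidates (per-miRNA candidate lists cover ~60% of the pool,
always including the planted targets, shared between cohorts); a DWI
phantom at SNR 20 with a necrotic blob of exactly 25% of the ROI at
ADC 1.4e-3 vs 8e-4 mm²/s viable; rendered H-DAB sections with 70 single
nuclei, 6 touching pairs (offset 1.7 r so the pair is one >200 px
component whose two distance-transform maxima survive pixelation) and 10
nuclei inside necrosis; and exponential xenograft growth (Td 4.5 d,
V0 ≈ 250 mm³, 8 tumors per group, 5% lognormal measurement noise) with
post-irradiation growth arrest of 20 d (miR line) vs 4 d (control), so
the planted enhancement factor is 5.

Deliberately **not** emulated: sequencing-read-level noise and batch
effects, multi-site recurrences (a config option, off by default),
Rician MRI noise (additive Gaussian is consistent with the log-linear
fit; Rician bias matters mainly at low SNR), spatial noise correlation,
stain variability and uneven illumination, and inter-tumor heterogeneity
in radiosensitivity. Passing tests therefore demonstrate the correctness
of the statistical machinery under the stated models, not robustness to
every artifact of real data.

## Numerical choices and degenerate inputs

- All random streams derive from one master seed through fixed per-stage
  offsets, so stages are independently reproducible and full runs are
  byte-identical for equal configurations.
- The equicorrelation matrix is Cholesky-factorized; a non-positive-
  definite request is rejected with a clear message.
- Zero-total samples (RPM), missing reference Cts, constant covariates,
  groups without events, empty ROIs and zero GFP areas are all rejected
  with named errors rather than producing NaN.
- Degenerate t-tests (constant groups) return NA rather than erroring,
  since they arise legitimately in noiseless phantom runs.
- Cutoff candidates assign "low" as score ≤ cutoff; group floors use
  ceiling(fraction·n).
- Exact-count phantom regions (necrosis, hypoxia, GFP) are constructed by
  pixel/voxel counting, so fraction recovery is testable to one-pixel
  rounding instead of a stochastic tolerance.

## Problem sizes used by the test and acceptance runs

Monte-Carlo checks use sizes chosen to keep the whole suite under a few
minutes while leaving the binomial error of each rate well inside its
asserted band: 200–400 replicates for coverage/type-I rates (binomial
s.e. ≈ 1–1.5%), 100 replicates for cutoff recovery, 200 null replicates
(and 5 planted replicates) for the target-filter FDR/recall, 1000 random
vectors for the BH/Holm–Šidák equivalences, 10⁴ voxels for the noisy ADC
phantom, and the default 256² histology scene.

## Known limitations

- Site-specific endpoints use censoring, not competing-risks modeling;
  cumulative-incidence estimates would need a Fine–Gray extension.
- The permutation correction permutes scores against whole outcome rows,
  which assumes exchangeability under the null (no covariate-dependent
  censoring linked to the score).
- The enrichment module tests user-supplied gene sets only; it does not
  reduce redundancy between overlapping ontology terms.
- Stain vectors are assumed known; estimating them from the image (e.g.
  by non-negative matrix factorization) is out of scope.
- T₁.₅ₓ interpolation is linear in volume; log-linear interpolation is a
  noted option but volumes sampled every 2 days make the difference
  negligible.
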