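# radiomir

Analysis pipeline for evaluating the **miR-200a/b/-429 cluster score** as a
biomarker of tumor radioresistance in locally advanced cervical cancer, with
the full supporting tool chain: site-specific survival analysis,
miRNA–target anticorrelation network inference, gene-set
over-representation, diffusion-weighted MRI (ADC) quantification,
digital-histology quantification, and xenograft radiation-response metrics.
Every stage is exercisable end to end on synthetic data with known ground
truth, so the statistical machinery is testable without access to patient
data.

It is written for researchers analyzing miRNA biomarkers against clinical
outcome and for preclinical imaging groups quantifying treatment response.

## The model

**Score.** For each patient, expression of the five mature cluster members
(miR-200a-5p/-3p, miR-200b-5p/-3p, miR-429) is normalized (log2 reads per
million for sequencing, −ΔCt against reference miRNAs for RT-qPCR),
median-centered per feature within the cohort, and averaged:

    score_j = (1/5) * sum_i ( x_ij − median_j(x_ij) )

A low score means low cluster expression. A three-member variant
(miR-200a-3p, miR-200b-3p, miR-429) serves qPCR cohorts.

**Survival.** Endpoints are central pelvic control, lateral pelvic control,
distal control, and progression-free survival over a 60-month horizon;
recurrence at a non-target site censors a site endpoint at the recurrence
time. The score is tested as a continuous covariate in Cox
proportional-hazards models (Efron ties, Wald CIs), by forward/backward
stepwise selection against clinical covariates (univariate screen at
p ≤ 0.1), and by Kaplan–Meier curves split at the optimal cutoff — an
exhaustive scan over score values maximizing the log-rank χ², with a
permutation-corrected p-value for the scan multiplicity.

**Target network.** Candidate target genes (database-style per-miRNA
lists) are filtered by Spearman anticorrelation in two independent
cohorts: ρ < 0 with nominal p < 0.05 in *both* cohorts and
Benjamini–Hochberg q < 0.1 in at least one. Passing pairs form a bipartite
miRNA–gene network; over-representation of the resulting gene list is
tested by the hypergeometric tail against either the global gene universe
or the candidate list as background.

**Imaging.** Voxel-wise ADC maps come from the log-linear fit
ln S(b) = c − b·ADC over the acquired b-values; voxels with
ADC > 0.0011 mm²/s are classified necrotic and the per-tumor median ADC is
the summary statistic. Histology sections are unmixed by Ruifrok–Johnston
H-DAB color deconvolution; nuclei are threshold-segmented with
watershed splitting of clusters larger than 200 px on the Euclidean
distance transform, and necrotic/hypoxic/GFP-positive fractions and cell
density are computed from aligned masks.

**Radiation response.** Tumor doubling time Td from exponential growth
fits; time to 1.5× baseline volume (T₁.₅ₓ) by linear interpolation; tumor
growth delay TGD = mean T₁.₅ₓ(irradiated) − mean T₁.₅ₓ(unirradiated); and
the enhancement factor EF = TGD(miR line)/TGD(control line).

## Worked example

```r
library(radiomir)
cfg <- sim_config(seed = 1)            # two cohorts, n = 90 + 110
res <- run_synthetic_pipeline(cfg)     # every stage, ~2 s
res$survival$pfs$cox
```

The numbered scripts under `analysis/` run the same stages as narrative
drivers and write their tables under `results/`. On the default seed they
print:

```
pfs              HR 0.43 (0.32-0.58) P 1.2e-08 | cutoff at 22% low, corrected P 0.002
central_control  HR 0.27 (0.15-0.49) P 1.3e-05 | cutoff at 22% low, corrected P 0.00399
...
potential targets: 50 of 2000 candidates (50 planted; recall 100%)
network: 50 genes, 164 edges; 48 (96%) genes interact with >1 miRNA
necrotic fraction (ADC > 0.0011): 0.244 (truth 0.250)
histology: 82 nuclei (truth 82), density 8213 /mm^2
enhancement factor EF = 5.20 (planted 5.0); irradiated-group t-test P = 1.97e-19
```

The simulated hazard ratio per score unit is 0.40; the fitted univariate
Cox HR of 0.43 (CI covering 0.40) shows the recovery, the cutoff scan
allocates ~22% of patients to the low-score group, the target filter
finds all 50 planted anticorrelated genes among 2000 candidates, and the
imaging and response modules recover their planted phantom truths.

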