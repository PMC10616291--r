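# radm6a — radiation biodosimetry from RNA m6A methylation

`radm6a` is an R package plus analysis workflow for discovering
radiation-responsive RNA N6-methyladenosine (m6A) biomarkers and
reconstructing absorbed ionizing-radiation dose from them. It is aimed at
researchers working on transcriptome-level biodosimetry: the package covers
the whole chain from raw two-channel epitranscriptomic microarray
intensities and qPCR Ct values to cross-validated dose-prediction models.

## What it computes

**Epiarray quantification.** Two-channel intensities (IP = immunoprecipitated,
Cy5 role; Sup = supernatant, Cy3 role) are spike-in normalized per channel
(log2 centering on control probes), and the per-gene m6A modification level
is the IP share of total signal,

    level = 100 * IP / (IP + Sup),

with the m6A quantity the normalized linear IP intensity. Differential
methylation between exposed and sham groups is called at fold change > 2 or
< 0.5 with p < 0.01 (two-sided t-test on log2 levels).

**Two-stage screen.** Transcripts are categorized per timepoint
(Hyper / Hypo / Inconsistent), each category's log2 fold-change time
profiles are split into sub-categories by fuzzy c-means, the consistently
responding sub-category is selected by the sign of the cluster mean profile
at every timepoint, and candidates are the intersection of that set with the
single-timepoint hyper sets at the anchor days.

**qPCR arithmetic.** MeRIP-qPCR IP enrichment
`E^(Ct_input − Ct_IP) · m_input/m_IP` (amounts rescaled to a common RNA
mass), relative m6A levels vs the unirradiated control with delta-method
errors, ΔΔCt relative expression, SELECT single-base standard curves
(`r = 2^(Ct − Ct_100%)` regressed on the m6A fraction) with fraction
estimation, and one-way ANOVA with Monte-Carlo Dunnett many-to-one
comparisons.

**Dosimetry.** Inverse-regression calibration: per-timepoint quadratic
models `dose = b0 + b1·m + b2·m²` and an integrated bivariate cubic model
over the 10 monomials `m^i t^j (i+j ≤ 3)` of marker level and time post
irradiation; R² between actual and estimated doses; dose-cutoff ROC AUC
(rank form, ties at half credit) with 100-times-repeated stratified
five-fold cross-validation.

**Synthetic data.** A generator emulates the whole study — a Hill-in-dose ×
log-normal-in-time response surface, planted hyper/hypo transcripts over a
null transcriptome, spike-in scale factors, and Ct tables that invert the
quantification formulas exactly at zero noise — so every stage is testable
against known truth.

## Worked example

```r
library(radm6a)

## simulate the default study: doses 0-6.5 Gy, days 1-28, n = 5
pts <- simulate_dose_response(study_design(), surface_params(),
                              noise_cv = 0.1,
                              seed = child_seed(1, "dose_response"))

## integrated dose model and cross-validated cutoff ROC
cubic <- fit_bivariate_cubic(pts)
cubic$r2
#> [1] 0.8153847
ev <- evaluate_cutoff(pts, 4, cv = list(k = 5, reps = 100,
                                        seed = child_seed(1, "cv")))
c(apparent = ev$auc, cv_mean = ev$cv_mean_auc)
#>  apparent   cv_mean 
#> 0.9854400 0.9851980
```

The training R² of 0.82 says the cubic surface explains most of the
dose variance of the noisy simulated marker; the cross-validated AUC of
0.985 at the 4 Gy cutoff says held-out samples above/below 4 Gy are almost
perfectly ranked by predicted dose. Running the screen driver
(`analysis/02_screen.R`) on the default planted study prints

    candidates: 60; sensitivity 1.000; FDP 0.000

i.e. the two-stage screen recovers exactly the 60 planted
consistently hyper-methylated transcripts out of 2,000.

The numbered scripts under `analysis/` run the full workflow — simulate,
screen, qPCR validation, dosimetry — and write their tables under
`results/`.

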