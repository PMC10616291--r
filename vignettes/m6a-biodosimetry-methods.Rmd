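---
title: "Methods: m6A biomarker screening and radiation dose reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A biomarker screening and radiation dose reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radm6a)
```

# The problem

Absorbed ionizing-radiation dose must often be reconstructed after the fact
from a biological measurement (biodosimetry), for example in triage after a
radiological accident. RNA N6-methyladenosine (m6A) methylation of specific
transcripts — `Ncoa4`/`NCOA4` being the prototype — responds to irradiation
in peripheral blood mononuclear cells in a dose- and time-dependent way,
which makes per-transcript m6A levels candidate dosimeters. This package
implements the full analysis chain for that idea:

1. **Epiarray quantification** — per-gene m6A modification levels from
   two-channel (IP/Sup) microarray intensities with spike-in normalization.
2. **Two-stage screening** — temporal categorization of differentially
   methylated transcripts, fuzzy c-means sub-clustering, consistency
   selection, and cross-stage intersection to nominate biomarkers.
3. **qPCR quantification** — MeRIP-qPCR IP enrichment, delta-delta-Ct
   expression, SELECT single-base m6A fractions, ANOVA + Dunnett group
   testing.
4. **Dosimetry** — per-timepoint quadratic and integrated bivariate cubic
   calibration models (dose regressed on marker level and time) with R²,
   dose-cutoff ROC and repeated cross-validation.
5. **Synthetic data** — a generator that emulates the statistical structure
   of all of these inputs, so that every stage is testable end to end
   without external data.

# The synthetic study and what it does (not) emulate

The default design mirrors a mouse total-body-irradiation time course:
gamma-ray doses $\{0.2, 0.5, 1, 2, 4, 6.5\}$ Gy plus sham controls, sampled
at days $\{1, 3, 7, 14, 28\}$ post irradiation with $n = 5$ animals per
group; an optional 10 Gy arm is restricted to days 1 and 3 (animals at that
dose do not survive longer). The expected relative m6A level of the marker
follows a Hill curve in dose times a log-normal kernel in time,

$$f(d, t) = b + A \, \frac{d^h}{d^h + K^h} \,
  \exp\!\left(-\frac{\ln^2(t/t_{peak})}{2 w^2}\right),$$

with defaults $b = 1$, $A = 6$, $K = 2$ Gy, $h = 1.2$, $t_{peak} = 14$ d,
$w = 1.5$ log-days for the Ncoa4-like marker (day-14 peak, detectable
day-1 response, roughly six-fold saturation). These values are the
package's own choice of a realistic response; published time-course figures
constrain the shape (unimodal on a log-spaced day grid, saturating in dose)
but not the parameters, and no variance components are published either.
The default measurement noise — multiplicative log-normal with coefficient
of variation 0.1 on fold values, additive Gaussian with sd 0.15 on log2
array intensities and sd 0.1 on Ct values — was likewise chosen once for
test power, not fidelity to a particular assay.

Consequences worth stating plainly:

* Passing tests demonstrate that the *methods* behave correctly under the
  assumed error model (unbiased recovery, calibrated error rates,
  reproducible CV), not that real arrays or real qPCR obey that model.
* The generator plants per-gene truth labels (`consistent_hyper`,
  `transient_hyper`, `hypo`, `null`) so sensitivity and false-discovery
  proportion of the screen are measurable exactly.
* Probe cross-hybridization, background, dye bias beyond a per-channel
  scale factor, and read-level artifacts are deliberately not modeled.

The log-normal noise factors use $\mu_{\log} = -\sigma_{\log}^2/2$, so the
factor has mean exactly 1 and group means are unbiased for the surface —
the law-of-large-numbers checks in the tests rely on this convention. One
global seed expands into per-component child seeds by fixed documented
offsets (`child_seed()`), so any sub-simulation can be reproduced in
isolation.

# Epiarray quantification

Each channel of a sample is centered on its spike-in probes: log2
intensities are shifted by minus the mean log2 spike-in intensity, after
which the spike-in mean is zero per channel and within-channel rank order
is untouched. The modification level is the IP share of total signal,
$100 \cdot \mathrm{IP} / (\mathrm{IP} + \mathrm{Sup})$, and the m6A
quantity is the normalized linear IP intensity itself. Differential calls
between exposed and sham groups use the fold change of mean levels on the
linear scale with an unpaired two-sided t-test on log2 levels; a gene is
`hyper` when FC $> 2$ and $p < 0.01$, `hypo` when FC $< 0.5$ and
$p < 0.01$ (strict inequalities, no multiple-testing correction on the
calls; a Benjamini–Hochberg column is emitted for information). The test
is Student's pooled-variance by default with a Welch flag — a deliberate
choice: the comparison is a standard two-group microarray contrast at
$n = 5$, and the thresholding convention filters on the raw p-value.
Degenerate inputs are defined, not fatal: zero within-group variance with
equal means gives $p = 1$; with unequal means $p = 0$ with a warning.

# The two-stage screen

Stage I assigns each transcript a broad category from its per-timepoint
statuses — `Hyper` (hyper at $\ge 1$ timepoint, never hypo), `Hypo`
(symmetric), `Inconsistent` (both, removed from further analysis), `None`.
Each category's log2 fold-change time profiles are then split into two
sub-categories by fuzzy c-means (fuzzifier 2), and the consistently
responding sub-category is selected by the sign pattern of each cluster's
*unstandardized* mean profile: for `Hyper`, every timepoint mean must be
positive. Stage II takes the single-timepoint hyper sets at the two anchor
days (1 and 14 by default). The candidate set is the exact intersection of
the consistent stage-I set with both stage-II sets, and by construction is
a subset of every contributing set.

Two design choices deserve their rationale:

* **Centering, not z-scoring, before clustering.** A consistently elevated
  ("flat-high") profile has essentially no temporal variance; dividing by
  the per-gene sd maps it to a pure noise direction on the unit sphere, and
  no c-means implementation can then separate flat-high from single-peak
  profiles (we verified the same failure with an independent fuzzy c-means
  implementation). Mean-centering keeps the flat class tightly grouped near
  the origin while preserving shape differences, and is therefore the
  default; full z-scoring remains available as `scale = "z"` for
  magnitude-free shape clustering of strongly varying profiles.
* **Union of sign-consistent clusters.** When all profiles in a category
  share the consistent pattern, c-means may split that one population
  across both clusters; any cluster whose mean profile keeps the category's
  sign at every timepoint contributes its genes. If none qualifies the
  result is empty.

The number of clusters (2) matches the observed sub-category structure and
is configuration, not a constant; likewise the anchor days.

# qPCR arithmetic

All quantification reduces to `amount = efficiency^(-Ct)` with efficiency
fixed at 2 (perfect doubling) unless overridden. MeRIP enrichment rescales
IP and input amounts to a common RNA mass (defaults 2000 ng IP / 500 ng
input) before their ratio; relative m6A levels divide group mean
enrichment by the unirradiated control's, with a delta-method standard
error. Primer feasibility gates the anti-m6A signal against the IgG
background at a ratio of 4 (inclusive); the background is gated, never
subtracted. SELECT standard curves regress the relative product
$r = 2^{(Ct - Ct_{100\%})}$ on the known m6A fraction — the normalization
written this way is taken verbatim from the assay's description; the
alternative abundance reading $r = 2^{-(Ct - Ct_{100\%})}$ is available as
`mode = "abundance"` and gives the same linear calibration with the
opposite slope sign. Fraction estimates invert the line and are clamped to
$[0, 1]$ with an out-of-range flag.

Group testing is one-way ANOVA followed by Dunnett many-to-one
comparisons. The Dunnett adjustment is computed by Monte Carlo of the null
maximum absolute t statistic — group means $Z_i \sim N(0, 1/n_i)$ sharing
the control $Z_0$, pooled variance $V \sim \chi^2_\nu/\nu$ — which is
exact for arbitrary (unbalanced) group sizes and is cross-checked against
the multivariate-t implementation in the tests. Adjusted p-values are
floored at the raw p-value, so dominance holds even at Monte-Carlo
resolution.

# Dose reconstruction

Calibration is inverse regression: dose on marker, matching how such
models are deployed (an observed level maps to a dose estimate).

* Per-timepoint model: OLS of dose on $(1, m, m^2)$ at a single TPI.
* Integrated model: OLS of dose on the 10 monomials $m^i t^j$, $i+j \le 3$
  — the standard reading of a bivariate cubic; the 16-term tensor basis is
  a configuration option. Rank deficiency (e.g. a single TPI) errors with
  the deficient columns named.
* $R^2 = 1 - SS_{res}/SS_{tot}$ between actual and estimated dose; 95%
  confidence bands come from the least-squares covariance.
* Negative dose estimates are reported as-is with a flag (a clamp option
  exists for triage-style reporting): transparency for calibration audits.

ROC analysis classifies `dose >= cutoff` by the model-predicted dose; the
AUC is the rank (Mann–Whitney) form with half credit for ties, identical
to exhaustive pair counting. Generalization is measured by 100-times
repeated five-fold cross-validation: folds are stratified by
(dose, timepoint) group so every training set spans the design (a fold
that lost an entire dose class would make extreme cutoffs undefined);
per-repetition held-out predictions are pooled into one AUC, and the mean
and sd over repetitions are reported. Stratification by subject is
available where repeated measures share a subject. The repetition stream
is a prefix: increasing `reps` under the same seed reproduces the earlier
repetitions.

On the default synthetic study the cross-validated AUC is strictly lowest
at the 0.2 Gy cutoff — separating 0.2 Gy from sham is the hardest
discrimination, since the expected elevation at 0.2 Gy is comparable to
the measurement noise at off-peak timepoints — and near its maximum at
intermediate cutoffs. The very top cutoff (6.5 Gy) also dips slightly:
there the positive class is only the extreme dose group, and early/late
timepoints compress the separation between the two highest doses. Both
edges of the cutoff range are therefore intrinsically harder than the
middle under this error model.

For parameter-recovery studies, `simulate_calibration_data()` generates
doses from a *known* cubic in $(m, t)$ with unit-mean multiplicative noise
on the response, so re-fitted OLS is unbiased for the planted
coefficients. Perturbing the marker values instead would be an
errors-in-variables design with a different (attenuated) estimand — that
distinction is why the generator noises the dose, not the marker.

# Numerical and testing choices

* OLS is solved by QR; the normal-equation solve appears only as an
  independent oracle in the tests.
* Fuzzy c-means iterates memberships
  $u_{ij} \propto (1/d_{ij}^2)^{1/(m-1)}$ and membership$^m$-weighted
  centroids; the objective is non-increasing and iteration stops on a
  $10^{-10}$ relative objective change. Points coinciding with centroids
  get equal membership over the tied clusters; a fully degenerate input
  (all profiles identical) yields uniform memberships. Hard assignment
  breaks ties toward the lowest cluster index.
* Test problem sizes are the package's own choices balancing resolution
  against runtime: 10,000-gene null and power screens, 200 simulations for
  coefficient bias, 2,000 simulated studies at 2,000 Monte-Carlo draws
  each for the Dunnett calibration, 100×5-fold CV at six cutoffs.
* The pipeline driver (`run_pipeline()`) writes every output as delimited
  text or JSON plus a manifest (package version, seed, configuration and
  its hash); outputs are a pure function of the manifest and re-running it
  reproduces them byte-identically.

# Known limitations

* The generator's response surface is parametric and smooth; real
  temporal responses need not be unimodal in log-time, and real array
  noise is neither homoscedastic in log2 nor gene-independent.
* The screen's operating characteristics are reported under planted
  truth; with correlated genes (co-regulation) the false-discovery
  proportion of the intersection stage would be less favorable.
* Dose models are trained and evaluated within one simulated cohort;
  transfer across cohorts (or species) is out of scope here.
* Hour-scale cell-culture time courses are carried with an explicit time
  unit tag and are never mixed with day-scale in one model fit.
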