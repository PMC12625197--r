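---
title: "Models and design choices in the NPQ panel pipeline"
author: "NPQtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in the NPQ panel pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NPQtools)
```

# Scope

NPQtools analyses targeted plasma proteomic panels delivered in NPQ
units — assay-normalized abundances on a log2 scale, here a ~123
analyte CNS panel — across five diagnostic groups (CO, AD, DLB, FTD,
PD) and AD endophenotypes (amyloid-PET Centiloids, tau-PET SUVR, CSF
Aβ42/Aβ40, CDR). Participant-level data from such studies are
typically request-only, so the package carries a first-class synthetic
cohort generator that reproduces the statistical structure the
analyses assume. This vignette records the models, their assumptions,
and the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

# Quality control

**Outlier masking.** Per analyte, values strictly outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are replaced
with `NA`. Quartiles use linear interpolation between order statistics
(`quantile(type = 7)`, the common statistical-software default); the
convention is recorded in the `QCReport` so fences are reproducible
bit-for-bit. Values exactly on a fence are retained (strict
inequality), so a constant analyte (IQR 0) loses nothing. Analytes
with fewer than 4 observed values have undefined fences and are
flagged rather than masked. Masking precedes call-rate computation.

**Two-step call-rate filter.** Call rate is the proportion of
non-missing measurements per analyte or sample. The filter removes
entities below 65%, recomputes rates on the reduced matrix, then
applies 85%; the recomputation is the point of the two-step design —
it retains borderline analytes/samples whose rates rise once grossly
incomplete rows/columns are gone. Within a step, analytes are filtered
first and sample rates are recomputed on the analyte-reduced matrix
before the sample filter; the source studies do not state an
inner order, so this deterministic choice is fixed here and recorded.
Assay-failed wells and masked outliers are treated identically (both
are `NA`); the distinction is not recoverable from a delivered matrix.

**LOD and CV** are reported, never filtered on. CV is
$100\cdot SD/mean$ over replicate groups on the linear scale. LOD is
`mean + 3·SD` of designated negative-control samples — a working
definition flagged as an assumption in the output, since panels report
LOD without defining it.

# Normalization

The chain is `log2_npq → linear_npq (2^x) → log10 → zscore`, applied
elementwise with missing cells staying missing. The z-score is per
analyte over all retained samples, computed once on the full QCed set
before any per-analysis subsetting, so that effect sizes from
different contrasts share units. The per-analyte means and SDs (and
the chain) are stored in the object's metadata; `zscoreToLinear()`
inverts them, which is how a z-score cutoff is reported as a linear
NPQ value. Backwards single-stage transitions are supported so the
chain is invertible without leaving the class.

# Differential abundance

Per analyte, ordinary least squares of z-scored abundance on the
contrast (disease vs CO; CO is always the reference) or a continuous
phenotype, adjusted for age at draw, sex, and the first two surrogate
variables; complete cases per analyte; two-sided t-test on the
predictor coefficient; BH FDR across the analytes of one contrast
(the analysis family). Cross-sectional analyses use one sample per
participant — the latest draw — matching the convention that group
sizes equal unique-participant counts.

**Surrogate variables.** Missing cells are imputed by sampling
observed values of the same analyte with replacement (seeded); the
primary design is projected out; candidates are the leading left
singular vectors of the residual matrix; one reweighting pass then
re-estimates them from the weighted *centered data*, with analyte
weights favouring residual structure the candidates explain and
discounting analytes driven by the primary design. Re-decomposing the
data rather than the residuals matters: it lets a surrogate variable
retain the component of a batch factor that is correlated with the
design, which is exactly what adjusting for it must remove. The count
is fixed at 2 by the panel design being emulated; the vectors are
orthonormal and deterministic given the seed.

**Open choices.** Phenotype models regress protein (outcome) on
phenotype (predictor) with the same covariates; the alternative
direction is defensible but this one keeps all outputs in abundance
units. CDR enters as a continuous predictor; an ordinal treatment
would need a link choice the emulated analyses do not specify.

# Cross-disease comparison

Effect sizes from two contrasts are compared with
$z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$ and a standard-normal
two-sided p, BH-adjusted across analytes per pair. When both contrasts
share the same control group the two estimates are positively
correlated and this z is conservative; the acceptance calibration
therefore measures type-I error with independent estimates.
Discordance categories follow the usual display convention:
FDR-significant, nominal (p < 0.05 only), or ns.

Clustering of the effect-size matrix uses Euclidean distance and
complete linkage on both axes. Rows/columns are sorted
lexicographically by label before clustering, which makes the result
invariant to input order even under tied merge heights. Trees export
as Newick.

The scorecard assigns, per protein and disease, +2 for a positive
FDR-significant association, +1 for positive nominal-only, −1/−2
mirrored for negative, 0 otherwise (signed two-sided p-values, the
same outputs the DAA stage reports; no re-fitting). The total rewards
consistent cross-disease associations; the absolute total ignores
direction, surfacing proteins with strong but diverging behaviour.
Missing cells score 0 and set a completeness flag.

# Biomarker cutoffs

**Mixture model.** A two-component univariate Gaussian mixture is fit
by EM with a deterministic median-split initialization — values
below/above the median seed the components — so repeated runs are
identical without multi-start. Convergence is a log-likelihood change
below 1e-8 (cap 1000 iterations); the trace is stored and is
nondecreasing by the EM guarantee. A variance floor of 1e-4 times the
total variance averts collapse and is flagged when active. Components
are relabeled so $\mu_1 < \mu_2$. A fit whose mixture density has no
interior dip between the means is reported as degenerate (one mode
split in two): crossing-based cutoffs are not meaningful there.

**Crossing cutoff.** The positivity threshold is the point where a
sample is equally likely to belong to either component:
$\pi_1 N(x;\mu_1,\sigma_1) = \pi_2 N(x;\mu_2,\sigma_2)$, a quadratic
in $x$ for unequal variances; the root inside $(\mu_1, \mu_2)$ is
returned and the posterior there is exactly ½. Extreme weight
imbalance can leave no interior root, which is an error with
diagnostics rather than a silent extrapolation.

**Reference-based cutoffs.** Against a binary reference (amyloid-PET
positivity at > 20 Centiloids), the Youden cutoff maximizes
$J = sens + spec - 1$ over midpoints of adjacent sorted unique values
(ties toward the smallest cutoff, making an exhaustive scan the exact
oracle), and the dual cutoffs are the largest threshold with
sensitivity ≥ 0.95 (lower) and the smallest with specificity ≥ 0.95
(upper). Values between them are "intermediate"; on well-separated
data the zone can collapse (lower ≥ upper), which is flagged, and
unattainable targets fall back to boundary thresholds with a warning.
Percentages are reported to two decimals rounding half away from zero
— the convention that reproduces printed ratios such as 297/325 =
91.38%.

# Evaluation

Confusion summaries satisfy their defining identities exactly on every
input; pairs with a missing or intermediate label are excluded into
`n_excluded`. The ROC AUC is the tie-aware Mann–Whitney statistic;
its variance comes from DeLong placement values and the 95% CI is
clipped to [0, 1]. Logistic predictors are standard IRLS fits whose
fitted probabilities feed the ROC; complete separation is detected
(divergent coefficients or degenerate fitted probabilities after the
glm warning) and raised as an error, never silently returned — except
in fixed-horizon discrimination, where a separating marker still has
well-defined ranking discrimination and the marker itself is ranked,
with the fallback recorded. Kruskal–Wallis uses the tie-corrected H;
Dunn z statistics are computed only for the requested comparisons (AD
vs each other group in the motivating design) and Bonferroni is exact
over exactly those. The APOE-ε4 caller applies the GMM crossing to the
ε4-proteoform analyte; ε4-positive truth is any genotype containing
ε4. Over-representation is the hypergeometric upper tail with fold
enrichment $(k/n)/(K/N)$, BH across pathways; annotation maps are
user-supplied (GMT round-trip supported) — no ontology download or ID
translation.

# Progression

Time-to-event is years from blood draw to AD onset (progressors) or
last follow-up (censored); only baseline-unimpaired participants with
follow-up enter. Cox models per analyte adjust for age at draw and
sex. Ties use **Breslow** — the emulated analyses do not state a
method, so the simplest well-defined choice is taken and recorded in
the output metadata. Monotone likelihoods (infinite HR) are flagged
without an estimate. Group survival uses plain Kaplan–Meier by the GMM
cutoff with a log-rank test; covariate-adjusted survival-curve
estimation is known to exist for this design but the specific
adjustment is not reproducible from the available description, so the
adjusted view is provided by the Cox model instead — a recorded
divergence. Horizon AUCs define non-progressors as followed at least
to the horizon without an event; censored-early records are ambiguous
and excluded.

# The synthetic cohort generator

The generator emulates, on the log2 NPQ scale: per-analyte Gaussian
noise with heteroscedastic SDs drawn log-uniform in [0.2, 1.0] (panels
report abundances on a roughly normal log2 scale but no per-analyte
variances, so this range is a stand-in, exposed in the config);
planted group effects in within-group SD units (defaults shaped after
canonical dementia markers: a p-tau217-like analyte strongly up in AD,
GFAP/NEFL patterns, an Aβ38-like analyte down everywhere); age and
sex slopes; rank-2 latent batch structure; MCAR missingness (2%) with
an optional intensity-dependent mode; outliers displaced by ±(3–6)×IQR
so the QC fence provably catches them; a bimodal biomarker whose
high-component probability tracks diagnosis and whose latent amyloid
variable (Centiloid scale, positivity > 20) has configurable
correlation with it; an ε4-proteoform signal drawn from
genotype-conditional normals (5 SD per ε4 allele) so genotype
concordance is high but imperfect by design; and exponential
proportional-hazards progression times with independent exponential
censoring calibrated to the configured censoring fraction.
Demographics follow the structure of large memory-clinic cohorts
(group mean ages 67–77, female fractions 0.33–0.60, ε4-carrier
frequency ≈ 40%).

What the generator does **not** emulate: assay chemistry and plate
layout, non-Gaussian heavy tails, longitudinal within-person
trajectories (repeated draws are fresh noise around the same biology),
imaging beyond a scalar Centiloid/SUVR analogue, and real LD structure
behind APOE genotypes. Tests passing on synthetic cohorts therefore
demonstrate the *statistical machinery* — estimator correctness,
calibration, recovery of planted structure — not robustness to every
pathology of real plasma data.

# Problem sizes and numerical choices

The test and acceptance simulations use deliberately modest sizes
chosen for stable statistics: null calibration pools 200 cohorts of
5×20 samples × 10 analytes; planted-effect recovery averages 50
cohorts at n_per_group = 200; hazard recovery uses 50 cohorts of
n = 1000 with ~40% events; GMM crossing recovery uses 100 fits at
n = 5000 with clearly separated components (at heavy overlap the
sampling error of the crossing itself exceeds the 0.05 recovery band
for any fitter — verified side by side with an independent mixture
implementation — so the recovery property is only meaningful for
separated modes). EM tolerance is 1e-8 on the log-likelihood; OLS uses
QR with the normal-equations solution as test oracle at 1e-8; Cox
estimation is checked against an independent Newton iteration on the
partial likelihood at 1e-6 on small fixtures. Seeds parameterize every
stochastic path; reruns of a pipeline config are bit-identical on
disk.

# Known limitations

- The scorecard and z-tests reuse DAA outputs; no joint model across
  diseases is fit.
- The SV estimator is a single reweighting pass, not the full
  iterative significance-based dimension selection of larger SVA
  implementations; the SV count is fixed rather than estimated.
- Concordance structure (not exact published values) is what the APOE
  and PET analyses reproduce on synthetic data; the exact published
  percentages are reproducible only as count arithmetic, which the
  evaluation module recomputes.
- No mixed-effects modelling of repeated draws, no competing risks,
  no time-varying covariates.
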