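---
title: "Distribution-centered analysis of adipocyte size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-centered analysis of adipocyte size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipodist)
```

## The problem

Fat-mass expansion in adults is dominated by adipocyte hypertrophy: existing
fat cells enlarge. "Adipocyte size" is, however, not one number. Histology
yields the cross-sectional area (µm²) of cell profiles in a tissue section;
collagenase digestion liberates mature adipocytes, which round up so their
microscope diameter (µm) is the maximal cell diameter. Under the assumption
of spherical cells one measurement determines the rest:

$$d = \sqrt{4A/\pi}, \qquad V = \tfrac{\pi}{6} d^3, \qquad S = 4A,$$

where $A$ is the largest cross-sectional area, $d$ the diameter, $V$ the
volume (we report picolitres, 1 µm³ = 1 fl) and $S$ the surface area of the
sphere. These transformations are nonlinear (except $S$), so they reshape
the *distribution* of sizes within a subject: the square root compresses the
right tail and lowers skewness, the cube sharpens it. By Jensen's
inequality the mean diameter of a sample is **not** the diameter of the mean
area, which is why all conversions here happen at the cell level, and
subject means are taken afterwards.

`adipodist` implements this distribution-centered workflow: per-cell
conversions and artifact filtering, a descriptor panel per subject and for
pooled cohorts, a histology-vs-collagenase method comparison, association
analyses against anthropometry, laboratory values and mitochondrial
respiration, and a calibrated synthetic cohort generator that makes the
whole pipeline testable without patient data.

## Descriptor panel

For a sample of cell sizes the panel reports: n, arithmetic mean, median,
first and ninth decile, interdecile range (IDR = D9 − D1), skewness,
kurtosis, modal size, and a Shapiro–Wilk normality test. Conventions are
fixed so that results are bit-stable across runs:

* **Quantiles** use linear interpolation of order statistics with
  $h = (n-1)p + 1$ (R's type 7, the common statistical-software default).
* **Skewness** is the moment estimator $g_1 = m_3 / m_2^{3/2}$ and
  **kurtosis** the Pearson form $m_4 / m_2^2$ (normal → 3), with
  $m_j = \frac{1}{n}\sum_i (x_i - \bar x)^j$. The Pearson convention is used
  because near-normal collagenase diameter distributions should sit around
  3, which matches how such panels are conventionally tabulated.
* **Mode** is the argmax of a Gaussian kernel density estimate with
  Silverman's rule-of-thumb bandwidth on a 512-point grid over the sample
  range. Modal size has no canonical estimator; the KDE argmax is simple,
  deterministic, and scale-equivariant (mode(c·x) = c·mode(x)), which the
  tests verify.
* **Normality**: `shapiro.test`, defined for 3 ≤ n ≤ 5000. Pooled samples
  above 5000 values are subsampled with the run seed for the test only, and
  the subsampling is reported in a message.

Because skewness and kurtosis are invariant under positive linear maps,
cross-sectional area and surface area (S = 4A) always have identical shape
statistics — a useful internal consistency check that the acceptance suite
exercises.

Degenerate inputs: a zero-variance sample returns `NA` skewness/kurtosis
(rather than an error) and the constant value as mode; n < 3 is an error;
deciles warn below n = 10.

## Sampling and filtering

Histology objects below 200 µm² or above 16,000 µm² are treated as
processing artifacts and removed before any analysis. The retention window
is **inclusive** at both bounds: the exclusion rule removes strictly smaller
and strictly larger objects, so areas of exactly 200 or 16,000 µm² are kept.

Each subject contributes a fixed number of cells to every analysis (default
500 histology areas, 100 collagenase diameters), drawn as a seeded simple
random sample without replacement, so subjects are equally represented in
pooled distributions. Subjects with fewer cells than requested are excluded
— never padded — and named in messages and result objects, because this
attrition changes the analyzable cohort and should be auditable.

## Method comparison

Subject mean diameters from histology and collagenase digestion are
inner-joined on subject (and depot; with pooled depots a subject measured in
both depots contributes two observations, matching how such comparisons are
conventionally pooled). Agreement is summarized by Pearson correlation and
Bland–Altman analysis with the difference fixed as histology −
collagenase; histology reads systematically smaller (section profiles are
chords, not equators), so the expected bias is negative. Limits of agreement
use the standard 1.96 multiplier.

## Associations

* **Correlation matrix**: Pearson r between each subject-mean sizing
  parameter and each continuous phenotype, with pairwise-complete deletion —
  each pair uses all subjects with both values, so per-pair n varies with
  missingness. P values are Bonferroni corrected within the per-depot family
  of all *tested* pairs ($p_{adj} = \min(1, m\,p)$); pairs with fewer than 3
  complete observations are reported as untested and do not inflate m. The
  family size is attached to the result.
* **Adjusted regression**: ordinary least squares of size (or a respiratory
  state) on BMI plus optional covariates; `sex` and `t2d` are coded 0/1 with
  female and non-T2D as reference. Complete cases per model; rank-deficient
  designs error with the collinear columns named.
* **Respirometry**: Pearson r per respiratory state (free OXPHOS, OXPHOS,
  ETS capacity, leak; pmol O₂ s⁻¹ ng DNA⁻¹) and depot against subject mean
  diameter, reported **uncorrected** — the respirometry subset is small and
  each state is a separate a priori question — plus BMI-adjusted regression
  rows when phenotypes are supplied.
* **Cell-count sensitivity**: per subject, the mean of `k_full` sampled
  cells versus the mean of a *nested* random `k_reduced`-subset of those
  same cells, correlated across subjects. Under this nested design the
  expected correlation has the closed form
  $r = \sqrt{(\sigma_b^2 + \sigma_w^2/k_{full})/(\sigma_b^2 +
  \sigma_w^2/k_{red})}$, which the tests use as an oracle.

## The synthetic cohort generator

No individual-level data are deposited for cohorts of this kind, so the
package ships a generator whose defaults emulate the statistical structure
the analyses assume. It is first-class, tested code — not a test fixture.

**Phenotypes.** A Gaussian copula: one latent multivariate-normal vector per
subject, mapped margin-by-margin to truncated normals with the published
mean, SD and observed range (age 48 ± 13 on [18, 78]; BMI 43.6 ± 13.3 on
[18.2, 83.3]; glucose 6.0 ± 3.0; HbA1c 6.0 ± 1.2; total cholesterol
5.1 ± 1.0; LDL 3.1 ± 0.8; HDL 1.3 ± 0.4; triglycerides 1.9 ± 1.0). Because
truncation pulls the mean toward the window center, the location parameter
is recentered numerically (one `uniroot` solve per margin) so the
post-truncation mean equals the target; the SD is left as configured, so
generated SDs sit slightly below the printed values — a deliberate
simplification. Sex (59/188 male) and T2D (prevalence 45/185 among known)
are thresholded latent scores; 3 subjects get `unknown` T2D status.
Missingness is completely at random with per-variable rates chosen to
reproduce the published per-variable sample sizes (e.g. glucose n = 139,
HbA1c n = 99, HDL n = 94); no informative missingness mechanism is claimed.

**Couplings.** Two extra latent variables, one per depot, act as subject
size factors. The copula ties them to BMI at r = 0.47 in both depots and to
glucose (0.26), HbA1c (0.31) and HDL (−0.32) in the visceral depot only;
subcutaneous lab couplings are exactly zero. The matrix is validated
positive semi-definite at construction. Background clinical correlations
(glucose–HbA1c 0.6, cholesterol–LDL 0.85, HDL–triglycerides −0.3, ...) are
plausible values chosen once to make the joint distribution realistic; they
are not fitted to any dataset.

**Cells.** Histology areas per subject are truncated lognormal:
$\log A \sim N(\mu_i, \sigma_w^2)$ with
$\mu_i = \mu_{depot} + \sigma_b z_i$, truncated by rejection to
[200, 16000] µm² so the artifact filter is exercised on in-range data. The
lognormal is the simplest strictly positive right-skewed family; no claim is
made that real adipocyte areas are exactly lognormal. Calibration is solved,
not quoted: $\sigma_w$ from the target per-subject skewness (1.1 sc → 0.35;
1.3 vc → 0.40) via the lognormal skewness identity
$(w+2)\sqrt{w-1},\ w = e^{\sigma^2}$; $\sigma_b$ from the coefficient of
variation of subject mean areas (886.8/3472.0 sc, 863.6/2748.8 vc); the
depot location from the target cohort mean area. Each available subject
receives 550 cells so that 500-cell sampling always succeeds at default
settings. Collagenase diameters are normal within subject (within-SD solved
from the published collagenase IDR under normality, IDR = 2.5631σ), with
subject means linked to the latent size factor at the configured
inter-method r = 0.46 and a systematically larger level (sc 105.6 µm vs the
histology-derived means), so Bland–Altman bias is negative by construction
of the scenario, not of the statistic.

**Respirometry.** Four states per subject × depot from a linear model in the
standardized subject mean diameter plus a shared "mitochondrial quality"
factor (loading 0.6) that correlates the states with each other. Couplings
default to the published subcutaneous values (−0.41 free OXPHOS, −0.53
OXPHOS, −0.59 ETS) and modest negative visceral values (−0.36 OXPHOS from
the published analysis; the remaining visceral couplings are not printed
numerically and are set to plausible negative values). State means and SDs
(e.g. OXPHOS 1.3 ± 0.3 pmol O₂ s⁻¹ ng DNA⁻¹) are **synthetic** plausible
scales: the source respirometry summary statistics are not published, and
correlations are scale-free, so only the couplings matter for the analyses.
The biochemical ordering ETS ≥ OXPHOS ≥ free OXPHOS ≥ 0 and leak ≤ OXPHOS is
enforced by clipping; state levels are separated widely enough that clipping
touches well under 1% of values, and the clipped count is reported.

**Availability.** Subcutaneous histology for 161 of 188 subjects, visceral
for all 188; collagenase for 84 (sc) and 97 (vc); respirometry for 24 (sc)
and 35 (vc). With visceral histology available for everyone, every
sc-measured subject is paired — the generator reproduces the per-depot
counts rather than a separately reported paired count, which those counts
cannot jointly satisfy.

**What the generator does not emulate.** Real histology sections have
section-plane bias (profiles are random chords, so the 2-D area
underestimates the equatorial area in a geometry-dependent way), possible
bimodal small-cell populations, spatial correlation within sections,
batch/staining effects, and informative missingness. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and well calibrated
under the stated model — not that the model captures every feature of real
adipose histology.

## Determinism and problem sizes

Every stochastic step takes an explicit seed, and compound stages derive
sub-seeds from one master seed; identical seed and configuration give
byte-identical outputs, which the tests assert. The test suite runs the
generator at the full default cohort size (188 subjects, ~210,000 cells);
recovery checks average 100 replicate cohorts, and the nested 500/200
subsampling simulation uses 146 subjects × 500 cells × 100 replicates —
sizes chosen to keep Monte-Carlo error well below the tolerances being
asserted while remaining comfortable on a laptop.

## Known limitations

* The spherical model is an idealization; histology cross-sections are not
  guaranteed to be equatorial, so "diameter from histology" is a lower-bound
  style estimate, which is exactly why the method comparison reports a
  negative bias rather than treating one method as truth.
* The descriptor panel assumes unimodality for the mode to be meaningful; no
  dip test or mixture modelling is included (deliberately out of scope).
* Bonferroni is the only multiplicity correction offered, matching the
  analysis this package operationalizes; FDR users should adjust externally.
* The generator's truncated-normal margins reproduce means exactly but SDs
  only approximately (truncation shrinks them); coupling recovery tests use
  sampling-interval tolerances that absorb this.
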