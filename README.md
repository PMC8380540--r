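# adipodist

Distribution-centered analysis of human adipocyte size in R.

## What it is for

Adipocyte (fat cell) size predicts metabolic risk, but "size" is measured in
incompatible ways: histology reports the cross-sectional **area** (µm²) of
cell profiles in a tissue section, while collagenase digestion reports the
**diameter** (µm) of liberated, spherical cells. Under the spherical-cell
model the parameters are linked by

```
d = sqrt(4A/π)        (diameter, µm)
V = (π/6) d³          (volume, reported in pl; 1 µm³ = 1 fl)
S = 4A                (surface area, µm²)
```

but the transformations are nonlinear, so they change the *shape* of the
within-subject size distribution: diameter distributions are less skewed
than area distributions, volume distributions more. A mean or median alone
can therefore misrepresent the cell population, and by Jensen's inequality
the transformed mean is not the mean of the transformed cells.

`adipodist` is aimed at labs analyzing adipocyte morphometry tables. It
provides:

* **geometry** — per-cell spherical conversions, the 200–16,000 µm²
  histology artifact filter (inclusive bounds), and seeded fixed-k cell
  sampling so every subject is equally represented;
* **panel** — a descriptor panel per subject × depot × method and for pooled
  cohorts: mean, median, first/ninth decile, interdecile range (IDR),
  skewness, Pearson kurtosis (normal → 3), KDE modal size, Shapiro–Wilk
  normality, plus density/histogram/QQ tables;
* **method comparison** — Pearson concordance and Bland–Altman agreement
  (bias = histology − collagenase) between subject mean diameters;
* **association** — Bonferroni-corrected Pearson matrices of size vs
  phenotype with pairwise-complete deletion, BMI/sex/T2D-adjusted linear
  regression, respirometry correlations (free OXPHOS, OXPHOS, ETS, leak),
  and the nested 500-vs-200-cell sensitivity analysis;
* **synthcohort** — a seeded Gaussian-copula generator producing a full
  synthetic study (phenotypes, ~210k cells, respirometry) calibrated to
  published cohort statistics, so every stage is testable without patient
  data;
* **io** — CSV readers/writers with validation, `run_pipeline()` to execute
  the whole analysis with one seed, and a thin CLI
  (`inst/cli/adipodist.R`) with `simulate`, `panel`, `compare-methods`,
  `associate`, `sensitivity` and `report` subcommands.

## Worked example

```r
library(adipodist)

cfg    <- synthetic_config()          # defaults calibrated to the cohort tables
cohort <- simulate_cohort(cfg, seed = 1)

# pooled subcutaneous histology areas, 500 cells per subject
pp <- pooled_panel(cohort$cells, "sc", "histology", "area", k = 500, seed = 1)
pp$panel
#>       n mean median   d1   d9  idr skewness kurtosis mode
#>   80500 3460   3139 1793 5535 3742      1.4      6.3 2647
```

The pooled area distribution is right-skewed (skewness 1.4): the mode
(2647 µm²) sits well below mean (3460 µm²), so the most frequent cell is
smaller than the "average" cell. The subject-level cohort mean area is
3460 µm² across 161 sc subjects, matching the generator's calibration target
of 3472 µm² to within sampling error.

```r
# method comparison on subject mean diameters, depots pooled
h <- dplyr::bind_rows(lapply(c("sc", "vc"), function(d)
  subject_mean_sizes(cohort$cells, d, "histology", "diameter", 500, seed = 1)))
co <- dplyr::bind_rows(lapply(c("sc", "vc"), function(d)
  subject_mean_sizes(cohort$cells, d, "collagenase", "diameter", 100, seed = 1)))
paired <- pair_subjects(h, co)
bland_altman(paired)      # bias -41.4 um, LoA [-69.1, -13.6], 168 pairs
method_concordance(paired) # r = 0.50, p = 3.8e-12
```

Histology diameters read ~41 µm smaller than collagenase diameters
(negative Bland–Altman bias: section profiles are chords, not equators),
while the two methods still rank subjects concordantly (r = 0.50).

```r
# visceral mean diameter vs phenotypes, Bonferroni within the depot matrix
vc <- subject_mean_sizes(cohort$cells, "vc", "histology", "diameter", 500, seed = 1)
vc$parameter <- "diameter"
correlation_matrix(vc, cohort$phenotypes)
#>   variable   n estimate        p p_adjusted
#>        bmi 184    0.465  2.9e-11    2.3e-10
#>    glucose 139    0.237  5.0e-03    4.0e-02
#>      hba1c  99    0.343  5.1e-04    4.1e-03
#>        hdl  94   -0.260  1.2e-02    9.2e-02
```

Visceral adipocyte size correlates with BMI, glucose and HbA1c (positively)
and HDL (negatively) at the configured couplings; per-pair `n` varies
because missingness is pairwise-complete, and `p_adjusted` multiplies by the
family of tested pairs.

`run_pipeline(cells, phenotypes, respirometry, run_config(seed = 1,
out_dir = "out"))` executes all stages and writes every table as CSV plus a
checksummed manifest; reruns with the same seed reproduce the checksums.

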