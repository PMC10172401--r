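# placentex

Quantitative analysis of in-vivo placental structure from segmented 3-D
MRI, and the longitudinal statistics used to compare pregnancy cohorts.
The package is aimed at perinatal imaging groups who have anatomic volumes
with binary placental segmentations (NIfTI) plus a per-scan clinical table,
and who want a reproducible path from voxels to cohort-level inference.

## What it computes

**Per scan, 23 features.**

* *Shape (3):* mesh **volume** `V = (1/6) |Σ_T det(v1, v2, v3)|` over a
  closed iso-surface of the mask (cm³); **thickness**, the maximum over
  maternal-surface points of the closest-point distance to the fetal
  surface (cm); **elongation**, the physical length of the longest branch
  of the 3-D medial-axis (curve-thinning) skeleton (cm).
* *Histogram (4):* mean, variance, skewness and kurtosis of the raw
  in-mask gray levels, each normalized by the same statistic over the
  whole image.
* *Gray-level co-occurrence (6):* with `p(i,j)` the level-pair frequency
  at lattice offset `d`, averaged over the 13 unique 3-D directions —
  energy `Σp²`, entropy `−Σ p log₂ p`, inverse difference moment
  `Σ p/(1+(i−j)²)`, contrast `Σ (i−j)² p`, cluster shade and prominence
  (3rd/4th moments of `i+j−μx−μy`).
* *Run length (10):* from run counts `r(i,j)` (gray level `i`, run length
  `j`, `Nr` runs): SRE `Σ r/j²/Nr`, LRE `Σ r j²/Nr`, GLNU, RLNU, and the
  low/high gray-level and short/long-run cross emphases.

**Across scans.** Marginal regression by generalized estimating equations
(Gaussian identity, unstructured working correlation, robust sandwich
covariance; subjects contribute up to two scans) for: cohort comparisons
of every feature adjusting for gestational age and maternal distress, with
least-squares means and Benjamini–Hochberg q-values within each feature
set; a three-step mediation analysis through the PSS/EPDS/SSAI/STAI
distress scores (high distress = any score strictly above 40/40/15/10);
birth-weight association models by cohort; sensitivity analyses; and time
trends (per-cohort slopes plus a quadratic-spline mixed model with a knot
at the pandemic onset).

Because no public imaging cohort accompanies the method, a first-class
synthetic-data module (`synth_config()`, `generate_cohort()`,
`placenta_phantom()`) generates placenta-like labeled volumes and
longitudinal cohort tables with known ground truth, which is how the
pipeline is validated end to end.

## Worked example

```r
library(placentex)
set.seed(1)

# one synthetic scan: deformed-ellipsoid mask + textured interior
ph <- placenta_phantom(c(45, 33, 12), spacing_mm = c(1.64, 1.64, 4),
                       corr_length_mm = 3, gamma = 0.5)
fv <- extract_features(ph$image, ph$mask)
round(fv[1:7], 3)
#>    volume_cm3  thickness_cm elongation_cm       mean_gl   variance_gl
#>        73.741         2.400         3.272         1.974         0.614
#>   kurtosis_gl   skewness_gl
#>         0.928         0.755

# a 228-subject synthetic cohort with the default injected pandemic shifts
tab <- generate_cohort(synth_config(n_subjects = 228, seed = 1))
cmp <- cohort_comparison(tab, features = c("volume_cm3", "thickness_cm",
                                           "elongation_cm"))
cmp[cmp$model == "distress_adjusted",
    c("feature", "ls_mean_pre", "ls_mean_pandemic", "beta",
      "ci_lower", "ci_upper", "p", "q")]
#>        feature ls_mean_pre ls_mean_pandemic   beta ci_lower ci_upper        p        q
#>     volume_cm3      590.49           643.01 52.521   29.786   75.257 5.96e-06 1.79e-05
#>   thickness_cm        4.93             5.19  0.261    0.139    0.382 2.60e-05 3.91e-05
#>  elongation_cm       17.71            17.18 -0.533   -0.890   -0.177 3.33e-03 3.33e-03
```

The table reads like the cohort-comparison tables of a placental MRI
study: adjusted group means (pre-pandemic vs pandemic), the cohort
coefficient β in feature units, its robust 95% CI, and p/q values. Here
the generator injected +44.32 cm³ volume and +0.38 cm thickness shifts;
the fitted βs recover them within sampling error at n = 228.

A full run (synthesize → extract → compare/mediate/birth-weight/trend)
is one call:

```r
cfg <- run_config(out_dir = "demo_out",
                  synth = synth_config(n_subjects = 40, size_scale = 0.35,
                                       voxel_spacing_mm = c(3, 3, 3),
                                       seed = 42),
                  seed = 42)
run_pipeline(cfg)
```

which writes `features.csv`, `comparison.csv`, `mediation.json`,
`birthweight.csv`, the time-trend tables and a checksummed
`manifest.json`. `inst/scripts/run_pipeline.R` wraps the same call for
shell use with a YAML config.

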