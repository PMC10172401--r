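---
title: "Placental morphometry and texture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placental morphometry and texture: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentex)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the measurement model for the 23
per-scan features, the statistical models fitted across scans, the
synthetic-data generator that stands in for clinical data, and the
numerical choices made where the underlying methodology leaves the design
open.

## The measurement model

A scan is a pair: a 3-D gray-level volume with anisotropic voxel spacing
(clinical default 1.64 × 1.64 mm in plane, 4 mm slices) and a binary
placental segmentation of the same geometry. All texture computations run
on the voxel lattice; physical spacing enters only where lengths and
volumes are reported, so shape features are in cm/cm³ and are invariant
to axis permutations and flips of the array.

### Shape features

**Volume.** The mask is converted to a closed triangular iso-surface at
level 0.5 and the volume is the divergence-theorem sum
$V = \tfrac{1}{6}\left|\sum_T \det(v_1, v_2, v_3)\right|$. Surface
extraction uses marching tetrahedra on the Kuhn (six-simplex)
decomposition of each voxel cell. The Kuhn decomposition is
translation-invariant and face-to-face consistent between neighboring
cells, which guarantees a watertight surface without a 256-case lookup
table; with binary input the iso-vertices are lattice edge midpoints.
Each triangle is wound so its normal points away from the interior corner
of its generating tetrahedron, making the signed volume positive by
construction. On a digitized 10³-voxel cube the mesh volume is within 1%
of 1000 mm³; on a digitized (50, 40, 20) mm ellipsoid it is within 0.1%
of $\tfrac{4}{3}\pi abc$.

**Thickness.** The vertex cloud is split by the sign of its projection on
the smallest principal axis — for a disc-like placenta, the flat axis —
into two caps (a band of configurable half-width around the splitting
plane, default 10% of the maximal projection, is labeled *rim*). One cap
is called maternal, the other fetal; the assignment is geometric, not
anatomical, because nothing intrinsic to a binary mask identifies the
uterine side. An explicit user labeling always overrides the heuristic,
and `flip` swaps the caps. Thickness is then the maximum over maternal
vertices of the exact point-to-triangle distance to the fetal sub-mesh.
"Projection onto the fetal surface" is interpreted as closest-point
projection: it is well defined for non-parallel surfaces and reduces to
the perpendicular separation for parallel plates (a 20 mm slab measures
exactly 2.0 cm).

**Elongation.** The mask is thinned to a curve skeleton by sequential
simple-point removal: six directional border passes per iteration, where
a voxel is deletable when its removal preserves both the object's local
26-connectivity and the background's 6-connectivity, endpoint status is
frozen at the start of each pass, and simplicity is re-checked at
deletion time. This is the behavior class of the standard 3-D
medial-axis thinning used across the imaging ecosystem, including its
known order sensitivity on thin digitized rods and plates (a 1-voxel
plate can erode completely; blob-like placental masks thin to a stable
medial curve). The skeleton becomes a weighted graph (nodes at voxel
centers, 26-neighbor edges weighted by physical length) and elongation is
the longest endpoint-to-endpoint geodesic, in cm. Whether "longest
branch" means that geodesic or the longest single segment after junction
decomposition is ambiguous; both are implemented (`method = "geodesic"`
is the default, `"branch"` the alternative) and on branchless skeletons
they coincide. Thinning runs on the native lattice by default, mirroring
native-resolution processing of clinical data; strong slice anisotropy
biases lattice thinning, so an optional nearest-neighbor
resample-to-isotropic flag is provided (default off).

### Histogram features

The first feature set is the mean, variance, skewness (standardized third
moment) and kurtosis (standardized fourth moment, not excess) of the raw
in-mask intensities, each divided by the same statistic over all finite
voxels of the whole image. Raw intensities are used rather than quantized
levels because the features are ratios of intensity statistics and
quantization would distort them. The whole-image reference includes
background air: whether the original analyses excluded it is not
recoverable, and including all finite voxels is the reproducible choice.
Degenerate cases are explicit: a constant region reports variance ratio 0
and zeroed, flagged skewness/kurtosis; a near-zero whole-image
denominator (|denominator| < 1e-12) yields the unnormalized region
statistic plus a flag.

### Co-occurrence and run-length features

Gray levels are quantized to `Ng` equal-width bins between the minimum
and maximum of the masked region (top edge inclusive). `Ng = 32` by
default: the bin count used in the original placental work is unstated,
and 32 is the common radiomics compromise between level resolution and
matrix sparsity; it is configurable and recorded in the output
provenance. Quantization over the whole-image range is available as a
scope switch.

Co-occurrence matrices are accumulated per direction over the 13 unique
3-D lattice directions at distance 1, with symmetric accumulation (the
transpose added), each matrix normalized to sum 1. Directions producing
no in-mask pair are dropped from the average with a warning. Features are
computed per direction and then averaged unweighted (feature-then-
average), matching the convention of averaging each feature over all
directions; matrix indices run 1..Ng so the inverse gray-level weights of
the run-length features are finite. Entropy uses log base 2 — consistent
with reported placental entropies around 8.4 at up to 256 levels — and
the base is configurable and recorded. A 2-D in-plane mode (4 directions
per slice) exists because 4 mm slices make through-plane co-occurrence
questionable; 3-D is the default.

Run-length matrices decompose the lattice into maximal 1-D lines per
direction; a run is a maximal same-level streak lying entirely inside the
mask, and mask gaps terminate runs (only placental tissue is measured —
no bridging across excluded voxels). The conservation identity
$\sum_{i,j} j\,R(i,j) = N_p$ (masked voxel count) holds per direction and
is asserted on every fixture in the test suite. Every co-occurrence and
run-length feature is also checked against independent brute-force
enumeration oracles to 1e-10 on one hundred random masked arrays.

## The statistical models

All cohort inference uses generalized estimating equations for Gaussian
outcomes with identity link: subjects are clusters (one or two scans),
the working correlation is unstructured by default (with up to two scans
it has a single free parameter), and inference uses the robust sandwich
covariance. The solver is iterated generalized least squares with
moment-based correlation estimates; if the unstructured estimate is not a
valid correlation matrix the fit falls back to exchangeable with a logged
warning (this legitimately happens when the outcome is constant within
subjects, e.g. birth weight). With all clusters of size one the estimator
reproduces ordinary least squares to machine precision, which the tests
assert, and on clustered data the coefficients match an independent GEE
implementation to 1e-6. Confidence intervals are normal-theory
$\beta \pm 1.96\,SE$. Least-squares means are model predictions per
cohort with every other design column at its grand mean over the rows
used; their difference equals the cohort coefficient exactly.

**Cohort comparison.** Per feature: `feature ~ cohort + GA` and the
distress-adjusted variant adding the binary high-distress indicator.
Benjamini–Hochberg q-values are computed within each feature set (3
shape, 4 histogram, 6 co-occurrence, 10 run-length) separately, following
the per-set multiplicity convention; the BH step-up is implemented
directly and tested against a min-over-suffix oracle.

**High distress** is 1 when any available score strictly exceeds its
instrument threshold (SSAI 40, STAI 40, PSS 15, EPDS 10), 0 when all
available scores are at or below threshold, missing only when all four
are missing. Equality does not flag (the definition is "greater than").
With partially missing questionnaires the any-available disjunction is
retained, because per-instrument Ns legitimately differ; a strict
complete-case mode is a switch.

**Mediation** follows the three-step logic: (1) feature on cohort + GA;
(2) each distress measure on cohort + GA; (3) feature on cohort + GA +
each step-2-significant measure, one at a time. `significance_altered`
operationalizes "the significance was altered" as the cohort p-value
crossing α = 0.05 between steps 1 and 3, in either direction; the
threshold is configurable, and β attenuation is reported alongside so
users can apply a magnitude criterion instead. When step 2 finds no
mediator, step 3 is skipped and noted.

**Birth weight.** Within each cohort separately,
`birth_weight ~ feature + GA_at_MRI + high_distress + GA_at_birth`.
Covariates that are constant within a cohort (under the default generator
no pre-pandemic subject crosses a distress threshold) are dropped with a
warning rather than producing a singular design; cohorts with fewer than
10 usable subjects are skipped.

**Time trends.** Per cohort, `feature ~ days + GA` with days since the
earliest scan (scale-free for slopes and splines); cohorts with fewer
than 3 distinct dates are skipped. The combined model is a quadratic
spline in date — continuous with continuous first derivative, basis
$(t, t^2, (t-k)_+^2)$ — with a subject random intercept fitted via lme4.
The knot count and placement are not prescribed anywhere, so a single
interior knot sits at the pandemic declaration date (2020-03-11) by
default and is configurable. The reported `net_change` (fitted value at
the last date minus the first, at the mean GA) summarizes the spline's
direction and matches the sign of injected step changes in simulation.

Missing data are handled by listwise deletion per model with the per-model
N reported; no imputation.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed to the published cohort design and are
not tuning knobs.

* **Design:** 228 subjects, 27.6% pandemic-era, 56% scanned twice with
  strictly increasing gestational ages in 17–39 weeks; pre-pandemic scan
  dates uniform over Mar 2014–Feb 2020, pandemic dates uniform over
  Jun 2020–Apr 2021, with a subject's second scan date consistent with
  its GA gap. Subjects never mix cohorts.
* **Distress:** per-questionnaire normals (subject random effect + scan
  noise, ICC ≈ 0.64) truncated to instrument ranges by rejection;
  truncation and integer rounding slightly shrink realized group
  differences. Pre-pandemic means are the published adjusted means and
  the pandemic means add the published cohort contrasts (+1.15 SSAI,
  +1.76 STAI, +3.23 PSS, +1.54 EPDS). The printed dispersions are
  adjusted-mean SEs, which the generator deliberately reuses as
  per-subject SDs — a high signal-to-noise regime that reproduces the
  published significance pattern at the published sample size.
* **Features:** each of the 23 features is baseline + GA trend + subject
  effect + scan noise + the configured pandemic shift. Baselines are the
  published pre-pandemic adjusted means; the injected shifts default to
  the published cohort contrasts (e.g. +44.32 cm³ volume, +0.38 cm
  thickness, −0.58 cm elongation). Per-cohort feature variances are not
  published, so the per-scan SD is set once to twice the printed
  pre-pandemic SE, split 81/19 (variance) between subject and scan
  components — chosen so the injected effects are detectable at the study
  scale, and stated here rather than calibrated to anything. Effect
  routing has three modes: `direct` (features shift with cohort;
  distress also shifts), `full` (the entire feature shift is carried by
  the PSS score, pandemic → distress → feature, no direct path — the
  fully mediated world), and `none` (the null generator).
* **Birth weight** is linear in the subject's last measured volume and
  elongation with cohort-specific slopes (0.73 vs 2.30 g/cm³, 4.19 vs
  7.77 g/mm), plus a GA-at-birth term and noise. Linking to the last
  scan reflects that near-term placental size predicts birth size and
  makes slope recovery exact in single-scan designs; in mixed designs the
  GEE estimate mixes between- and within-subject information and
  attenuates toward the within-subject null, which is a property of the
  estimand, not a bug.
* **Images:** `placenta_phantom()` builds an ellipsoid with a gentle
  volume-preserving bend along its major axis (a z-shear, so the analytic
  volume $\tfrac{4}{3}\pi abc$ and slab thickness 2c are exact and the
  true elongation is the centerline arc length). Semi-axes are solved
  from the same volume/thickness/elongation growth curves used for the
  cohort table. Interior texture is white Gaussian noise smoothed to a
  configurable correlation length ℓ and passed through the monotone
  transform $g(z) = (e^{\gamma z}-1)/\gamma$, so run-length structure (ℓ)
  and histogram skewness (γ) are independently steerable; the background
  carries a dimmer noise floor so whole-image normalization is
  meaningful. Increasing ℓ measurably increases long-run emphasis and
  decreases short-run emphasis, which the tests verify over seed batches.

What the generator does *not* emulate: cotyledon and vascular anatomy,
maternal/fetal tissue outside the placenta, motion artifacts, scanner
inhomogeneity, or item-level questionnaires (scores are generated at the
summary level, which is the level the analyses consume). Passing tests
therefore demonstrate correctness of the measurement and inference code
under a controlled model of the data, not clinical validity on real
images.

## Validation scale and determinism

The simulation-based checks run at n = 400 subjects with 100–500
replicates (CI coverage 200, type-I error 500, mediation 100 per mode)
and the imaging checks use phantoms from ~20³ up to ~110×90×50 voxels;
these sizes give stable Monte-Carlo estimates while keeping the full
suite in a few minutes. Everything is seeded: identical config + seed
yields byte-identical cohort tables, images, result CSVs and manifest
(the manifest stores config digest, seed, version and output checksums,
and no timestamps).

## Known limitations

* Surface labeling is geometric; on nearly spherical masks the principal
  axes degenerate (a warning is raised) and the maternal/fetal assignment
  is arbitrary unless supplied.
* Curve thinning is order-sensitive on thin digitized rods/plates, as is
  the standard algorithm family; elongation of structures ≤2 voxels thick
  after anisotropy is unreliable (the resample flag mitigates this).
* The GEE engine implements the Gaussian-identity case only — sufficient
  for every model here, not a general GEE replacement.
* Spline p-values use the normal approximation to the Wald statistic;
  with many small clusters this is mildly liberal.
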