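---
title: "Fat-omics methods: EAT quantification and survival modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fat-omics methods: EAT quantification and survival modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the conventions behind the 148-feature catalogue, the tunable parameters,
the synthetic ground-truth generators, the numerical choices made where a
definition was genuinely open, and what the tests do and do not establish
about real data.

## Scope and assumptions

The package starts from a non-contrast cardiac CT volume and a co-registered
binary pericardium ("sac") mask on the same lattice. Segmentation itself is
out of scope: the sac mask is an input, and the EAT mask is either supplied
or derived by thresholding within the sac. Grids must be congruent (exact
shape match, spacing within 10⁻³ mm); resampling and registration are user
responsibilities, and a mismatch is treated as an error rather than silently
fixed. Volumes are reoriented on load (where the NIfTI header permits) so
the third axis is axial with slice index increasing toward the head; all
physical quantities are computed in millimetres from the header spacing,
never in voxel indices — at a typical calcium-score lattice
(0.5 × 0.5 × 2.5 mm) an index-space computation would distort distances
along z by a factor of five.

EAT is defined as sac voxels with attenuation in a closed fat window,
default **[−190, −30] HU** — the span tiled exactly by the intensity bins
below. HU values are used as stored; NIfTI carries calibrated values.

## The thickness field

The package's central feature family is a dense angular map of EAT
thickness. From the sac centroid, one ray is cast per direction on a full
spherical sweep: azimuth θ ∈ {0°, …, 359°} in the XY-plane and polar angle
φ ∈ {0°, …, 179°} from +z, at a 1° step — 360 × 180 = **64,800 rays**. The
polar convention gives exactly that count while covering the sphere.

Each ray is sampled at a fixed arc step of 0.25 × min(spacing) (0.125 mm at
the default lattice); each sample is attributed to its nearest voxel. The
ray terminates at the first sample outside the sac (or the grid). Its
thickness is the Euclidean distance in mm between the first and the last
sample whose voxel is EAT — zero if the ray meets no fat. Two conventions
are deliberate:

* **Gaps are spanned.** If myocardium interrupts the fat along a ray, the
  first-to-last reading includes the gap. This is the literal reading of a
  "first to last intersected fat voxel" distance and is monotone under
  shell thickening.
* **Zero rays are kept.** Rays that meet no fat stay in the field, so the
  count is always 64,800 and the histogram denominators are comparable
  across subjects. `summarize_thickness(include_zeros = FALSE)` provides
  the alternative; nothing downstream assumes either choice.

The sub-voxel sampling step bounds the chance of stepping across a thin
shell without registering it; halving the step changes no ray by more than
a voxel diagonal (tested). On an analytic 6 mm spherical shell at the
default lattice, every ray is recovered within one voxel diagonal
(≈ 2.6 mm — the z spacing dominates) and the field mean within one voxel.

Summary features use all 64,800 values: mean, max, median, standard
deviation, skewness and *excess* kurtosis (normal → 0), plus counts and
fractions in four fixed 8 mm bins [0,8), [8,16), [16,24), [24,32] mm.
Values above 32 mm are folded into the last bin and counted separately.
A constant field reports skewness and kurtosis of 0 rather than NaN, so
degenerate phantoms cannot poison a feature table.

## Subregion partitions

**Axial slabs.** The slices containing sac foreground are split into four
consecutive runs of near-equal count, labelled PQ1 (lowermost) to PQ4
(uppermost). When the slice count is not divisible by four, the extra
slices go to the *lower* slabs (10 slices → 3, 3, 2, 2): any fixed
remainder rule works, and this one is deterministic and mirror-symmetric
under a z-flip with a PQ1↔PQ4 relabelling (tested as an invariant).

**Equidistant shells.** For every sac voxel the Euclidean distance *d* to
the sac exterior is computed with an exact separable distance transform
that respects anisotropic spacing (implemented in C++; validated against
hand-computable cases and analytic sphere bands). With D = max *d*, shell
k collects voxels with d ∈ ((k−1)·D/4, k·D/4], SH1 outermost; a voxel
exactly on a band edge goes to the outer shell. Bands have equal *depth*,
not equal volume — they are the "equidistant ribbons" of the design. The
shells are defined on the sac and intersected with EAT afterwards, so band
geometry does not depend on how sparse the fat is. On a 40 mm sphere the
band volumes agree with the closed-form spherical-band volumes to a few
percent (surface-voxel effects); refining the grid 2× moves band volumes by
about 1% (the test asserts < 2%).

Both partitions are exact set partitions of their parent mask, asserted at
voxel-count level.

## Intensity features

HU moments over a region report min, max, mean, population standard
deviation, **negative skewness** (−m₃/m₂^1.5 — positive when attenuation
piles toward the high, inflammation-associated end), and excess kurtosis.
The fixed bins tile [−190, −30]: eight 20 HU bins (`Vol_190_170` …
`Vol_50_30`) and four 40 HU bins (`Vol4_*`), each with a probability
version normalized by the in-span region volume, so probabilities sum to 1
whenever the region lies inside the span (with the default fat window,
always). Bins are right-open except the last ([−50, −30] closed at −30),
which tiles the span without double counting. Out-of-span voxels are
excluded from bins but reported, and conservation (Σ bins + out-of-span =
region) is exact in voxel counts.

The 4-bin span and widths mirror the 8-bin set symmetrically; that reading
is an inference (the bin count pair is fixed, the 4-bin edges are not
printed anywhere authoritative) and is recorded here as such.

## The 148-feature catalogue

The catalogue is a reconstruction constrained to (a) include every feature
name analyzed downstream (`EAT_vol`, `EAT_mean_HU`, `Thickness_Max`,
`Vol_PQ4`, `Vol_50_30`, `Pro_50_30`, `Thickness_Kurtosis`, …), (b) follow
the three feature categories and the slab/shell/bin structures, and (c)
total exactly 148:

| group | count | contents |
|---|---|---|
| global morphology | 8 | EAT/sac volumes, EAT fraction, 3 principal-axis extents, 2 aspect ratios |
| thickness | 14 | 6 moments + 4 bin counts + 4 bin fractions |
| global intensity | 30 | 6 moments + 8+8 bin volumes/probabilities + 4+4 coarse bins |
| subregion | 96 | 12 features × {PQ1..PQ4, SH1..SH4}: volume, volume fraction, 6 HU moments, 4 coarse bin volumes |

`feature_dictionary()` is the single machine-readable source of truth
(name, category, group, units, definition); extraction asserts its output
matches the dictionary exactly. Volumes are in cm³, thicknesses in mm, HU
dimensionless. Degenerate regions (empty EAT, a fat-free shell) produce
zeros with a per-feature missingness flag exported alongside the table —
penalized Cox cannot ingest NaN, zeros are the least-informative
imputation, and the flags preserve auditability.

Principal-axis length is the projection extent (max − min) of foreground
voxel centres on each covariance eigenvector: parameter-free and directly
comparable to physical heart dimensions, unlike eigenvalue multiples which
require a distributional assumption.

## Feature reduction and the survival model

**mRMR.** Survival data has no single obvious mRMR target; the package
supervises on the binary event indicator, with one-way ANOVA F as
relevance and mean |Pearson correlation| with the selected set as
redundancy, combined as the FCQ quotient. This is the most common
adaptation; the time component re-enters in the Cox stage.

**Cox elastic net.** Features are standardized inside the fit (the scaler
is stored and reapplied at prediction; test-set risk always uses the
training standardization). Mixing parameter α = 0.8 — mostly lasso with a
ridge stabilizer for correlated features — and λ chosen by 10-fold
cross-validated partial likelihood. A target support size can be requested
instead, picking the path λ whose support is closest. ln-transforms of
volume features are a modeling option (`ln_volumes`), not an extraction
behaviour: the feature table always stores raw values.

**Evaluation.**
* Harrell's C over event-anchored pairs, risk ties 0.5 — matched exactly
  against a brute-force all-pairs oracle in the tests.
* AIC on an *unpenalized* refit of the selected support (AIC is undefined
  for penalized partial likelihood; the refit is the standard workaround).
* Cumulative/dynamic AUC(t) with inverse-probability-of-censoring weights
  from a Kaplan–Meier estimate of the censoring distribution; with no
  censoring before t it reduces to the binary Mann–Whitney AUC (tested).
* Categorical NRI at a horizon, two categories split at each model's own
  median; event proportions within movement groups are KM-adjusted so
  subjects censored before the horizon contribute through the weighting
  instead of being dropped (naive exclusion biases NRI). CI and p come
  from a seeded subject-level bootstrap with medians recomputed per
  resample.
* KM median-split stratification with log-rank p, a univariate Cox
  hazard ratio on the group indicator, and restricted-mean survival.
* Likelihood-ratio tests only produce a χ² p-value for nested models;
  non-nested comparisons return the log partial-likelihood difference with
  a warning rather than an invalid calibration.

The pipeline splits subjects 80/20, stratified by event indicator, before
selection and fitting; all selection happens on the training split.

## Synthetic ground truth

`make_shell_phantom()` voxelises an ellipsoidal sac with a fat shell of
known angular thickness onto an anisotropic lattice (default 0.5 × 0.5 mm
in-plane, 2.5 mm slices — the calcium-score acquisition geometry), fat HU
drawn from a truncated normal (default mean −100, sd 25) inside the fat
window, interior at 40 HU, background at −1000 HU. A voxel belongs to a
region iff its centre does, which makes voxel-count truths exact by
construction. The truth record carries the analytic shell volume (spherical
constant-thickness case), the designed per-angle thickness on the 1° sweep
grid, and the drawn HU moments. `simulate_survival()` uses an exponential
baseline hazard (default median ≈ 600 days) with uniform censoring on
[0, 6 years] — the simplest generative model sufficient for
parameter-recovery tests; a real cohort provides no generative model to
copy. All randomness flows from explicit integer seeds.

What the phantoms do *not* emulate: cardiac anatomy and the true sparse,
lobulated spatial texture of EAT, partial-volume effects, scanner noise
spectra, motion. Passing the analytic-phantom suite therefore establishes
the correctness of the geometry, counting and modeling machinery — not
clinical performance, which requires real cohorts.

## Numerical choices and problem sizes

* Moments use population formulas (m₂, m₃/m₂^1.5, m₄/m₂²−3) with the
  zero-variance convention (skewness = kurtosis = 0 for constant samples).
* Ray sampling at 0.25 × min(spacing); voxel membership by nearest-voxel
  lookup; band/bin boundary ties always go to the outer/lower member so
  partitions are deterministic.
* Test fixtures: 176 × 176 × 40 sphere phantoms at the default lattice for
  thickness recovery (built once per session and cached); a 134 × 134 × 56
  ellipsoid for axis recovery; pipeline smoke tests run 10 phantom
  subjects on a coarser lattice. Statistical suites use n = 500 × 20 seeds
  (support recovery), 200 simulations (LRT calibration), and n = 2000
  (null AUC). The full suite runs in under a minute on one CPU; the
  acceptance script in well under a minute.

## Known limitations

* The catalogue enumeration beyond the named headline features is a
  symmetric reconstruction; other fillings of the same category structure
  are possible.
* mRMR supervision on the event indicator ignores time-to-event ordering.
* The NRI p-value is a normal approximation on the bootstrap SE.
* Shell bands inherit a ~1% grid-dependence from the distance transform at
  clinical resolutions.
* `read_volume()` honours complete orientation headers; exotic oblique
  acquisitions should be reoriented upstream.
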