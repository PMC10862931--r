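# fatomics

Quantitative "fat-omics" analysis of epicardial adipose tissue (EAT) in
non-contrast cardiac CT, with downstream time-to-event risk modeling.

EAT — the fat enclosed by the pericardial sac — is metabolically active and
in direct vascular communication with the myocardium and coronary arteries;
inflamed fat shows elevated attenuation (toward −30 HU), and its amount,
placement and thickness have all been linked to major adverse cardiovascular
events (MACE). Simple summaries (total EAT volume, mean HU, one thickness
measurement) discard most of that signal. This package computes a
148-feature catalogue from a CT volume and a pericardium ("sac")
segmentation, and models time-to-event outcomes from it:

* **Morphology** — EAT and sac volumes, EAT fraction, and the principal
  axes of the sac (extent along the eigenvectors of the voxel-coordinate
  covariance), with aspect ratios.
* **Thickness field** — rays are cast from the sac centroid over the full
  sphere at 1° steps (360 azimuth × 180 polar = 64,800 directions); each
  ray's EAT thickness is the Euclidean distance between the first and last
  fat voxel it crosses. The field's moments and fixed 8 mm histogram bins
  become features.
* **Intensity** — HU moments over EAT (including *negative skewness*, which
  is positive when attenuation piles up toward the inflamed end of the fat
  window), plus volumes and probabilities in fixed 20 HU and 40 HU bins
  tiling [−190, −30] (e.g. `Vol_50_30`, the EAT volume with HU in
  [−50, −30]).
* **Spatial distribution** — the sac is cut into four equal-thickness axial
  slabs (`PQ1` bottom … `PQ4` top) and four equidistant shells from the
  pericardial surface inward (`SH1` … `SH4`, via an anisotropy-aware
  Euclidean distance transform); per-subregion volume and HU features.

Feature reduction and modeling follow the standard penalized-survival
stack: greedy mRMR (F-statistic relevance / mean-|correlation| redundancy
quotient) down to 50 features, then a Cox proportional-hazards elastic net
(mixing α = 0.8, λ by 10-fold cross-validated partial likelihood):

    h(t | x) = h0(t) · exp(xᵀβ),   β̂ = argmax PL(β) − λ [α‖β‖₁ + (1−α)‖β‖₂²/2]

Evaluation: Harrell's C-index, AIC of an unpenalized refit, per-feature
hazard ratios, IPCW time-dependent AUC(t), likelihood-ratio tests between
nested models, categorical net reclassification improvement (NRI) with a
Kaplan–Meier correction for censoring, and KM median-split stratification
with log-rank test and between-group hazard ratio.

Because clinical CT cohorts cannot be shipped, the package includes a
first-class synthetic module: ellipsoidal shell phantoms with known
geometry and fat-HU distribution on an anisotropic CT lattice
(0.5 × 0.5 mm in-plane, 2.5 mm slices by default), and an exponential
proportional-hazards survival simulator with recorded ground truth. Every
stage is tested against analytic values or brute-force oracles on these.

## Worked example

Build a phantom with a known 6 mm fat shell inside a spherical sac, extract
the catalogue, and inspect the headline features:

```r
library(fatomics)

ph <- make_shell_phantom(phantom_spec(seed = 7))   # CTCS-like lattice
fv <- extract_features(ph$ct, ph$sac, ph$eat, subject_id = "phantom-01")
round(fv[c("EAT_vol", "Sac_vol", "EAT_mean_HU", "Thickness_Mean",
           "Thickness_Max", "Thickness_Kurtosis", "Vol_PQ4",
           "Vol_50_30", "Pro_50_30", "Axis_Major")], 3)
#>            EAT_vol            Sac_vol        EAT_mean_HU     Thickness_Mean
#>             71.835            162.420           -100.171              5.884
#>      Thickness_Max Thickness_Kurtosis            Vol_PQ4          Vol_50_30
#>              7.875             -0.185             17.030              1.483
#>          Pro_50_30         Axis_Major
#>              0.021             75.500
ph$truth$fat_volume_mm3 / 1000   # generator ground truth, cm^3
#> [1] 71.835
```

`EAT_vol` reproduces the generator's ground truth exactly (both count
voxels); `Thickness_Mean` recovers the designed 6 mm shell to within the
voxel diagonal; the fat HU was drawn around −100 HU, so `EAT_mean_HU`
lands there and only ~2% of the volume sits in the high-attenuation
[−50, −30] bin (`Pro_50_30`).

Modeling on simulated survival data with two informative features:

```r
so  <- simulate_survival(simsurv_spec(n = 300, p = 50,
                                      beta = c(f1 = 1, f2 = 1), seed = 1))
sel <- mrmr_select(so$features, so$surv$event, k = 20)
m   <- fit_cox_elasticnet(so$features[, sel], so$surv, alpha = 0.8, seed = 2)
m
#> <cox_model> alpha = 0.80, lambda = 0.04024, 10/20 features selected
#>      f2      f1     f35     f30     f48     f14     f21     f41     f46     f42
#>  0.8257  0.7969  0.0957  0.0707  0.0385  0.0088 -0.0136 -0.0233 -0.1481 -0.1699

r <- predict(m, so$features[, sel])
concordance_index(r, so$surv)        #> 0.784
auc_at_time(r, so$surv, 730)         #> 0.862
km_stratify(r, so$surv)$hr           #> 5.42  (median-split hazard ratio)
```

The two true coefficients (simulated at β = 1) dominate the fitted support.

The full pipeline (phantom batch or CSV inputs → features → mRMR → elastic
net → evaluation report, with a reproducibility manifest) is available as
`run_pipeline(config, out_dir)` or from the shell:

```sh
Rscript inst/cli/fatomics.R run --config config.yaml --out results/
Rscript inst/cli/fatomics.R extract --ct ct.nii.gz --sac sac.nii.gz --out features.csv
```

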