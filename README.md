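# mprad

Multiparametric radiomics for co-registered radiological image volumes.

Conventional radiomics computes texture features from one image at a
time — a single MRI sequence, CT, or PET volume — and combines the
per-image features afterwards. When the data are intrinsically
multiparametric (e.g. breast mpMRI with T1, T2, diffusion/ADC and DCE
series), per-image analysis cannot see how the channels co-vary at each
voxel. `mprad` instead builds every feature on the **tissue signature**

```
S_p = [ I_p^(1), I_p^(2), ..., I_p^(N) ]^T
```

the vector of intensities voxel *p* takes across all N co-registered
channels, and quantifies texture jointly over all channels.

## Feature families

| Family | What it measures |
|---|---|
| **TSPM** | Joint probability matrix of quantized signatures over a ROI: joint entropy `H = -Σ p log2 p`, uniformity `U = Σ p²`, and multivariate mutual information by inclusion–exclusion over channel subsets (any channel subset can be marginalized out). |
| **TSFOS** | One first-order histogram of all channels' in-ROI intensities pooled into B equal bins: entropy, uniformity/energy, histogram moments. |
| **TSCM** | Cross-voxel co-occurrence: per-pair signature GLCMs summed over all in-ROI voxel pairs at offset (d, θ), then the 22 Haralick-type features. With N = 1 this is exactly the classical symmetric GLCM. |
| **TSCIN** | Per-voxel first-order statistics of the signature vector itself (entropy, SD, range, max, median absolute deviation, skewness, kurtosis), producing feature maps that are reduced to ROI values by mean/median/SD. |
| **TSRM** | Within-voxel relationship matrix: co-occurrence of levels at channel positions k and k+d, for ordered sequences such as DCE frames; analyzed with the same 22 features. |

On top of extraction, the package provides sliding-window **feature
maps** (`mpmap()`, with the classical 5×5-window/128-level setting as
the default and single-image GLCM maps as the baseline), the **IsoSVM**
classifier — Isomap geodesic embedding followed by a class-cost-weighted
linear SVM with a leave-one-out cross-validated grid search over
benign:malignant penalty ratios {1, 1.5, 2, 2.5, 3, 3.5, 4}:1 — and
ROC/AUC diagnostics with DeLong confidence intervals.

Because no clinical dataset ships with the package, a seedable
**synthetic phantom generator** emulates the relevant tissue geometry:
a glandular-texture background, homogeneous smooth ("benign-like") vs
heterogeneous rough ("malignant-like") lesions, and a uniform "cyst"
compartment, with a tunable inter-channel coupling.

## Worked example

```r
library(mprad)

ph    <- generate_phantom(phantom_spec(seed = 42))
field <- extract_signature_field(ph$volume, ph$rois$lesion, quant_spec(G = 8))
tp    <- build_tspm(field)
tspm_entropy(tp); tspm_uniformity(tp); tspm_mutual_information(tp)
#> lesion: H=5.974  U=0.0199  MI=-0.091
haralick_features(build_tscm(field))[c("entropy", "contrast",
                                       "correlation", "homogeneity")]
#>     entropy    contrast correlation homogeneity
#>       4.748       1.592       0.643       0.596
```

The heterogeneous lesion has high joint entropy; the uniform cyst, on
volume-scoped levels, is nearly a single signature (`H = 1.913` with the
default acquisition noise, exactly 0 without it).

A full benchmark cohort — 20 benign-like + 20 malignant-like subjects
at a 4:1 heterogeneity ratio — with the IsoSVM classifier:

```r
co  <- generate_cohort(20, 20, effect_size = 3, seed = 1)
group_stats(co$features$tspm_entropy, co$features$label)
#> TSPM entropy benign 2.10 +/- 0.15, malignant 6.25 +/- 0.04,
#> Welch p = 2.8e-18, AUC = 1.00
pan <- feature_panels(co$features)
loocv_grid_search(as.matrix(co$features[, pan$mp]), co$features$label)
#> IsoSVM LOOCV: AUC 1.00 (ratio 1:1), sens 100%, spec 100%
```

Malignant-like lesions carry significantly higher joint signature
entropy (the multiparametric heterogeneity signal), and the
cross-validated classifier separates the benchmark classes completely.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "mprad.R", package = "mprad")` with subcommands
`simulate`, `extract`, `maps` and `classify`.

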