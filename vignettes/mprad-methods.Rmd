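---
title: "Multiparametric radiomics with mprad: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric radiomics with mprad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprad)
```

## The tissue-signature model

Multiparametric radiological data — for instance breast mpMRI with T1,
T2, diffusion (b-values / ADC) and DCE series — consist of N
co-registered scalar channels on one voxel grid. `mprad` analyzes such
data through the *tissue signature*: at voxel position $p$,

$$S_p = \left[I_p^{(1)}, I_p^{(2)}, \ldots, I_p^{(N)}\right]^T,$$

the vector of intensities the voxel takes across channels, in channel
order. All feature families are functions of the signature field of a
region of interest (ROI), so they capture how channels co-vary at each
voxel — information that per-image ("single radiomic") features discard
by construction.

Two assumptions are made and *not* checked beyond shape/affine
agreement: the channels are already co-registered (no resampling or
registration is performed), and intensities are finite (non-finite
voxels are a hard error rather than being silently masked, so the
caller controls pre-cleaning).

### Quantization

Second-order and joint features operate on integer gray levels
$1..G$ obtained by linear, equally spaced binning between a scope
minimum and maximum (`quant_spec()`). Bins are half-open with the
maximum closed into level $G$, so the top level is never empty; a
constant input maps wholly to level 1. Three range modes are exposed:
per-channel min–max, global (all-channel) min–max, and a fixed
user-supplied range; the scope can be the ROI or the whole volume.

Which scope to use is a genuine modeling choice:

* **ROI scope** maximizes intra-ROI dynamic range and is the
  `quant_spec()` default for ad-hoc ROI analysis.
* **Volume scope** (or a fixed range) keeps the level scale common
  across regions and subjects. This is what the sliding-window maps use
  — per-window re-quantization would destroy spatial contrast — and
  what `extract_features()`/`generate_cohort()` use, because ROI-scoped
  min–max *normalizes lesion amplitude away*: a homogeneous lesion and
  a heterogeneous one then occupy equally many levels and joint-entropy
  contrast between them largely disappears. On a common scale a
  homogeneous lesion occupies few cells and a heterogeneous one many,
  which is the behavior that makes joint entropy a heterogeneity
  marker in the first place. The cohort benchmark goes one step
  further and uses a *fixed* range shared by all subjects (the
  synthetic analogue of a fixed acquisition bit depth); a per-subject
  volume range would couple the background compartment's levels to the
  (class-dependent) lesion amplitude and spuriously break the
  background null comparison.

## The five feature families

**TSPM** (`build_tspm()`). The joint probability distribution of
quantized signatures over the ROI, stored sparsely as the occupied
cells (at most one per ROI voxel — a dense $G^N$ array for, say,
$G = 128, N = 10$ is impossible and never allocated). Features: joint
entropy $H = -\sum p \log_2 p$, uniformity $U = \sum p^2$, and
multivariate mutual information by inclusion–exclusion over all
non-empty channel subsets $Y$:
$MI = \sum_Y (-1)^{|Y|+1} H(Y)$. For $N = 2$ this is
$H_1 + H_2 - H_{12} \ge 0$; for $N \ge 3$ the interaction information
can be negative and is reported signed, not clipped. Any channel
subset can be marginalized out (`marginalize()`), multiplying the
number of available features. Conventions: $0\log 0 = 0$; all
logarithms in the package are base 2, so entropies are in bits.

**TSFOS** (`build_tsh()`). All channels' in-ROI intensities pooled
into one histogram of B equal bins. Raw pooling is meant for series
whose channels share an intensity scale (b-values, DCE frames);
`"normalized"` pooling rescales each channel to $[0,1]$ over the ROI
first. Moments are computed on bin centers weighted by bin probability
— features are strictly functions of the histogram. Energy is the
conventional first-order alias of uniformity; both names are returned.
Kurtosis is non-excess (3 for a Gaussian); skewness/kurtosis of a
zero-variance histogram are 0 by convention.

**TSCM** (`build_tscm()`). For two signatures $S_i, S_j$ the pair
matrix counts channel indices $r$ with $S_i(r) = m, S_j(r) = n$; the
TSCM sums these over all in-ROI voxel pairs at distance $d$ and
in-plane angle $\theta \in \{0°, 45°, 90°, 135°\}$. Accumulation is
symmetric (each pair counted in both directions, as in common GLCM
practice, so the matrix equals its transpose); pairs with either
endpoint outside the ROI are skipped; counts from multiple requested
angles are pooled, which is how a single scalar per feature is
obtained — per-angle matrices are available by passing a single angle.
With one channel the TSCM is exactly the classical symmetric GLCM, a
property the test suite verifies against a brute-force reference.

**Haralick features** (`haralick_features()`). The package evaluates
22 features on any normalized co-occurrence matrix: the 14 classical
ones (energy, contrast, correlation, sum-of-squares variance,
homogeneity, sum average, sum variance, sum entropy, entropy,
difference variance, difference entropy, information measures of
correlation 1/2, maximal correlation coefficient) plus 8 common
extensions (autocorrelation, cluster prominence/shade/tendency,
dissimilarity, maximum probability, inverse difference normalized,
inverse difference moment normalized). Degenerate denominators follow
fixed conventions: correlation → 0 when a marginal SD is 0;
information measures → 0 when the relevant marginal entropy is 0; the
maximal correlation coefficient is the square root of the
second-largest eigenvalue magnitude of the Q matrix, with any
eigen-decomposition failure → 0. Sum variance is centered on the sum
average (the modern convention, rather than re-using sum entropy).

**TSCIN and TSRM** (`tscin_first_order()`, `build_tsrm()`).
First-order TSCIN statistics are computed per voxel on the signature
vector itself, after per-channel rescaling to $[0,1]$ so channels with
different physical units are comparable — an explicit convention, since
max/range/SD of a raw mixed-unit vector would be dominated by the
widest-scaled channel. Dispersion uses the population ($1/N$)
convention; per-voxel entropy uses a fixed-bin histogram
(`B_sig = 8` bins over $[0,1]$: signature vectors are short, e.g. ~14
DCE frames, so finer binning would be mostly empty) and is therefore
bounded by $\log_2 B_{sig}$. The TSRM counts within-signature level
pairs at channel distance d ($N - d$ pairs per voxel, exactly). It is
kept *ordered* (not symmetrized): parameter sequences such as DCE time
or b-values are directional, and reversing channel order transposes
the matrix. TSRM features are the same 22 Haralick formulas; maps of
either kind reduce to ROI scalars via `summarize_map()`
(mean/median/SD).

## Sliding-window feature maps

`mpmap()` assigns to each voxel the requested feature computed on its
w × w in-plane neighborhood treated as a small ROI (3D volumes are
processed slice by slice, matching the in-plane window convention).
The defaults follow the classical mpMRI setting: 5 × 5 window with
G = 128 gray levels. Levels are quantized once, volume-scoped, so map
values are comparable across windows; borders use mirror padding so
the output grid matches the input. `single_glcm_map()` is the N = 1
baseline. Note that duplicating a channel does *not* reproduce the
single-image map: pair counts accumulate over channels, so the joint
map differs whenever channels co-vary (the test suite asserts this
non-equivalence on purpose).

## IsoSVM classification

Features are z-scored (the families live on very different scales),
embedded by Isomap — k-nearest-neighbor graph on Euclidean distances,
geodesics as graph shortest paths, classical MDS of the geodesic
matrix — and classified by a linear SVM in which the benign class
(label 0, typically the minority) carries `ratio` times the
misclassification cost of the malignant class. The ratio is chosen by
a grid search over {1, 1.5, 2, 2.5, 3, 3.5, 4}:1 in leave-one-out
cross-validation, maximizing AUC; ties break toward the smaller ratio
(parsimony). Defaults k = 20, embedding dimension 1.

Numerical/design choices worth knowing:

* A disconnected neighbor graph is repaired by repeatedly adding the
  shortest inter-component edge — a documented, deterministic repair.
* The default mode is **transductive**: Isomap is fit once on all
  subjects and only the SVM is cross-validated. A **strict** mode
  re-embeds each training fold and projects the held-out subject by
  the Nyström/landmark-MDS formula; on the packaged benchmark the two
  modes agree to within 0.1 AUC (asserted in the tests). The
  transductive default mirrors how such pipelines are usually run, but
  strict mode is the honest generalization estimate.
* AUC is the Mann–Whitney statistic with midranks for ties; the 95% CI
  uses DeLong's method; the reported sensitivity/specificity operating
  point maximizes Youden's J (a threshold rule that must be fixed by
  convention, since an ROC alone does not pick one).
* Group comparisons use Welch's unequal-variance t-test (robustness
  over the pooled-variance form), plus univariate logistic regression
  and per-feature AUC. A feature with zero variance in both groups is
  flagged and its t-test is NA while the AUC is still computed.

## The synthetic phantom generator

No clinical dataset can ship with the package, so validation runs on
seedable phantoms (`generate_phantom()`, `generate_cohort()`) that
emulate the tissue geometry the features must resolve:

* a glandular-texture **background** (Gaussian random field,
  correlation length 3 voxels),
* a **lesion** disk whose texture heterogeneity is class-conditional,
* optionally a uniform **cyst** disk (zero texture — its joint entropy
  is exactly 0 without acquisition noise).

Textures are Gaussian random fields built by FFT filtering of white
noise with a Gaussian kernel, so the correlation length is directly
controllable and everything is reproducible from one integer seed
(identical seeds give bit-identical volumes). Channels mix one shared
latent field per compartment with channel-specific fields via the
`coupling` weight, so inter-channel mutual information rises with
coupling in a known direction.

The cohort generator models "heterogeneity" on two axes, because they
control different feature families: malignant-like lesions have full
texture amplitude and short correlation length (rough), benign-like
lesions are attenuated by $1/(1+\text{effect\_size})$ in amplitude and
smooth. Amplitude drives the joint-distribution features (TSPM/TSFOS —
these are blind to spatial arrangement), correlation length drives the
spatial pair features (TSCM contrast and relatives). `effect_size = 0`
makes the classes exchangeable; the packaged benchmark uses
`effect_size = 3`, i.e. a 4:1 ratio. Defaults, chosen once as a
realistic desk-scale configuration: 32 × 32 grid, N = 3 channels,
lesion radius 8 (~200 voxels), coupling 0.7, noise SD 0.1, lesion
offset +2 over background, G = 16 on the fixed range [-4, 6].

What the phantoms deliberately do **not** emulate: MR physics (no
Bloch simulation or pharmacokinetic enhancement curves), anatomy,
partial-volume effects, bias fields, or registration error. Passing
the packaged benchmark therefore shows that the implementation
measures what it claims on controlled texture — not that any fixed
AUC will be attained on clinical data.

## Validation strategy and problem sizes

The test suite checks every family against independent brute-force
oracles (naive loops, Floyd–Warshall shortest paths, exhaustive
AUC pair counting, hand-evaluated small matrices) and property-based
invariants (entropy bounds, permutation equivariance/invariance,
conservation of counts, translation equivariance of maps). The
benchmark properties are evaluated on 50 cohorts of 20 + 20 subjects:
the malignant-like class shows higher lesion joint entropy (Welch
p < 0.01), the best multiparametric feature's univariate AUC is at
least that of the best single-channel feature, and the identically
distributed background compartments show no significant difference.
The cross-validated-AUC machinery is checked against the closed-form
two-Gaussian limit $\Phi(1/\sqrt{2}) \approx 0.760$ at n = 100 over 50
seeds. These sizes keep the whole suite to a few minutes while leaving
the statistical assertions well-powered.

## Known limitations

* 3D volumes are supported throughout, but co-occurrence offsets are
  in-plane only (maps and TSCM process slices independently).
* The 22-feature list fixes one widely used canon; other radiomics
  standards enumerate slightly different extension sets.
* The multivariate mutual information for $N \ge 3$ follows the
  inclusion–exclusion (interaction information) convention; other
  multivariate generalizations (total correlation, dual total
  correlation) exist and give different values.
* LOOCV AUC under an exchangeable null is biased below 0.5 (each
  held-out subject pulls the boundary the wrong way); null-signal
  checks should bound it from above only, as the tests do.
* `fixed_range` quantization clips out-of-range intensities into the
  end bins rather than erroring.
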