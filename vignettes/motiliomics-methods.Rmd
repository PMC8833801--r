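---
title: "Methods: from MR radiomics to cellular motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MR radiomics to cellular motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

motiliomics implements a complete analysis chain relating quantitative
features of contrast-enhancing brain-tumor MRI to the *random motility
coefficient* (RMC) of cells cultured from the same tumors. This vignette is
the package's own account of the models it fits, the parameters that matter,
and the choices made where reasonable alternatives existed.

## 1. Cell motility from time-lapse tracks

Cells plated on polyacrylamide gels of six stiffnesses (0.7-200 kPa) are
imaged every 15 minutes for 16 hours (65 frames). For a track $r(t)$ the
time-averaged mean squared displacement over overlapping windows is

$$\mathrm{MSD}(\tau) \;=\; \big\langle\, \lVert r(t+\tau) - r(t)\rVert^2 \,\big\rangle_t .$$

For 2-D Brownian motion $\mathrm{MSD}(\tau) = 4 D \tau$, and the RMC is the
diffusivity $D$ in $\mu m^2/\mathrm{min}$. `fit_rmc()` estimates $D$ by a
weighted least-squares slope through the origin, weighting each lag by its
number of contributing pairs and using only the first quarter of available
lags, where the time average is best sampled; both fractions are arguments.
An optional persistent-random-walk (PRW) model fits Furth's form
$\mathrm{MSD}(\tau) = 4D\,[\tau - P(1 - e^{-\tau/P})]$ for data with visible
short-lag persistence; which model the upstream tracking literature used is
not fully specified, so `brownian_linear` is the documented default and the
PRW fit is provided alongside. Negative slope estimates are floored at zero
(a diffusivity cannot be negative) and flagged.

A tumor's motility is the unweighted mean RMC over all cells pooled across
the six gels — the literal reading of averaging "across all of the gel
stiffnesses"; a mean-of-condition-means variant is available via the
per-cell table. An inclusion rule (`enforce_min_cells`) flags subjects with
fewer than 25 tracked cells in any condition.

## 2. Radiomics extraction

`extract_all_features()` reproduces a standard 107-feature catalogue:
14 shape, 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM
features, under the canonical `family_FeatureName` keys.

**Histogram matching.** Volumes are first matched to the cohort's "mean
image": the reference is the pointwise mean of per-volume empirical quantile
functions on a 1001-point probability grid, and each volume is remapped
monotonically onto it. The mean-of-quantile-functions construction is a
documented choice — the phrase "matched to the mean of the images" does not
pin down the reference — and matching is applied to the whole volume before
masking, so the mapping is estimated from the full field of view.

**Discretisation.** Bin widths are chosen per subject so that the masked
intensity range yields 50-125 bins, targeting the midpoint (87). The level
of a voxel is $\lfloor (v - \min)/w \rfloor + 1$; a maximum that divides the
width exactly occupies its own top bin. Per-subject binning follows the
range rule as stated per extraction; a cohort-fixed width can be passed
explicitly.

**Texture matrices.** GLCM (symmetric, distance 1) and GLRLM are accumulated
per 3-D direction over the 13 unique lattice angles, features computed per
direction and averaged — the per-direction-average convention of the
standard catalogue; a merged-matrix variant is intentionally out of scope.
GLSZM zones use 26-connectivity, NGTDM uses the 26-neighbourhood mean, and
GLDM uses dependence threshold $\alpha = 0$ with the centre voxel included
in the dependence count. Degenerate single-gray-level regions return defined
limits (correlation and MCC 1, entropies and contrast 0, NGTDM coarseness
capped at $10^6$) so the feature vector is always finite.

**Shape.** `MeshVolume` and `SurfaceArea` come from a triangular isosurface
mesh of the binary mask, built by marching tetrahedra on the 6-tetrahedron
Kuhn decomposition with vertices at edge midpoints. Midpoint meshes carry a
large staircase bias in surface area (a digital ball's raw mesh is ~25% over
the true area), so vertices are relaxed with shrink-free Taubin smoothing
($\lambda = 0.5$, $\nu = 0.53$, 60 iterations); with those settings a
radius-10 digital ball measures sphericity 0.976 and an axis-aligned box's
mesh volume is within 2% of its true volume. Axis lengths derive from
principal components of the physical voxel coordinates ($4\sqrt{\lambda}$);
maximum 3-D/2-D diameters use boundary-voxel centre distances (a voxel-level
convention, reported as such); `VoxelVolume` counts voxels, so both volume
conventions are available.

## 3. Feature selection and regression

With 107 candidate features and ~31 subjects, selection happens in two
stages. First a *bootstrap forest*: `n_repeats = 10` regression forests of
100 trees (bootstrap resampling per tree, $\sqrt{p}$ feature subsampling,
variance-reduction splits), ranking features by impurity-decrease importance
averaged over repeats; repeating the forest averages out bootstrap noise in
a single ranking. The top 10 go to the *adaptive lasso*:

$$\hat\beta \;=\; \arg\min_\beta \; \tfrac{1}{2n}\lVert y - X\beta\rVert^2
  + \lambda \textstyle\sum_j w_j |\beta_j|, \qquad w_j = 1/|\hat\beta^{\text{pilot}}_j|^\gamma,$$

with OLS pilot, $\gamma = 1$, solved by cyclic coordinate descent with
soft-thresholding on internally standardised features. $\lambda$ runs over a
100-point log grid spanning four decades below $\lambda_{\max}$ (the
smallest penalty zeroing every coefficient), *plus the unpenalised
solution*: including $\lambda = 0$ lets the selection criterion fall back to
plain OLS when the data genuinely support it, and makes the noiseless limit
exact. The reported $\lambda$ minimises AICc by default — appropriate at
n ≈ 31 — with BIC and inner leave-one-out CV as options. Near-singular
pilots (condition number $> 10^{10}$) fall back to a lightly ridged pilot.
Post-selection OLS t-tests are reported for the selected support and are
labelled naive: they ignore the selection event.

## 4. Validation

`loocv_evaluate()` repeats the *entire* procedure — forest ranking, top-10
selection, adaptive lasso — inside every fold, so the held-out subject never
influences selection. The baseline is the mean-value predictor's LOOCV RMSE.
`fit_line_r2()` is the squared Pearson correlation between predicted and
actual motility (the $R^2$ of the fitted line through the scatter).

`permutation_test()` refits the identical procedure on permutations of the
motility vector. The observed statistic is the in-sample full-data fit
(matching how the single observed $R^2$/RMSE pair is usually quoted), with
the LOOCV statistic available via `statistic = "loocv"`. p-values use the
add-one estimator $(1 + \#\{\text{null} \geq \text{obs}\})/(n_{perm} + 1)$
and are therefore never zero. Fold and permutation RNG streams derive from a
master seed, so any replicate is reproducible in isolation.

## 5. The synthetic cohort generator

No patient images or tracks are distributable, so the package ships a
generator whose defaults emulate the study conditions: 31 subjects, ~192
tracks per subject (32 cells × 6 gels, 65 frames at 15 min), cohort motility
mean 2.24 and SD 1.25 $\mu m^2/\mathrm{min}$, and a planted linear
relationship explaining `target_r2 = 0.60` of the motility variance.

Each subject is an ellipsoidal "enhancing tumor" phantom: bright rim, dark
core (intensity $c + (r - c)\rho^{s}$ in normalised radius $\rho$), a small
homogeneous necrotic nugget darker than the core, and a correlated Gaussian
texture field — embedded in a brain ellipsoid with noisy tissue intensity,
bright vessel-like foci, and a dark air/skull compartment filling the rest
of the volume. The air and vessel compartments matter more than they look:
cohort histogram matching is a rank transform of the whole volume, so if
the tumor's darkest (or brightest) voxels were the global extremes, every
subject's masked minimum (maximum) would map to the same reference value
and the feature would degenerate to a cohort constant. With populated dark
and bright tails — as in real head MRI — tumor extremes rank inside those
distributions and stay informative after matching.

Subject parameters are drawn uniformly from ranges chosen to look like a
heterogeneous glioma cohort (base radius 9-15 voxels at the default 64³
grid with ±20% anisotropy; core/rim ratio 0.15-0.6; rim exponent 2-6;
texture SD 25-90 intensity units with correlation length 1.2-3.5 voxels;
rim level 850-1150; nugget intensity 0.05-0.5 of the core). These ranges
deterministically drive the four planted features — the first-order minimum
through the nugget depth, the 10th percentile through the core depth and
dark-volume fraction, and the GLRLM gray-level non-uniformity and long-run
low-gray-level emphasis through size, smoothness and texture structure.

The response is composed on the *extracted* features: the four planted
columns are cohort-standardised, combined with standardised coefficients
$(1, -1, 0.7, 0.7)$: higher low-end intensity raises predicted motility, a
deeper necrotic minimum raises it (hence the negative sign on the minimum),
and more heterogeneous, dark-run-rich texture raises it. The magnitudes are
a package choice — raw-scale coefficient estimates do not transfer across
image generators. The combination is rescaled so the signal variance is
$R^2_{\text{target}} \sigma^2$, and Gaussian noise with variance
$\mathrm{Var}(\mu)(1/R^2_{\text{target}} - 1)$ is added before shifting to
the cohort mean. Motility is clipped at 0.05 $\mu m^2/\mathrm{min}$ (an RMC
is nonnegative); clipping is recorded and a warning raised if it affects
more than 10% of subjects. Setting all planted coefficients to zero yields a
null cohort (pure-noise motility) for calibration studies. Tracks are then
simulated per subject with `rmc_true` equal to that subject's motility —
uniform across gel conditions, an explicit simplification: how motility
varied across gels within a patient is not recoverable from the tumor-level
summaries the generator is calibrated to, and the analysis pools across
gels anyway.

### What passing tests do and do not show

The generator emulates the *statistical* structure of the study — sample
sizes, noise calibration, feature-driven response, track sampling — not the
physics of MRI or microscopy. Phantom texture is a stationary Gaussian
field; real enhancing tumors have non-stationary, non-Gaussian structure,
and real feature-feature correlations will differ. Recovery results on
synthetic cohorts therefore validate the *machinery* (estimators unbiased,
selection behaves as designed, permutation nulls calibrated), not clinical
transportability.

One measured consequence of realistic feature correlation: several of the
ten candidate features are near-duplicates of one another by construction
of the catalogue (joint average vs low percentiles, dependence
non-uniformity vs gray-level non-uniformity), correlating at
$|r| \approx 0.5$-$0.9$ across default cohorts. With n = 31 and a planted
$R^2$ of 0.60, the adaptive lasso reliably retains the planted minimum and
long-run emphasis, retains the other two planted features in roughly half
of cohorts, and swaps a correlated decoy in for a planted feature often
enough that the exact planted support is not the typical outcome. On an
independent (uncorrelated) design at the same n and $R^2$, planted features
are retained several times more often than nulls and recovered signs always
match — the selection machinery is sound; the limit is informational, not
algorithmic. Perfectly stable support recovery at this sample size would
require an implausibly decorrelated phantom, and the package does not
pretend otherwise.

## 6. Numerical choices and problem sizes

- Coordinate descent converges at max coefficient change $< 10^{-10}$
  (tested against soft-threshold closed forms at $10^{-10}$ and an
  independent solver); ties in forest ranking break by feature name.
- The quantile convention is linear interpolation (type 7) throughout.
- Texture kernels, the mesh builder and the lasso path run in C++; a full
  107-feature extraction of a 64³ subject takes ~0.1 s, a full cohort
  ~10 s, which sets the simulation sizes used in the test suite and the
  reproduction script (50 cohorts for calibration means, 20 tracked cohorts
  for motility recovery, 500-permutation significance runs).
- Brute-force enumeration oracles (all-pairs MSD, run/zone/dependence
  recounts on 5³ volumes) back every texture family at $10^{-10}$.

## 7. Known limitations

- Shape diameters use boundary voxel centres, not mesh vertices; on coarse
  masks they can differ from mesh-based conventions by up to a voxel.
- The PRW fit uses Nelder-Mead least squares without measurement-noise
  modelling; it is intended for well-sampled synthetic curves.
- Naive post-selection p-values are reported for transparency only.
- Under a null response the selected model collapses to the intercept in a
  third or so of fits, so the in-sample $R^2$ statistic has a point mass at
  zero and the permutation p-value is conservative in its upper tail (an
  atom at 1.0 from ties between degenerate observed and null fits). The
  small-p region, which decides significance, stays calibrated: the
  frequency of $p \leq 0.1$ under the null measures at its nominal level.
- The permutation test refits the full procedure per scramble; at 2000
  scrambles with the default forest settings this is minutes of compute,
  and the repeat count is the natural knob for exploratory runs.
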