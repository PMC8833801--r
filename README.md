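# motiliomics

Can routine contrast-enhanced MRI predict how motile a glioblastoma's cells
are? Measuring cell motility directly requires resecting tissue, culturing
the cells and tracking them under time-lapse microscopy for hours — a
per-patient experiment. motiliomics implements the full analysis chain that
links the two worlds, for imaging scientists and biophysicists who want to
reproduce, stress-test or extend that kind of radiomics-to-phenotype
pipeline:

- **Motility**: per-cell mean squared displacement
  $\mathrm{MSD}(\tau) = \langle \lVert r(t+\tau)-r(t)\rVert^2 \rangle_t$ and
  the random motility coefficient (RMC, $\mu m^2/\mathrm{min}$) from the
  2-D Brownian relation $\mathrm{MSD}(\tau) = 4D\tau$ (weighted
  through-origin fit; Furth's persistent-random-walk model optional),
  pooled to a tumor-level mean across six gel-stiffness conditions.
- **Radiomics**: a 107-feature catalogue (14 shape, 18 first-order,
  24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) on NIfTI volumes with
  binary tumor masks, after cohort histogram matching and 50–125-bin
  adaptive discretisation. Texture matrices and the isosurface mesh run in
  C++.
- **Model**: repeated bootstrap-forest ranking (impurity importance,
  100 trees, $\sqrt{p}$ subsampling), top-10 selection, then an adaptive
  lasso $\min_\beta \frac{1}{2n}\lVert y-X\beta\rVert^2 +
  \lambda\sum_j w_j|\beta_j|$ with OLS-pilot weights
  $w_j = 1/|\hat\beta_j^{\mathrm{pilot}}|$, solved by coordinate descent
  with AICc-selected $\lambda$.
- **Validation**: leave-one-out CV with feature selection repeated inside
  every fold, a mean-predictor baseline, fitted-line $R^2$, and a
  permutation test that refits the entire procedure on scrambled motility.
- **Synthetic cohorts**: a tumor-phantom generator with planted
  feature–motility relationships (default: 31 subjects, motility
  2.24 ± 1.25 $\mu m^2/\mathrm{min}$, planted $R^2 = 0.60$, ~192 tracks per
  subject) so everything above is testable without patient data.

## Worked example

```r
library(motiliomics)

co  <- generate_cohort(cohort_config(seed = 1))   # 31 phantoms + tracks
est <- estimate_motility(co$tracks)               # MSD -> RMC -> tumor means
mean(est$subjects$tumor_mean)
#> [1] 2.221

fit <- fit_motility_model(co$features, co$motility, seed = 1)
fit$r2                                            # in-sample fitted-line R2
#> [1] 0.636

cv <- loocv_evaluate(co$features, co$motility, seed = 1)
c(cv$loocv_rmse, cv$baseline_rmse)
#> [1] 1.172 1.438

pt <- permutation_test(co$features, co$motility, n_perm = 200, seed = 1,
                       n_repeats = 2)
pt
#> <permutation_result> 200 permutations (in_sample statistic)
#>   observed R2 0.727 (p = 0.00995), RMSE 0.731 (p = 0.00995)
```

Reading the numbers: the track-derived cohort mean motility
(2.22 $\mu m^2/\mathrm{min}$) recovers the generator's 2.24 calibration;
the full-data model explains about the planted fraction of the motility
variance (target $R^2$ 0.60); the feature model beats the mean-predictor
baseline out of fold (1.17 vs 1.44 $\mu m^2/\mathrm{min}$); and no
scrambled-motility refit out-performed the true model (add-one p ≈ 0.01 at
200 scrambles). Cohorts at other seeds scatter around these values — the
methods vignette discusses what varies at n = 31 and why.

Single-subject feature extraction:

```r
p  <- tumor_params(shape = c(48, 48, 48), radii = c(12, 11, 10))
vm <- generate_tumor_volume(p, seed = 3)
fv <- extract_all_features(vm$image, vm$mask)
length(fv)
#> [1] 107
round(fv[c("firstorder_Minimum", "shape_Sphericity")], 3)
#>  firstorder_Minimum    shape_Sphericity
#>             297.491               0.976
```

A thin CLI over the same functions lives at
`inst/scripts/motiliomics.R` (subcommands `simulate`, `motility`,
`features`, `fit`, `validate`, `run`).

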