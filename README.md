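# angulai

Multi-angular hyperspectral estimation of leaf area index (LAI) in crop
canopies, and a reproducible comparison of the estimation methods a
field spectroscopist would reach for.

Canopy reflectance is angularly sensitive: the same wheat plot viewed at
nadir and at a 60° view zenith angle (VZA) mixes leaf and soil signal in
different proportions and carries more noise off-nadir, so the accuracy
of any LAI retrieval depends on the view angle. `angulai` implements the
four standard retrieval strategies behind one tabular, pipe-friendly
interface and evaluates them across the 13 VZAs −60°, −50°, ..., +60°
(negative = backscattering):

* **Published vegetation indices** — 21 narrow-band indices (NDVI, RVI,
  DVI, OSAVI, PRI, WDRVI, VOG, CIred-edge, mND705, mSR705, EVI-1,
  MCARI2, MTVI2, SIPI, MTCI, DDn, TCARI/OSAVI, MSAVI2, red-edge
  position, DD, VOG-2), each used as the predictor of a linear LAI
  model.
* **Optimal two-band indices** — exhaustive search over every wavelength
  pair (λ₁, λ₂) in 400–900 nm for the forms ND = (R₁−R₂)/(R₁+R₂),
  SR = R₁/R₂ and DVI = R₁−R₂, maximizing the R² of the ordinary least
  squares fit LAI = a·index + b.
* **PLSR** — partial least squares regression on all 501 bands,
  implemented from scratch by NIPALS (weights w ∝ Xᵀy, scores t = Xw,
  deflation per component), with the number of latent variables A chosen
  by five-fold cross-validated RMSE.
* **BPNN** — a single-hidden-layer ReLU network trained by full-batch
  Adam, hidden size grid-searched by cross-validation, with repeated
  random initializations aggregated into an ensemble mean.

Accuracy is reported as R² = 1 − SSE/SST and RMSE = √(Σ(Pᵢ−Oᵢ)²/n) on a
fixed 176/45 calibration/validation split of 221 samples, shared across
all angles. Because no public multi-angular dataset exists for this
problem, the package includes a synthetic canopy generator
(Beer–Lambert gap fraction, chlorophyll-driven red edge, soil line,
angular brightness asymmetry, angle-growing noise) whose defaults
emulate the statistical structure of such field campaigns; the methods
vignette (`vignettes/multiangular-lai.Rmd`) documents the model and its
limits.

## Worked example

```r
library(angulai)

d <- generate_canopy(canopy_config(seed = 1), vzas = c(-60, 0, 60))
part <- make_partition(d, seed = 2)            # shared 176/45 split, 5 folds
res <- evaluate_vza(d, part, methods = c("vi", "optimal_vi", "plsr"))
dplyr::filter(res, set == "validation")
#> # A tibble: 9 × 5
#>   method        vza     r2  rmse     n
#>   <chr>       <dbl>  <dbl> <dbl> <int>
#> 1 vi:DVI        -60 0.0286 1.30     45
#> 2 optimal:DVI   -60 0.769  0.632    45
#> 3 plsr          -60 0.910  0.396    45
#> 4 vi:DVI          0 0.579  0.855    45
#> 5 optimal:DVI     0 0.876  0.464    45
#> 6 plsr            0 0.959  0.265    45
#> 7 vi:DVI         60 0.141  1.22     45
#> 8 optimal:DVI    60 0.723  0.693    45
#> 9 plsr           60 0.908  0.399    45
```

Reading the table: every method peaks at nadir (vza 0) and loses
accuracy at ±60°; the fixed-band DVI(810, 680) index degrades
drastically, the per-angle optimized two-band index much less, and PLSR
is both the most accurate and the least angle-sensitive — the ordering
the package exists to study. The two-band search itself:

```r
nadir <- dplyr::filter(d, vza == 0)
s <- r2_surface(nadir, "DVI", step = 2, partition = part)
select_optimum(s, nadir, part)
#> # A tibble: 1 × 8
#>   index_type   vza lambda1 lambda2    r2 slope intercept     n
#> 1 DVI            0     724     760 0.931 -25.9    0.0920   176
```

Both selected bands sit in the red edge (700–780 nm), where the
reflectance difference of two nearby bands tracks the chlorophyll-driven
red-edge shift while soil and leaf-structure nuisance cancels.
`autoplot(s)` draws the full (λ₁, λ₂) R² surface;
`plot_angular_profile(res)` draws the accuracy-versus-angle profiles;
`tidy()`/`glance()` methods expose PLSR coefficients, loadings and fit
summaries.

The end-to-end driver writes a complete tabular report (optimal pairs
per angle, per-index results, method profiles, decline-vs-nadir
percentages, R² surfaces, PLSR loading and RMSE-curve tables, run log):

```r
run_experiment(out_dir = "report", seed = 1)   # or a YAML config
```

A thin shell interface over the same functions ships in
`inst/scripts/lai-experiment.R` (subcommands `simulate`, `indices`,
`optimize`, `report`).

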