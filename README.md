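# agbfusion

Multi-feature fusion for estimating potato above-ground biomass (AGB) from
plot-scale UAV imagery.

## The problem

Fresh above-ground biomass is the workhorse indicator of crop growth status,
but vegetation indices computed from a single flight saturate as the canopy
closes and behave differently across cultivars whose growth cycles differ by
weeks. `agbfusion` implements a whole-growth-period estimation pipeline that
fuses five feature groups extracted per plot and flight date:

- **VIs** — a 14-index vegetation-index bank (NDVI, NDRE, SR, WDRVI, MSR,
  MCARI, MCARI2, TCARI, GRVI, GCI, RECI, RDVI, TDVI, NDI) computed from
  six-band multispectral plot means,
- **Texture** — eight gray-level co-occurrence matrix (GLCM) statistics per
  band (ME, VA, DI, CON, HO, SE, COR, EN), angle-averaged,
- **CC** — canopy cover by bimodal (Otsu) segmentation of a greenness index
  (excess green on RGB, or NDVI),
- **GDD** — growing degree days,
  `GDD = sum over days of max(0, (T_max + T_min)/2 - T_b)`,
- **GPR** — the growth process ratio, `GPR = T1 / TO`: days after emergence
  divided by the cultivar's total growth period, which puts early-, mid- and
  late-maturing cultivars on a common developmental clock.

Two feature-selection routes (Boruta shadow-feature selection with
variance-inflation screening, and Pearson top-k ranking) feed six regression
algorithms (random forest, PLSR, multiple and simple linear regression,
ridge, lasso), evaluated with R², RMSE, rRMSE and MAE on a stratified
2/3 : 1/3 holdout.

Because the motivating field campaign's data were never deposited, the
package ships a first-class synthetic scene generator that emulates the
three factorial experiments (E1: 2 cultivars × 3 densities × 3 blocks = 18
plots; E2: 2 cultivars × 5 N rates × 4 blocks = 40; E3: 1 cultivar × 3 N ×
4 K × 3 blocks = 36), four flights per experiment (376 plot-date samples),
latent logistic-in-GPR biomass trajectories, and clumped vegetation/soil
mixed-pixel rasters with sensor noise, spectral jitter and late-season
senescence. Every downstream stage is testable against the generator's
ground truth.

## Worked example

```r
library(agbfusion)

scene    <- generate_dataset(scene_config(), seed = 1)   # 376 plot-date samples
features <- build_feature_table(scene)                   # VIs, texture, CC, GDD, GPR
sel      <- pearson_rank(features)                       # top-5 VIs + top-3 textures
split    <- split_train_test(features, fraction = 2/3, seed = 1)

rbind(
  fit_predict(model_spec("RF", seed = 1), split$train, split$test,
              "VIs", selection = sel),
  fit_predict(model_spec("RF", seed = 1), split$train, split$test,
              c("VIs", "GDD", "CC", "GPR"), selection = sel)
)
```

prints

```
  model          combo n_train n_test r2_train r2_test rrmse_test mae_test
1    RF            VIs     251    125     0.94    0.74       0.38     0.31
2    RF VIs+GDD+CC+GPR     251    125     0.99    0.96       0.15     0.13
```

i.e. on the synthetic study a random forest trained on vegetation indices
alone explains 74% of test-set AGB variance, and fusing canopy cover,
growing degree days and the growth process ratio lifts that to 96% while
halving the relative error — the qualitative fusion benefit the pipeline is
built to measure (magnitudes are scene-dependent).

The developmental clock itself is reconstructed from each cultivar's
first-flight anchor and the flight calendar:

```r
head(gpr_schedule()[, c("cultivar_id", "stage", "flight_date", "t1", "gpr_2dp")], 4)
#>   cultivar_id stage flight_date t1 gpr_2dp
#> 1         Z27    S1  2023-07-04 19    0.20
#> 2         Z27    S2  2023-07-17 32    0.34
#> 3         Z27    S3  2023-08-03 49    0.52
#> 4         Z27    S4  2023-08-13 59    0.62
```

An end-to-end run (simulate → extract → select → model → report) is one
call, `pipeline_run(run_config(outdir = "run1", seed = 1))`, or from a
shell via the thin CLI at `inst/cli/agbpipe.R`:

```sh
Rscript inst/cli/agbpipe.R run-all --outdir run1 --seed 1 --selection both
```

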