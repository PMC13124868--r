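# ramanscreen

Systematic selection of Raman spectral preprocessing for bioprocess
soft sensing.

Inline Raman probes let cell-culture processes be monitored in real
time — viable cell density, viability, glucose, lactate, glutamine,
glutamate, ammonium — once chemometric models are calibrated against
offline assays. Model quality hinges on spectral preprocessing, which
is usually picked by trial and error. `ramanscreen` replaces that with
an exhaustive, statistically grounded screen:

1. **Filter library** — 19 operators in four categories (smoothing,
   baseline correction, normalization, other): Savitzky-Golay,
   symmetric EWMA, Daubechies-4 wavelet denoising, moving median,
   asymmetric least squares (AsLS), row-centre / offset / linear / AsLS
   baselines, SNV, peak-height and peak-area normalization, MSC, and
   Savitzky-Golay derivatives. Crossed exhaustively:
   6 × 5 × 4 × 4 = **480 combinations**.
2. **Screen** — every combination is pushed through a calibration model
   per biochemical parameter (PLS with 7-group cross-validated
   latent-variable selection, or an automated MLP architecture search
   over `25·(N+1)` networks on PCA scores), on one shared run-stratified
   80/20 calibration/validation split; validation-set MAE, SD of the
   absolute errors (SD_AE), and per-sample absolute/relative errors are
   recorded for each of the 490 rows (480 cells + 10 raw replicates).
3. **Factorial modelling** — MAE and SD_AE are modelled by OLS on the
   four sum-to-zero-coded factors (main effects + two-factor
   interactions, backward elimination at α = 0.05, automatic
   Box-Cox/log transform selection).
4. **Desirability optimization** — Derringer desirability
   (`D = (∏ dᵢ^{rᵢ})^{1/Σrᵢ}`, minimize goals, importance 5 for MAE and
   4 for SD_AE) is evaluated at all 480 cells of the fitted models; the
   argmax is the recommended preprocessing, per parameter or for all
   parameters combined, followed by a paired one-tailed t-test of
   individual vs overall optima.

Because no public spectra exist for the target system (batch Sf9
insect-cell culture with baculovirus infection), the package includes a
fully synthetic study generator — five bioreactor runs (12/12/13/13/15
samples, 65 in total), growth/infection kinetics, linear
concentration-to-band mixing, run-specific fluorescence background,
smooth per-spectrum drift, detector noise, and 6-spectrum pre-sampling
averaging — so the entire workflow runs and is tested without any
instrument data.

## Worked example

```r
library(ramanscreen)
library(dplyr)

study <- generate_study(seed = 42)
study
#> <synthetic_study> 65 calibration spectra over 5 runs (12/12/13/13/15)

scr <- run_screen(study$spectra, study$references, technique = "pls",
                  parameters = c("Gluc_g_L", "Lac_g_L"),
                  config = screen_config(max_lv = 8), seed = 42)

scr |> filter(!failed, repetition == 1) |>
  group_by(parameter) |> slice_min(mae, n = 1) |>
  select(parameter, label, mae, sd_ae)
#>   parameter label                                                 mae   sd_ae
#> 1 Gluc_g_L  smoothing=WDS,baseline=linear,norm=none,other=d1q 0.147   0.0858
#> 2 Lac_g_L   smoothing=WDS,baseline=asls,norm=none,other=d1q   0.00202 0.00176
```

The best observed cells already show what the factorial stage
formalizes: wavelet/AsLS-style baseline handling plus a derivative
dominates raw spectra. Fitting the metric models and optimizing the
pooled desirability:

```r
coded <- code_design(scr)
models <- list()
for (p in c("Gluc_g_L", "Lac_g_L")) {
  d <- filter(coded, parameter == p)
  models[[paste0(p, ".mae")]]   <- fit_metric_model(d, "mae")
  models[[paste0(p, ".sd_ae")]] <- fit_metric_model(d, "sd_ae")
}
best <- optimize_combination(models)
best
#> <desirability_result>
#>   best: smoothing=SG,baseline=asls,norm=none,other=d1q
#>   overall D = 1.0000 over 4 responses

sel <- filter(scr, parameter == "Gluc_g_L",
              label == best$best$label, repetition == 1)
re_mean_ci(sel$errors[[1]]$re)
#>    mean    lo    hi     n
#> 1  1.81  1.17  2.46    13
```

The recommended combination (Savitzky-Golay smoothing, AsLS baseline
subtraction, first derivative) predicts validation glucose with a mean
relative error of **1.8%** (95% CI 1.2–2.5%) on the synthetic study —
versus 3.2% for raw spectra. `glance()`/`tidy()` expose the
factorial fits (here: Box-Cox-transformed MAE model, R² = 0.91),
`autoplot(best)` draws the ramp view of the optimum, and
`simulate_profiles()` replays hourly spectra that never entered
calibration through the fitted models.

A thin command-line front end over the same functions lives at
`inst/scripts/raman-screen.R`
(`generate` / `screen` / `optimize` / `compare` / `simulate` / `report`).

## Method details

See the methods vignette
(`vignettes/preprocessing-selection.Rmd`) for the model and algorithm
descriptions, the synthetic-study conditions and their rationale,
numerical edge cases, and known limitations.
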