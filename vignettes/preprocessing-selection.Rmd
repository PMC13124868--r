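---
title: "Selecting Raman spectral preprocessing by exhaustive factorial screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting Raman spectral preprocessing by exhaustive factorial screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Inline Raman spectroscopy is the workhorse soft sensor of upstream
bioprocessing: a single immersion probe tracks nutrients, metabolites
and cells in real time, once a chemometric model has been calibrated
against offline reference assays. The calibration quality, however,
depends heavily on how the raw spectra are preprocessed — smoothed,
baseline-corrected, normalized, derivatized — and practitioners usually
pick a recipe by habit or trial and error. `ramanscreen` implements a
systematic alternative: run **every** combination of a curated filter
library through the calibration pipeline, model the resulting
prediction errors as a designed experiment, and let a desirability
optimization recommend the preprocessing, per analyte and overall.

The package targets batch insect-cell (Sf9) culture with baculovirus
infection and its seven routinely monitored parameters — viable cell
density (`Xv`), percent viability (`CV`), glucose, lactate, glutamine,
glutamate and ammonium — but nothing in the machinery is specific to
that system beyond the synthetic data generator.

## The filter library and the screen

Four preprocessing categories are crossed exhaustively:

| category       | levels                                                            |
|----------------|-------------------------------------------------------------------|
| smoothing      | Savitzky-Golay (quadratic, 15 pt), symmetric EWMA, wavelet denoise (Daubechies-4, mean detrend), moving median (15 pt), AsLS smooth, none |
| baseline       | row-centre, offset (lowest point), linear (full-axis OLS), AsLS subtraction, none |
| normalization  | SNV, peak height, peak area, none                                  |
| other          | MSC, 1st derivative (quadratic), 2nd derivative (cubic), none      |

giving `6 * 5 * 4 * 4 = 480` unique combinations. Operators apply in
the category order above; `none` is the identity. AsLS appears twice
with identical parameters (smoothing factor `1e4`, asymmetry `0.001`):
as a smoother it *returns* the fitted curve, as a baseline correction
it *subtracts* it — the only interpretation under which the two levels
differ. Within a combination everything is strictly per-spectrum except
the MSC reference, which is the mean of the calibration spectra only
and is reused unchanged for validation and new data; this is the single
place where preprocessing can leak information across samples, and it
is deliberately restricted to the calibration split.

Parameters without a published value were fixed once: the EWMA
smoothing constant is `alpha = 0.3` (smoothing strength comparable to
the 15-point windows) and the derivative window is 15 points to match
the smoothing window. The "linear" baseline is a full-spectrum OLS fit
rather than endpoint anchoring, and the peak normalizations use the
global maximum / total trapezoid area with an optional wavenumber
sub-range (`norm_range`) because commercial software sometimes targets
a named band. The wavelet operator pads to a power of two, decomposes
to the maximum feasible depth and soft-thresholds at the universal
threshold with a MAD noise estimate — standard defaults, both
configurable.

A *screen* (`run_screen()`) evaluates all 480 combinations plus ten
replicate fits of the raw (all-`none`) cell — 490 rows per parameter —
for one technique:

* **PLS**: single-response NIPALS on column-centred spectra, with
  `Q2cum` from 7-group cross-validation (groups assigned round-robin
  after a seeded shuffle). Latent variables are accepted while the
  `Q2cum` gain exceeds 0.01 (a SIMCA-like sequential rule; threshold
  configurable), at least one. Internally the screen uses an exactly
  equivalent kernel-space formulation (one 65x65 Gram matrix per
  preprocessed matrix), which makes the 3 430 model fits of a full
  screen run in about a minute; a test asserts prediction equality with
  the NIPALS path to 1e-8.
* **ANN**: PCA scores (smallest count reaching 99% variance) feed a
  single-hidden-layer perceptron grid — hidden neurons 1..N+1 crossed
  with five hidden and five output activations (identity, logistic,
  tanh, exponential, sine), exactly `25 (N+1)` candidates — trained by
  full-batch gradient descent with momentum on a 70/15/15
  train/test/validation split, early-stopped on test loss. The winner
  maximizes the test-set target/output correlation (ties: fewer
  neurons, then activation order). Exponential activations are clipped
  at |x| = 30 to prevent overflow.

All 490 rows share one 80/20 calibration/validation split, drawn once
per seed and stratified by run so every run informs calibration —
otherwise cells would not be comparable. Metrics (`MAE`, `SD_AE`,
per-sample `AE` and `RE`) are computed on the validation split: the
paper-style tables do not say which side their errors come from, and
the hold-out side is the honest generalization surface
(`metrics_on = "calibration"` is available for parity experiments).
`SD_AE` is the sample standard deviation of the absolute errors; the
population (n-denominator) variant is a switch. A cell whose
preprocessing degenerates (SNV of a constant spectrum, zero peak area)
becomes a failure row with missing metrics — never an abort — so the
factorial design downstream stays as balanced as the data allow.

The raw-cell replicates differ only by their model-fitting seed, which
also reshuffles the CV groups; the resulting spread is the pure-error
estimate the factorial models lean on. With a fully deterministic LV
selection the PLS replicates would be identical and pure error
degenerate, so the CV shuffle is deliberately part of the replicate
seed.

## Factorial modelling and desirability optimization

`code_design()` recodes the four categories as sum-to-zero contrasts
(the DoE-software convention for "coded variables"); the main-effects
design matrix has 16 columns and the full two-factor-interaction model
99, full rank on the 480-cell grid. `fit_metric_model()` fits OLS of a
(possibly transformed) response — `MAE` or `SD_AE` — on main effects
plus all two-factor interactions, then removes terms backwards: the
droppable term with the largest F-test p-value above `alpha = 0.05`
goes first, and `drop1()`'s marginality rule keeps the model
hierarchical. Three-factor interactions are excluded: they are rarely
reported in practice and their omission preserves residual degrees of
freedom. `transform = "auto"` compares none / log / Box-Cox on the
Box-Cox profile likelihood and prefers the simplest transform whose
`lambda` lies inside the 95% profile interval.

Because per-term testing at `alpha` controls each term's false
retention rate — not the family-wise rate — a reduced model will
occasionally carry a spurious interaction (about one in twenty per
term, slightly more for interactions involving a strong factor, since
the ten raw replicates make the design mildly unbalanced). The test
suite asserts exactly these operating characteristics: the true term is
essentially always retained and each null interaction appears at about
the nominal rate.

Optimization is Derringer desirability with minimize goals:
`d = ((U - y)/(U - L))^w` clipped to [0, 1], with `L`/`U` the observed
response minimum/maximum over the screen (the common DoE default) and
`w = 1`; the overall score is `D = (prod d_i^r_i)^(1/sum r_i)` with
importance 5 for `MAE` and 4 for `SD_AE`. Since the factors are
categorical and the space exhaustive, `optimize_combination()` simply
evaluates the fitted models at all 480 cells and returns the argmax of
`D` — over *model predictions*, honouring the two-stage procedure
(predict-then-optimize); the per-cell table is returned as `ramp` for
diagnostics and plotting. In overall mode all parameters' `MAE`
(importance 5) and `SD_AE` (importance 4) models are pooled — 14
responses — each scaled by its own bounds so units never mix.
`compare_individual_vs_overall()` then asks, per parameter, whether the
individually optimal combination has genuinely lower absolute errors
than the overall one: a one-tailed paired Student's t-test on the
validation-sample AE pairs at `alpha = 0.05`.

## The synthetic study

No public spectra exist for this system, so the package ships a
generator that emulates the study design end to end; it is first-class,
tested code, and the conditions below are its defaults.

**Design.** Five batch runs of about 120 h: uninfected (12 samples),
two single infections at TOI 24 h and 36 h (12 and 13 samples), a
pre-infected inoculum (13 samples) and a coinfection (15 samples) — 65
calibration samples. Each calibration spectrum is the mean of 6
consecutive rendered sub-spectra, mimicking pre-sampling averaging of
continuously acquired inline spectra; hourly spectra per run are
rendered separately and never enter calibration.

**Kinetics.** Logistic growth (`mu_max = 0.035 /h`, carrying capacity
`45e5 cells/mL`) with a lytic-arrest switch ~6 h after TOI: growth
stops, viability declines at `0.01 /h`, dying cells leave the viable
pool. Glucose (10 g/L start) and glutamine (1.3 g/L) are consumed
proportionally to viable-cell density; lactate, glutamate and ammonium
are produced with fixed yields. Rates were chosen so glucose is not
exhausted within the batch (realistic for Sf9 in rich serum-free
medium) and no analyte approaches zero — relative errors stay
well-defined. Viability starts at 97% and is monotone non-increasing.
A full virus-dynamics model is out of scope; the arrest switch is
enough to produce infection-shaped profiles.

**Spectra.** Intensity is linear in concentration: each analyte
contributes Gaussian bands at fixed positions (loosely inspired by
known Raman bands, e.g. a glucose band near 1125 cm^-1 — configuration
values, not spectroscopic claims) on the 100-3425 cm^-1 axis at
1 cm^-1. Viable cells enter through a biomass component and viability
through a debris component proportional to the non-viable density, so
both are spectrally identifiable. Degradations, chosen once as the
study conditions: additive detector noise (sd 10 counts), 5%
per-spectrum multiplicative gain, a run-specific degree-5 positive
fluorescence polynomial (scale 800 counts, 25% per-spectrum coefficient
jitter), and a per-spectrum smooth fluorescence drift (sd 80 counts,
120 cm^-1 correlation length). The drift matters: a polynomial
background alone is low-rank across a run and PLS simply absorbs it in
a few latent variables, which would make preprocessing look useless;
independent smooth drift — the spectral signature of photobleaching and
probe fouling — degrades uncorrected spectra in a way only
baseline-type filters undo. Reference assays carry 2% relative noise,
typical of biochemistry-analyzer precision.

**What passing tests do and do not show.** The generator provides
linear mixing, smooth additive interference and well-behaved noise; it
omits water-band distortion, sapphire-window artefacts, cosmic spikes
(instrument-removed), detector nonlinearity and matrix effects. Results
on it validate the *machinery* — that the screen ranks, the factorial
models recover planted structure, the optimizer finds planted optima,
and clean signals are recovered within stated tolerances — not that any
particular filter recipe is best for real instruments.

## Numerical choices and edge cases

* AsLS solves the banded penalized system with sparse Cholesky
  (`Matrix`), iterating weights to `1e-6` with a 50-iteration cap; the
  cap triggers a warning and returns the last iterate (weight
  oscillation on noisy flat regions is a known property of the
  asymmetric weighting). Penalty matrices are cached per
  (length, lambda).
* All windowed operators shrink or polynomial-extend their windows at
  the edges, so output length always equals input length; Savitzky-Golay
  filters reproduce polynomials up to their order exactly, edges
  included.
* PLS rank cutoffs are scale-relative, so combinations that shrink
  spectra to tiny magnitudes (e.g. AsLS-smooth + area-normalize +
  second derivative) remain fittable.
* Degenerate responses (zero variance), insufficient samples for a
  split, and axis mismatches raise classed errors
  (`ramanscreen_*_error`); inside a screen they become failure rows.
* All randomness flows from one master seed through named substreams
  (split / CV / per-cell fit / generator run), so any part of a run can
  be reproduced in isolation; seeds stay below 2^31.

## Problem sizes used in the checks

The package's own test battery runs the full default study (65 samples
x 3326 wavenumbers) through the complete PLS screen (490 cells, 7-group
CV, latent-variable cap 8) plus optimization and hourly simulation in a
few minutes on one CPU; operator- and model-level properties run on
scaled fixtures (a 251-point axis, three runs of seven samples) built
by the same generator. Planted-optimum recovery uses 20 random
constructions over the full 480-cell grid; term-selection operating
characteristics use 100 seeded replicates of the 490-row design; the
null rate of the individual-vs-overall comparison uses 200 replicates.
An ANN screen over all 490 cells is supported but not exercised at full
scale in the tests (a single automated search is — the grid-size and
winner contracts are cheap to verify); screening ANN exhaustively is an
overnight job, which matches how these searches are used in practice.

## Known limitations

* The commercial-software semantics being emulated ("symmetric" EWMA,
  wavelet "mean detrend mode", the exact LV-selection wizard rule, the
  ANN trainer's trajectory) are proprietary; the implementations here
  are documented best-effort equivalents with the knobs exposed.
* PLS is single-response by design (one model per parameter), matching
  the screening procedure; there is no multi-Y mode.
* The desirability bounds come from the observed screen; a screen whose
  models predict outside the observed range is clipped into [0, 1]
  rather than extrapolated.
* The ANN winner is chosen on the test subset's correlation (the
  automated-search convention); choosing on the validation subset
  instead is a one-line change but not currently a switch.
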