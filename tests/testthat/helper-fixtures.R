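# Shared fixtures. Everything is generated in code; the mini study is a
# scaled-down bioprocess (short axis, 3 runs, 2 presample spectra) used
# where the full 65 x 3326 default would be needlessly slow.

mini_axis <- function() seq(300, 800, by = 2) # 251 points

mini_components <- function() {
  tibble::tribble(
    ~analyte, ~center, ~width, ~amplitude, ~response,
    "Gluc_g_L", 420, 8, 1.0, 8,
    "Gluc_g_L", 520, 6, 0.6, 8,
    "Lac_g_L", 470, 7, 1.0, 900,
    "Gln_g_L", 560, 8, 1.0, 180,
    "Glu_g_L", 620, 7, 1.0, 450,
    "NH4_g_L", 680, 9, 1.0, 1400,
    "Xv_1e5_cells_per_mL", 740, 6, 1.0, 7,
    "nonviable_1e5_cells_per_mL", 640, 8, 1.0, 10,
    "water_medium", 760, 30, 1.0, 60
  )
}

mini_config <- function(noise = noise_model(additive_sd = 4,
                                            multiplicative_sd = 0.03,
                                            baseline_scale = 300,
                                            baseline_jitter_sd = 0.15,
                                            drift_sd = 30,
                                            drift_length_cm1 = 60)) {
  study_config(
    runs = list(
      run_config("run1", 7L, scenario = "uninfected", xv0 = 5),
      run_config("run2", 7L, scenario = "single-infection", xv0 = 7, toi_h = 24),
      run_config("run3", 7L, scenario = "coinfection", xv0 = 5, toi_h = 24)
    ),
    components = mini_components(),
    noise = noise,
    axis = mini_axis(),
    n_presample = 2L
  )
}

clean_mini_config <- function() {
  cfg <- mini_config(noise = noise_model(additive_sd = 0,
                                         multiplicative_sd = 0,
                                         baseline_scale = 0,
                                         baseline_jitter_sd = 0,
                                         drift_sd = 0))
  cfg$assay_cv <- 0
  cfg
}

# Memoised mini study + PLS screen so several test files can share one
# computation.
mini_cache <- new.env(parent = emptyenv())

mini_study <- function() {
  if (is.null(mini_cache$study)) mini_cache$study <- generate_study(mini_config(), seed = 11)
  mini_cache$study
}

mini_screen <- function() {
  if (is.null(mini_cache$screen)) {
    st <- mini_study()
    mini_cache$screen <- run_screen(
      st$spectra, st$references, "pls",
      parameters = c("Gluc_g_L", "Lac_g_L"),
      config = screen_config(max_lv = 6), seed = 11)
  }
  mini_cache$screen
}

# Closed-form Savitzky-Golay convolution coefficients from the normal
# equations of the local polynomial fit (independent oracle).
sg_coef_oracle <- function(window, order, deriv = 0) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:order, `^`)
  H <- solve(crossprod(A), t(A))
  H[deriv + 1, ] * factorial(deriv)
}
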