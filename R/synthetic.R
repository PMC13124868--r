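#' Configuration for one synthetic bioreactor run
#'
#' Defaults emulate batch insect-cell (Sf9) culture with baculovirus
#' infection: logistic growth until the time of infection (TOI), then
#' growth arrest and a viability decline (lytic-arrest switch);
#' glucose/glutamine consumed proportionally to the viable-cell
#' integral, lactate/glutamate/ammonium produced with yield
#' coefficients.
#'
#' @param run_id run identifier.
#' @param n_samples number of offline samples collected.
#' @param duration_h batch duration (default 120 h).
#' @param scenario `"uninfected"`, `"single-infection"`,
#'   `"coinfection"` or `"pre-infected-inoculum"`.
#' @param xv0 initial viable cell density (1e5 cells/mL).
#' @param toi_h time of infection (h); ignored when uninfected.
#' @param mu_max maximum specific growth rate (1/h).
#' @param xv_max logistic carrying capacity (1e5 cells/mL).
#' @param q_gluc,q_gln specific consumption rates
#'   (g/L per h per 1e5 cells/mL).
#' @param y_lac_gluc,y_glu_gln,y_nh4_gln product yields (g/g consumed).
#' @param kd_inf post-infection death rate (1/h) driving the viability
#'   decline.
#' @param gluc0,lac0,gln0,glu0,nh40 initial concentrations (g/L).
#' @param cv0 initial viability (%).
#' @return a list of class `run_config`.
#' @export
run_config <- function(run_id = "run1", n_samples = 12L, duration_h = 120,
                       scenario = c("uninfected", "single-infection",
                                    "coinfection", "pre-infected-inoculum"),
                       xv0 = 5, toi_h = 24, mu_max = 0.035, xv_max = 45,
                       q_gluc = 2.4e-3, q_gln = 4.5e-4,
                       y_lac_gluc = 0.05, y_glu_gln = 0.45, y_nh4_gln = 0.25,
                       kd_inf = 0.010,
                       gluc0 = 10, lac0 = 0.02, gln0 = 1.3, glu0 = 0.35,
                       nh40 = 0.04, cv0 = 97) {
  scenario <- match.arg(scenario)
  if (n_samples < 2L) abort("n_samples must be >= 2",
                            class = "ramanscreen_parameter_error")
  structure(
    list(run_id = run_id, n_samples = as.integer(n_samples),
         duration_h = duration_h, scenario = scenario, xv0 = xv0,
         toi_h = toi_h, mu_max = mu_max, xv_max = xv_max,
         q_gluc = q_gluc, q_gln = q_gln, y_lac_gluc = y_lac_gluc,
         y_glu_gln = y_glu_gln, y_nh4_gln = y_nh4_gln, kd_inf = kd_inf,
         gluc0 = gluc0, lac0 = lac0, gln0 = gln0, glu0 = glu0,
         nh40 = nh40, cv0 = cv0),
    class = "run_config"
  )
}

#' Simulate the biochemical time courses of one run
#'
#' Euler integration (0.1 h internal step) of the growth/consumption
#' kinetics in [run_config()], reported on a 1 h grid. Viable cell
#' density follows logistic growth; infected scenarios switch to
#' growth arrest at TOI (plus a 6 h lag) after which viability declines
#' and dying cells leave the viable pool. All trajectories are clamped
#' non-negative; consumption stops when a nutrient is exhausted.
#'
#' @param run a [run_config()].
#' @return a tibble: `time_h` plus the seven parameter columns.
#' @export
simulate_kinetics <- function(run) {
  stopifnot(inherits(run, "run_config"))
  dt <- 0.1
  times <- seq(0, run$duration_h, by = dt)
  arrest_t <- switch(run$scenario,
    "uninfected" = Inf,
    "pre-infected-inoculum" = 6,
    run$toi_h + 6) # infection takes hold ~6 h after TOI
  xv <- run$xv0; v <- run$cv0 / 100
  gluc <- run$gluc0; lac <- run$lac0; gln <- run$gln0
  glu <- run$glu0; nh4 <- run$nh40
  out <- matrix(NA_real_, length(times), 8L)
  for (i in seq_along(times)) {
    t <- times[i]
    out[i, ] <- c(t, xv, 100 * v, gluc, lac, gln, glu, nh4)
    infected <- t >= arrest_t
    mu <- if (infected) 0 else run$mu_max * (1 - xv / run$xv_max)
    kd <- if (infected) run$kd_inf else 0
    xv_viable <- xv * v
    d_gluc <- if (gluc > 0) run$q_gluc * xv_viable else 0
    d_gln <- if (gln > 0) run$q_gln * xv_viable else 0
    xv <- max(xv + (mu - kd / 2) * xv * dt, 0)
    v <- min(max(v - kd * v * dt, 0), 1)
    gluc <- max(gluc - d_gluc * dt, 0)
    gln <- max(gln - d_gln * dt, 0)
    lac <- lac + run$y_lac_gluc * d_gluc * dt
    glu <- glu + run$y_glu_gln * d_gln * dt
    nh4 <- nh4 + run$y_nh4_gln * d_gln * dt
  }
  hourly <- out[times %% 1 < dt / 2, , drop = FALSE]
  colnames(hourly) <- c("time_h", reference_parameters())
  tibble::as_tibble(hourly)
}

#' Component spectra for the synthetic mixing model
#'
#' Each analyte contributes a sum of Gaussian bands, linear in
#' concentration. Band positions are loosely inspired by known Raman
#' bands (e.g. a glucose band near 1125 cm^-1) but are configuration
#' values, not spectroscopic claims: the pipeline must work for any
#' layout. Viable cell density enters through a biomass component
#' (protein/lipid-like bands) and viability through a debris component
#' proportional to the non-viable cell density, which makes both
#' predictable from spectra.
#'
#' @return a tibble: `analyte, center, width, amplitude, response`.
#' @export
component_library <- function() {
  tibble::tribble(
    ~analyte, ~center, ~width, ~amplitude, ~response,
    "Gluc_g_L", 915, 12, 0.6, 8,
    "Gluc_g_L", 1060, 10, 0.8, 8,
    "Gluc_g_L", 1125, 10, 1.0, 8,
    "Lac_g_L", 830, 10, 0.8, 900,
    "Lac_g_L", 1045, 12, 1.0, 900,
    "Gln_g_L", 1090, 14, 1.0, 180,
    "Gln_g_L", 1410, 12, 0.5, 180,
    "Glu_g_L", 870, 10, 0.9, 450,
    "Glu_g_L", 1350, 14, 0.6, 450,
    "NH4_g_L", 1450, 18, 1.0, 1400,
    "Xv_1e5_cells_per_mL", 1004, 8, 1.0, 7,
    "Xv_1e5_cells_per_mL", 1660, 20, 0.7, 7,
    "Xv_1e5_cells_per_mL", 2935, 30, 0.9, 7,
    "nonviable_1e5_cells_per_mL", 1260, 16, 1.0, 10,
    "nonviable_1e5_cells_per_mL", 1745, 12, 0.6, 10,
    "water_medium", 1640, 60, 0.5, 60,
    "water_medium", 3200, 180, 1.0, 60
  )
}

#' Detector and background noise model
#'
#' @param additive_sd additive detector noise sd (counts).
#' @param multiplicative_sd per-spectrum multiplicative gain sd
#'   (fraction), applied to the chemical signal — the scatter the MSC /
#'   SNV filters exist to remove.
#' @param baseline_degree fluorescence background polynomial degree.
#' @param baseline_scale overall background magnitude (counts).
#' @param baseline_jitter_sd per-spectrum jitter of the background
#'   coefficients (fraction of each coefficient).
#' @param drift_sd,drift_length_cm1 per-spectrum smooth fluorescence
#'   drift: Gaussian noise smoothed to a correlation length of
#'   `drift_length_cm1` (cm^-1) and rescaled to sd `drift_sd` (counts).
#'   Unlike the polynomial background it is independent across
#'   spectra and not low-rank, so it degrades uncorrected models the
#'   way real fluorescence drift does while remaining removable by
#'   baseline filters.
#' @param spike_rate expected cosmic-spike count per spectrum (default
#'   0: the instrument removes them).
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 10, multiplicative_sd = 0.05,
                        baseline_degree = 5L, baseline_scale = 800,
                        baseline_jitter_sd = 0.25,
                        drift_sd = 80, drift_length_cm1 = 120,
                        spike_rate = 0) {
  stopifnot(additive_sd >= 0, multiplicative_sd >= 0, baseline_jitter_sd >= 0,
            drift_sd >= 0, drift_length_cm1 > 0)
  structure(
    list(additive_sd = additive_sd, multiplicative_sd = multiplicative_sd,
         baseline_degree = as.integer(baseline_degree),
         baseline_scale = baseline_scale,
         baseline_jitter_sd = baseline_jitter_sd,
         drift_sd = drift_sd, drift_length_cm1 = drift_length_cm1,
         spike_rate = spike_rate),
    class = "noise_model"
  )
}

# Smooth per-spectrum drift: white noise convolved with a Gaussian
# kernel, rescaled to the requested sd. Drawn from the current RNG.
smooth_drift <- function(n, step, sd_target, length_cm1) {
  if (sd_target <= 0) return(numeric(n))
  half <- max(3L, ceiling(1.5 * length_cm1 / step))
  kern <- exp(-0.5 * (seq(-half, half) * step / (length_cm1 / 2))^2)
  kern <- kern / sum(kern)
  x <- rnorm(n + 2L * half)
  sm <- as.numeric(stats::filter(x, kern, sides = 2L))
  sm <- sm[(half + 1L):(half + n)]
  sm * sd_target / stats::sd(sm)
}

# Gaussian band profile matrix: one row per library entry.
component_profiles <- function(components, axis) {
  prof <- matrix(0, nrow(components), length(axis))
  for (i in seq_len(nrow(components))) {
    prof[i, ] <- components$amplitude[i] *
      exp(-0.5 * ((axis - components$center[i]) / components$width[i])^2)
  }
  prof
}

# Per-run fluorescence baseline coefficients (degree-3 polynomial in
# scaled wavenumber), drawn once per run. Fluorescence adds counts, so
# the curve is shifted to stay positive with headroom for the
# per-spectrum jitter.
run_baseline_coefs <- function(noise, seed) {
  with_seed(seed, {
    c0 <- runif(noise$baseline_degree + 1L, -1, 1)
  })
  coefs <- c0 * noise$baseline_scale / seq_len(noise$baseline_degree + 1L)
  u <- seq(0, 1, length.out = 201L)
  curve <- as.numeric(outer(u, seq_along(coefs) - 1L, `^`) %*% coefs)
  coefs[1L] <- coefs[1L] - min(curve) + 0.15 * noise$baseline_scale
  coefs
}

eval_baseline <- function(coefs, axis) {
  u <- (axis - min(axis)) / diff(range(axis)) # scaled to [0, 1]
  as.numeric(outer(u, seq_along(coefs) - 1L, `^`) %*% coefs)
}

#' Render one synthetic Raman spectrum
#'
#' `intensity = sum(conc * response * bands) * gain + baseline + noise`:
#' linear concentration-to-intensity mixing, a per-spectrum
#' multiplicative gain perturbation, a slowly varying polynomial
#' fluorescence background (jittered per spectrum) and additive
#' Gaussian detector noise. Deterministic for a given seed.
#'
#' @param concentrations named numeric vector (names matching
#'   `components$analyte`).
#' @param components component tibble (see [component_library()]).
#' @param noise a [noise_model()].
#' @param axis wavenumber axis.
#' @param seed integer seed.
#' @param baseline_coefs per-run background coefficients
#'   ([run_baseline_coefs()]); `NULL` = no background.
#' @return numeric intensity vector.
#' @export
render_spectrum <- function(concentrations, components = component_library(),
                            noise = noise_model(), axis = default_axis(),
                            seed = 1L, baseline_coefs = NULL) {
  prof <- component_profiles(components, axis)
  conc <- concentrations[components$analyte]
  conc[is.na(conc)] <- 0
  signal <- as.numeric(crossprod(prof, conc * components$response))
  with_seed(seed, {
    gain <- 1 + rnorm(1L, 0, noise$multiplicative_sd)
    base <- if (is.null(baseline_coefs)) 0 else {
      jit <- 1 + rnorm(length(baseline_coefs), 0, noise$baseline_jitter_sd)
      eval_baseline(baseline_coefs * jit, axis)
    }
    eps <- if (noise$additive_sd > 0) rnorm(length(axis), 0, noise$additive_sd) else 0
    drift <- smooth_drift(length(axis), axis[2L] - axis[1L],
                          noise$drift_sd, noise$drift_length_cm1)
    spikes <- 0
    if (noise$spike_rate > 0) {
      k <- stats::rpois(1L, noise$spike_rate)
      if (k > 0) {
        spikes <- numeric(length(axis))
        spikes[sample.int(length(axis), k)] <- runif(k, 5, 50) * noise$additive_sd
      }
    }
    signal * gain + base + drift + eps + spikes
  })
}

#' Study-level configuration
#'
#' The five-run default design: one uninfected run (12 samples), two
#' single-infection runs (12 and 13 samples), one pre-infected-inoculum
#' run (13 samples) and one coinfection run (15 samples) — 65 samples
#' in total over ~120 h each.
#'
#' @param runs list of [run_config()]s.
#' @param components component tibble.
#' @param noise a [noise_model()].
#' @param axis wavenumber axis.
#' @param n_presample number of consecutive spectra averaged per
#'   calibration point (default 6).
#' @param assay_cv relative sd of the offline reference assays
#'   (default 0.02).
#' @return a list of class `study_config`.
#' @export
study_config <- function(runs = NULL, components = component_library(),
                         noise = noise_model(), axis = default_axis(),
                         n_presample = 6L, assay_cv = 0.02) {
  if (is.null(runs)) {
    runs <- list(
      run_config("run1", 12L, scenario = "uninfected", xv0 = 5),
      run_config("run2", 12L, scenario = "single-infection", xv0 = 7.4,
                 toi_h = 24),
      run_config("run3", 13L, scenario = "single-infection", xv0 = 7.2,
                 toi_h = 36),
      run_config("run4", 13L, scenario = "pre-infected-inoculum", xv0 = 7.2),
      run_config("run5", 15L, scenario = "coinfection", xv0 = 5, toi_h = 24)
    )
  }
  structure(
    list(runs = runs, components = components, noise = noise, axis = axis,
         n_presample = as.integer(n_presample), assay_cv = assay_cv),
    class = "study_config"
  )
}

#' Generate the full synthetic study
#'
#' For each run: simulate the kinetics, choose `n_samples` sampling
#' moments spread over the batch, render `n_presample` consecutive raw
#' spectra (30 s apart) before each moment and average them into the
#' calibration spectrum, and perturb the true concentrations with
#' assay noise to produce the offline reference table. Hourly spectra
#' per run (never used in calibration) are rendered for profile
#' simulation.
#'
#' @param config a [study_config()].
#' @param seed master seed; every random draw derives from it.
#' @return a list of class `synthetic_study`: `spectra` (the 65-sample
#'   calibration [spectral_dataset()]), `references` (tibble),
#'   `hourly` (named list of per-run `spectral_dataset`s), `truth`
#'   (named list of per-run hourly kinetics tibbles) and `config`.
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  axis <- config$axis
  all_spec <- list(); all_ref <- list(); hourly <- list(); truth <- list()
  for (run in config$runs) {
    kin <- simulate_kinetics(run)
    truth[[run$run_id]] <- kin
    run_seed <- derive_seed(seed, paste0("run_", run$run_id))
    base_coefs <- run_baseline_coefs(config$noise,
                                     derive_seed(run_seed, "baseline"))
    # sampling moments: evenly spread, skipping the first hours
    st <- round(seq(4, run$duration_h - 2, length.out = run$n_samples))
    conc_at <- function(t) {
      row <- kin[which.min(abs(kin$time_h - t)), ]
      c(Gluc_g_L = row$Gluc_g_L, Lac_g_L = row$Lac_g_L, Gln_g_L = row$Gln_g_L,
        Glu_g_L = row$Glu_g_L, NH4_g_L = row$NH4_g_L,
        Xv_1e5_cells_per_mL = row$Xv_1e5_cells_per_mL,
        nonviable_1e5_cells_per_mL =
          row$Xv_1e5_cells_per_mL * (1 - row$CV_pct / 100),
        water_medium = 1)
    }
    cal_mat <- matrix(NA_real_, run$n_samples, length(axis))
    for (k in seq_len(run$n_samples)) {
      conc <- conc_at(st[k])
      subs <- vapply(seq_len(config$n_presample), function(j) {
        render_spectrum(conc, config$components, config$noise, axis,
                        seed = derive_seed(run_seed, paste0("s", st[k], "_", j)),
                        baseline_coefs = base_coefs)
      }, numeric(length(axis)))
      cal_mat[k, ] <- rowMeans(subs)
    }
    sample_ids <- sprintf("%s_s%02d", run$run_id, seq_len(run$n_samples))
    all_spec[[run$run_id]] <- spectral_dataset(cal_mat, axis, sample_ids,
                                               run$run_id, st)
    truth_rows <- kin[match(st, kin$time_h), ]
    noisy <- truth_rows
    with_seed(derive_seed(run_seed, "assay"), {
      for (p in reference_parameters()) {
        noisy[[p]] <- pmax(truth_rows[[p]] *
                             (1 + rnorm(nrow(truth_rows), 0, config$assay_cv)), 0)
      }
    })
    noisy$CV_pct <- pmin(noisy$CV_pct, 100)
    all_ref[[run$run_id]] <- dplyr::bind_cols(
      tibble::tibble(sample_id = sample_ids, run_id = run$run_id,
                     time_h = st),
      noisy[reference_parameters()]
    )
    hh <- kin$time_h
    h_mat <- matrix(NA_real_, length(hh), length(axis))
    for (k in seq_along(hh)) {
      h_mat[k, ] <- render_spectrum(conc_at(hh[k]), config$components,
                                    config$noise, axis,
                                    seed = derive_seed(run_seed, paste0("h", hh[k])),
                                    baseline_coefs = base_coefs)
    }
    hourly[[run$run_id]] <- spectral_dataset(
      h_mat, axis, sprintf("%s_h%03d", run$run_id, hh), run$run_id, hh)
  }
  spectra <- do.call(rbind_spectra, unname(all_spec))
  structure(
    list(spectra = spectra, references = dplyr::bind_rows(all_ref),
         hourly = hourly, truth = truth, config = config, seed = seed),
    class = "synthetic_study"
  )
}

# Row-bind spectral datasets sharing an axis.
rbind_spectra <- function(...) {
  ds <- list(...)
  axis <- ds[[1L]]$wavenumbers
  for (d in ds) stopifnot(identical(d$wavenumbers, axis))
  spectral_dataset(
    do.call(rbind, lapply(ds, function(d) d$intensities)), axis,
    unlist(lapply(ds, function(d) d$samples$sample_id)),
    unlist(lapply(ds, function(d) d$samples$run_id)),
    unlist(lapply(ds, function(d) d$samples$time_h))
  )
}

#' @exportS3Method base::print
print.synthetic_study <- function(x, ...) {
  counts <- table(x$spectra$samples$run_id)
  cat(sprintf("<synthetic_study> %d calibration spectra over %d runs (%s)\n",
              nrow(x$spectra$intensities), length(counts),
              paste(counts, collapse = "/")))
  invisible(x)
}

#' Synthesize a screen table with a planted optimum
#'
#' Builds a 490-row-per-parameter metrics table over all 480 cells
#' where `winner` has strictly minimal MAE and SD_AE for every
#' parameter: additive positive factor effects (zero for the winner's
#' levels), pairwise-interaction-free, plus seeded noise kept small
#' relative to the effect gaps. Used as a constructed oracle for the
#' factorial-model + desirability optimizer chain.
#'
#' @param winner a one-row combination tibble or label string.
#' @param parameters parameter names (default two, enough to exercise
#'   both optimization modes).
#' @param base baseline MAE at the winner cell.
#' @param effect_gap minimum main-effect penalty of a non-winner level.
#' @param noise_sd response noise sd (0 = exact construction).
#' @param seed integer seed.
#' @return a `screen_table`-shaped tibble (no nested errors).
#' @export
planted_screen <- function(winner, parameters = c("Gluc_g_L", "Lac_g_L"),
                           base = 0.5, effect_gap = 0.25, noise_sd = 0.02,
                           seed = 1L) {
  if (is.character(winner)) winner <- parse_combination(winner)
  winner <- tibble::as_tibble(as.list(winner)[c("smoothing", "baseline",
                                                "normalization", "other")])
  lv <- filter_levels()
  plan <- enumerate_screen(10L)
  out <- purrr::map_dfr(parameters, function(param) {
    eff <- with_seed(derive_seed(seed, paste0("effects_", param)), {
      lapply(names(lv), function(cat) {
        e <- effect_gap * (1 + runif(length(lv[[cat]])))
        e[lv[[cat]] == winner[[cat]]] <- 0
        rlang::set_names(e, lv[[cat]])
      }) |> rlang::set_names(names(lv))
    })
    mae_v <- base +
      eff$smoothing[plan$smoothing] + eff$baseline[plan$baseline] +
      eff$normalization[plan$normalization] + eff$other[plan$other]
    sd_v <- 0.6 * mae_v
    if (noise_sd > 0) {
      with_seed(derive_seed(seed, paste0("noise_", param)), {
        mae_v <- mae_v + rnorm(length(mae_v), 0, noise_sd)
        sd_v <- sd_v + rnorm(length(sd_v), 0, noise_sd)
      })
      mae_v <- pmax(mae_v, 1e-4)
      sd_v <- pmax(sd_v, 1e-4)
    }
    tibble::tibble(
      parameter = param, technique = "pls",
      smoothing = plan$smoothing, baseline = plan$baseline,
      normalization = plan$normalization, other = plan$other,
      label = plan$label, repetition = plan$repetition,
      model_size = NA_integer_, n_eval = 13L,
      mae = as.numeric(mae_v), sd_ae = as.numeric(sd_v), failed = FALSE
    )
  })
  attr(out, "winner") <- combination_label(winner)
  class(out) <- c("screen_table", class(out))
  out
}
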