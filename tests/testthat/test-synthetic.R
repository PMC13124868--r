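test_that("kinetics obey the configured consumption structure", {
  # zero rates: concentrations are constant
  rc <- run_config("r", 5L, scenario = "uninfected", q_gluc = 0, q_gln = 0)
  kin <- simulate_kinetics(rc)
  expect_equal(unique(kin$Gluc_g_L), rc$gluc0)
  expect_equal(unique(kin$Lac_g_L), rc$lac0)
  expect_equal(unique(kin$NH4_g_L), rc$nh40)
  # glucose never increases, in every default scenario
  for (sc in c("uninfected", "single-infection", "coinfection",
               "pre-infected-inoculum")) {
    k <- simulate_kinetics(run_config("r", 5L, scenario = sc))
    expect_true(all(diff(k$Gluc_g_L) <= 1e-12), info = sc)
    expect_true(all(k$CV_pct >= 0 & k$CV_pct <= 100), info = sc)
    expect_true(all(diff(k$CV_pct) <= 1e-9), info = sc) # non-increasing
    expect_true(all(as.matrix(k[-1]) >= 0), info = sc)
  }
})

test_that("lactate production balances glucose consumption", {
  rc <- run_config("r", 5L, scenario = "uninfected", q_gln = 0,
                   y_lac_gluc = 0.3)
  kin <- simulate_kinetics(rc)
  d_gluc <- rc$gluc0 - kin$Gluc_g_L[nrow(kin)]
  d_lac <- kin$Lac_g_L[nrow(kin)] - rc$lac0
  expect_gt(d_gluc, 0.5) # the pathway actually ran
  expect_equal(d_lac, 0.3 * d_gluc, tolerance = 1e-8)
})

test_that("spectral rendering is linear in concentration and seeded", {
  ax <- mini_axis()
  comps <- mini_components()
  silent <- noise_model(additive_sd = 0, multiplicative_sd = 0,
                        baseline_scale = 0, baseline_jitter_sd = 0,
                        drift_sd = 0)
  conc0 <- c(Gluc_g_L = 0, Lac_g_L = 0, Gln_g_L = 0, Glu_g_L = 0,
             NH4_g_L = 0, Xv_1e5_cells_per_mL = 0,
             nonviable_1e5_cells_per_mL = 0, water_medium = 0)
  expect_equal(render_spectrum(conc0, comps, silent, ax, seed = 1),
               numeric(length(ax)))
  c1 <- conc0; c1[["Gluc_g_L"]] <- 5
  c2 <- conc0; c2[["Gluc_g_L"]] <- 10
  s1 <- render_spectrum(c1, comps, silent, ax, seed = 1)
  s2 <- render_spectrum(c2, comps, silent, ax, seed = 1)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # determinism per seed
  noisy <- noise_model(additive_sd = 3, baseline_scale = 100)
  expect_identical(render_spectrum(c1, comps, noisy, ax, seed = 9),
                   render_spectrum(c1, comps, noisy, ax, seed = 9))
  expect_false(identical(render_spectrum(c1, comps, noisy, ax, seed = 9),
                         render_spectrum(c1, comps, noisy, ax, seed = 10)))
})

test_that("rendered detector noise matches its configured scale", {
  ax <- mini_axis()
  comps <- mini_components()
  nm <- noise_model(additive_sd = 3, multiplicative_sd = 0,
                    baseline_scale = 0, baseline_jitter_sd = 0, drift_sd = 0)
  conc <- c(Gluc_g_L = 5, water_medium = 1)
  base <- render_spectrum(conc, comps,
                          noise_model(additive_sd = 0, multiplicative_sd = 0,
                                      baseline_scale = 0, drift_sd = 0),
                          ax, seed = 1)
  resid <- vapply(1:500, function(s) {
    render_spectrum(conc, comps, nm, ax, seed = s)[100] - base[100]
  }, numeric(1))
  expect_lt(abs(sd(resid) - 3) / 3, 0.2)
})

test_that("the default study reproduces the five-run sampling design", {
  study <- generate_study(seed = 2)
  counts <- table(study$spectra$samples$run_id)
  expect_equal(unname(as.integer(counts)), c(12L, 12L, 13L, 13L, 15L))
  expect_equal(nrow(study$references), 65L)
  expect_equal(nrow(study$spectra$intensities), 65L)
  expect_identical(study$spectra$samples$sample_id, study$references$sample_id)
  expect_length(study$hourly, 5L)
  # reproducibility: identical output for the same master seed
  again <- generate_study(seed = 2)
  expect_identical(study$spectra$intensities, again$spectra$intensities)
  expect_identical(study$references, again$references)
})

test_that("each calibration spectrum is the mean of the presample renders", {
  cfg <- mini_config()
  study <- generate_study(cfg, seed = 5)
  run <- cfg$runs[[1]]
  kin <- study$truth[[run$run_id]]
  run_seed <- ramanscreen:::derive_seed(5, paste0("run_", run$run_id))
  base_coefs <- ramanscreen:::run_baseline_coefs(
    cfg$noise, ramanscreen:::derive_seed(run_seed, "baseline"))
  st <- study$spectra$samples$time_h[1]
  row <- kin[which.min(abs(kin$time_h - st)), ]
  conc <- c(Gluc_g_L = row$Gluc_g_L, Lac_g_L = row$Lac_g_L,
            Gln_g_L = row$Gln_g_L, Glu_g_L = row$Glu_g_L,
            NH4_g_L = row$NH4_g_L,
            Xv_1e5_cells_per_mL = row$Xv_1e5_cells_per_mL,
            nonviable_1e5_cells_per_mL =
              row$Xv_1e5_cells_per_mL * (1 - row$CV_pct / 100),
            water_medium = 1)
  subs <- vapply(seq_len(cfg$n_presample), function(j) {
    render_spectrum(conc, cfg$components, cfg$noise, cfg$axis,
                    seed = ramanscreen:::derive_seed(run_seed,
                                                     paste0("s", st, "_", j)),
                    baseline_coefs = base_coefs)
  }, numeric(length(cfg$axis)))
  expect_equal(study$spectra$intensities[1, ], rowMeans(subs),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise- and baseline-free spectra are PLS-identifiable", {
  if (is.null(mini_cache$clean_study)) {
    mini_cache$clean_study <- generate_study(clean_mini_config(), seed = 21)
  }
  st <- mini_cache$clean_study
  X <- st$spectra$intensities
  n_analytes <- dplyr::n_distinct(mini_components()$analyte)
  for (p in c("Gluc_g_L", "Lac_g_L", "Gln_g_L")) {
    y <- st$references[[p]]
    m <- fit_pls(X, y, max_lv = n_analytes, cv_groups = 5, q2_gain = -Inf,
                 seed = 1)
    expect_gte(max(m$r2cum), 0.999)
  }
})

test_that("planted screens have their designed structure", {
  winner <- "smoothing=MW,baseline=offset,norm=none,other=none"
  exact <- planted_screen(winner, parameters = "Gluc_g_L", noise_sd = 0,
                          seed = 3)
  expect_equal(nrow(exact), 490L)
  w_rows <- exact$label == winner
  expect_equal(min(exact$mae[w_rows]), min(exact$mae))
  expect_equal(sum(exact$mae == min(exact$mae)), sum(w_rows)) # unique min cell
  # different seeds: different noise, same winner
  a <- planted_screen(winner, parameters = "Gluc_g_L", seed = 4)
  b <- planted_screen(winner, parameters = "Gluc_g_L", seed = 5)
  expect_false(identical(a$mae, b$mae))
  expect_identical(attr(a, "winner"), attr(b, "winner"))
  # the factorial model recovers the planted smoothing effects: the
  # winner's level has the smallest estimated cell mean in each category
  fit <- fit_metric_model(code_design(a), "mae", transform = "none")
  pred <- predict(fit, filter_combinations())
  expect_equal(filter_combinations()$label[which.min(pred)], winner)
})
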