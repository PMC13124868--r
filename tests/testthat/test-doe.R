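test_that("factor coding is sum-to-zero over the balanced grid", {
  coded <- code_design(filter_combinations() |>
                         dplyr::mutate(mae = 1, sd_ae = 1))
  mm <- stats::model.matrix(~ smoothing + baseline + normalization + other,
                            data = coded)
  expect_equal(ncol(mm), 16L) # 1 + 5 + 4 + 3 + 3
  expect_equal(max(abs(colSums(mm[, -1]))), 0)
  mm2 <- stats::model.matrix(
    ~ (smoothing + baseline + normalization + other)^2, data = coded)
  expect_equal(qr(mm2)$rank, ncol(mm2)) # full rank incl. interactions
})

test_that("a noiseless contrast-built response is recovered exactly", {
  coded <- code_design(filter_combinations() |>
                         dplyr::mutate(mae = 0, sd_ae = 0))
  mm <- stats::model.matrix(~ smoothing + baseline + normalization + other,
                            data = coded)
  beta <- c(2, 0.5, -0.3, 0.2, 0.1, -0.4, 0.25, -0.15, 0.05, 0.3,
            -0.2, 0.1, 0.15, 0.4, -0.1, 0.2)
  coded$mae <- as.numeric(mm %*% beta) + 10 # keep positive
  fit <- fit_metric_model(coded, "mae", transform = "none")
  # exact recovery: model predictions reproduce the constructed response
  expect_equal(predict(fit, filter_combinations()), coded$mae,
               tolerance = 1e-8)
  got <- coef(fit$fit)
  main <- setdiff(intersect(names(got), colnames(mm)), "(Intercept)")
  expect_equal(unname(got[main]), unname(beta[match(main, colnames(mm))]),
               tolerance = 1e-8)
})

test_that("backward elimination keeps true terms and drops noise terms", {
  set.seed(40)
  plan <- enumerate_screen()
  eff <- c(SG = 0, EWMA = 0.4, WDS = 0.1, MW = 0.6, AsLS = 0.3, none = 0.8)
  coded <- plan |>
    dplyr::mutate(mae = 1 + eff[.data$smoothing] + rnorm(dplyr::n(), 0, 0.1),
                  sd_ae = .data$mae)
  fit <- fit_metric_model(code_design(coded), "mae", transform = "none")
  expect_true("smoothing" %in% fit$terms)
  expect_false(any(c("baseline", "normalization", "other") %in% fit$terms))
})

test_that("log transform is selected for a multiplicative response", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    plan <- filter_combinations()
    eff <- c(SG = 0, EWMA = 1, WDS = 0.2, MW = 1.5, AsLS = 0.7, none = 2)
    lp <- 0.5 + eff[plan$smoothing]
    plan$mae <- exp(lp + rnorm(nrow(plan), 0, 0.3))
    plan$sd_ae <- plan$mae
    fit <- fit_metric_model(code_design(plan), "mae", transform = "auto")
    fit$transform$name == "log"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("desirability follows the Derringer closed form", {
  # both responses at their lower bound: fully desirable
  expect_equal(desirability(c(1, 2), lower = c(1, 2), upper = c(3, 6))$D, 1)
  # any response at/above its upper bound zeroes the overall score
  d0 <- desirability(c(3, 2), lower = c(1, 1), upper = c(3, 6))
  expect_equal(d0$d[1], 0)
  expect_equal(d0$D, 0)
  # d = (1, 0.5), importances (5, 4): D = (1^5 * 0.5^4)^(1/9)
  mid <- desirability(c(1, 4), lower = c(1, 2), upper = c(3, 6),
                      importance = c(5, 4))
  expect_equal(mid$d, c(1, 0.5))
  expect_equal(mid$D, (1^5 * 0.5^4)^(1 / 9), tolerance = 1e-12)
  expect_equal(mid$D, 0.7348672, tolerance = 1e-6)
  expect_error(desirability(1, lower = 2, upper = 2),
               class = "ramanscreen_parameter_error")
})

test_that("desirability is invariant to affine rescaling of a response", {
  set.seed(41)
  y <- runif(5, 1, 3)
  d1 <- desirability(y, lower = rep(1, 5), upper = rep(3, 5),
                     importance = c(5, 4, 3, 2, 1))
  d2 <- desirability(10 * y + 2, lower = rep(12, 5), upper = rep(32, 5),
                     importance = c(5, 4, 3, 2, 1))
  expect_equal(d1$D, d2$D, tolerance = 1e-12)
})

test_that("optimization over two cells equals direct comparison", {
  cells <- filter_combinations()[c(1, 480), ]
  scr <- planted_screen(cells$label[1], parameters = "Gluc_g_L",
                        noise_sd = 0, seed = 1)
  coded <- code_design(scr)
  m <- fit_metric_model(coded, "mae", transform = "none")
  res <- optimize_combination(list(mae = m), cells = cells)
  pred <- predict(m, cells)
  expect_equal(res$best$label, cells$label[which.min(pred)])
  # returned D is consistent with recomputing from the returned cell
  again <- desirability(res$predicted, lower = res$bounds$lower,
                        upper = res$bounds$upper,
                        importance = unname(res$importance))
  expect_equal(res$D, again$D, tolerance = 1e-12)
})

test_that("planted optima are recovered in individual and overall modes", {
  set.seed(42)
  grid <- filter_combinations()
  for (s in 1:5) {
    winner <- grid[sample.int(480, 1), ]
    scr <- planted_screen(winner, parameters = c("Gluc_g_L", "Lac_g_L"),
                          noise_sd = 0.02, seed = s)
    coded <- code_design(scr)
    models <- list()
    for (p in c("Gluc_g_L", "Lac_g_L")) {
      d <- dplyr::filter(coded, .data$parameter == p)
      res_i <- optimize_combination(list(
        mae = fit_metric_model(d, "mae", transform = "none"),
        sd_ae = fit_metric_model(d, "sd_ae", transform = "none")))
      expect_equal(res_i$best$label, winner$label)
      models[[paste0(p, ".mae")]] <- fit_metric_model(d, "mae", transform = "none")
      models[[paste0(p, ".sd_ae")]] <- fit_metric_model(d, "sd_ae", transform = "none")
    }
    res_o <- optimize_combination(models)
    expect_equal(res_o$best$label, winner$label)
  }
})

test_that("individual-vs-overall comparison flags a planted AE shift", {
  scr <- mini_screen()
  labs <- unique(scr$label)[1:2]
  # identical combinations: nothing to flag
  fake_res <- function(lab) {
    structure(list(best = tibble::tibble(label = lab)),
              class = "desirability_result")
  }
  same <- compare_individual_vs_overall(
    scr, list(Gluc_g_L = fake_res(labs[1])), fake_res(labs[1]))
  expect_false(same$individual_lower[1])
  # construct a screen where the overall label's AE is shifted +1
  base_errors <- scr$errors[[which(scr$label == labs[1] &
                                     scr$parameter == "Gluc_g_L" &
                                     scr$repetition == 1)]]
  shifted <- base_errors
  shifted$ae <- shifted$ae + 1
  scr2 <- scr
  k <- which(scr2$label == labs[2] & scr2$parameter == "Gluc_g_L" &
               scr2$repetition == 1)
  scr2$errors[[k]] <- shifted
  j <- which(scr2$label == labs[1] & scr2$parameter == "Gluc_g_L" &
               scr2$repetition == 1)
  scr2$errors[[j]] <- base_errors
  out <- compare_individual_vs_overall(
    scr2, list(Gluc_g_L = fake_res(labs[1])), fake_res(labs[2]))
  expect_true(out$individual_lower[1])
  expect_lt(out$p_value[1], 0.05)
})
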