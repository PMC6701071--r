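test_that("loss is the sum of squared prevalence errors", {
  sim <- data.frame(year = 2000:2001, prevalence = c(0.12, 0.18))
  hist <- data.frame(year = 2000:2001, cohort = "AVERAGED",
                     prevalence = c(0.10, 0.20))
  expect_equal(loss(sim, hist), 0.0008)
  # exact match -> 0
  expect_equal(loss(sim, transform(hist, prevalence = sim$prevalence)), 0)
  # constant offset over n years -> n * delta^2
  n <- 10; delta <- 0.03
  sim_n <- data.frame(year = 2000:2009, prevalence = rep(0.1, n))
  hist_n <- data.frame(year = 2000:2009, cohort = "AVERAGED",
                       prevalence = rep(0.1 + delta, n))
  expect_equal(loss(sim_n, hist_n), n * delta^2)
  # invariant to record order
  shuffled <- hist_n[sample(n), ]
  expect_equal(loss(sim_n, shuffled), loss(sim_n, hist_n))
  # coverage error
  expect_error(loss(sim, data.frame(year = 1990, cohort = "AVERAGED",
                                    prevalence = 0.1)), "cover")
})

test_that("loss matches trajectories by cohort", {
  tr <- base_trajectory()
  hist <- data.frame(year = c(2000, 2000, 2000),
                     cohort = c("MIDDLE", "HIGH", "AVERAGED"),
                     prevalence = c(traj_value(tr, "prevalence.MIDDLE", 2000),
                                    traj_value(tr, "prevalence.HIGH", 2000),
                                    traj_value(tr, "prevalence.avg", 2000)))
  expect_equal(loss(tr, hist), 0)
})

test_that("shape metrics find the peak with its tie and boundary conventions", {
  s <- data.frame(year = c(1992, 1996, 2000), prevalence = c(0.1, 0.2, 0.15))
  expect_equal(shape_metrics(s)$peak_year, 1996)
  # monotone decline: peak at the first year, no rising span
  dec <- data.frame(year = 1992:2000, prevalence = seq(0.2, 0.12, by = -0.01))
  m <- shape_metrics(dec)
  expect_equal(m$peak_year, 1992)
  expect_equal(m$rising_span, 0)
  expect_gt(m$declining_span, 0)
  # plateau tie at the maximum: earliest year wins
  tie <- data.frame(year = 1992:1997,
                    prevalence = c(0.1, 0.2, 0.2, 0.2, 0.15, 0.1))
  expect_equal(shape_metrics(tie)$peak_year, 1993)
  expect_error(shape_metrics(dec[1:2, ]), "3 points")
})

test_that("shape metrics are invariant to uniform scaling", {
  s <- generate_target_series()
  a <- shape_metrics(data.frame(year = s$year, prevalence = s$prevalence))
  b <- shape_metrics(data.frame(year = s$year, prevalence = 3 * s$prevalence))
  expect_identical(a, b)
})

test_that("noise-free self-calibration recovers a single parameter exactly", {
  env <- default_env()
  truth <- behavior_params()
  grid <- coarse_grid()
  obs <- generate_observations_from_model(truth, env, grid = grid, noise_sd = 0)
  fit <- calibrate(obs, env, free = list(h_init = c(0.05, 0.3)),
                   params = update(truth, h_init = 0.08),
                   grid = grid, n_starts = 3)
  expect_lt(abs(coef(fit)[["h_init"]] - truth$h_init) / truth$h_init, 0.01)
  expect_lt(fit$rmse, 1e-4)
})

test_that("calibration is reproducible given a seed and respects bounds", {
  env <- default_env()
  obs <- default_target()
  f <- list(h_init = c(0.08, 0.2), s_social = c(0.3, 1.5))
  fit1 <- calibrate(obs, env, free = f, grid = coarse_grid(), n_starts = 3,
                    seed = 99)
  fit2 <- calibrate(obs, env, free = f, grid = coarse_grid(), n_starts = 3,
                    seed = 99)
  expect_identical(coef(fit1), coef(fit2))
  expect_true(all(coef(fit1) >= c(0.08, 0.3) - 1e-12))
  expect_true(all(coef(fit1) <= c(0.2, 1.5) + 1e-12))
})

test_that("bounds collapsed to a point return that point with its loss", {
  env <- default_env()
  obs <- default_target()
  fit <- calibrate(obs, env, free = list(h_init = c(0.1, 0.1)),
                   grid = coarse_grid(), n_starts = 3)
  expect_equal(unname(coef(fit)), 0.1)
  expect_equal(fit$sse, loss(simulate_prevalence(
    update(behavior_params(), h_init = 0.1), env, grid = coarse_grid())[,
      c("year", "AVERAGED")] |> setNames(c("year", "prevalence")), obs),
    tolerance = 1e-10)
})

test_that("the fit object supports the standard modelling generics", {
  env <- default_env()
  obs <- default_target()
  fit <- fixture("small_fit", function()
    calibrate(obs, env, free = list(h_init = c(0.08, 0.2)),
              grid = coarse_grid(), n_starts = 2))
  expect_s3_class(fit, "smoking_fit")
  expect_named(coef(fit), "h_init")
  expect_equal(length(residuals(fit)), nrow(obs))
  expect_equal(fit$rmse, sqrt(fit$sse / nrow(obs)))
  expect_equal(unname(fitted(fit)), obs$prevalence + unname(residuals(fit)))
  pr <- predict(fit, years = 2020:2032)
  expect_equal(pr$year, 2020:2032)
  expect_true(all(pr$prevalence >= 0 & pr$prevalence <= 1))
  expect_output(print(fit), "RMSE")
  expect_output(print(summary(fit)), "Bounds")
  reps <- simulate(fit, nsim = 2, seed = 5)
  expect_length(reps, 2)
  expect_false(identical(reps[[1]]$prevalence, reps[[2]]$prevalence))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("a degenerate sweep produces zero level change and preserved mode", {
  env <- default_env()
  p <- behavior_params()
  rep_ <- sensitivity_sweep(p, list(h_init = c(p$h_init, p$h_init, 3)), env,
                            grid = coarse_grid())
  expect_equal(rep_$max_level_change_pct, 0)
  expect_equal(rep_$max_peak_shift_yr, 0)
  expect_true(rep_$behavior_mode_preserved)
})

test_that("sensitivity sweeps are deterministic", {
  env <- default_env()
  p <- behavior_params()
  sw <- list(s_social = c(0.6, 1.0, 3), h_init = c(0.1, 0.16, 3))
  a <- sensitivity_sweep(p, sw, env, grid = coarse_grid())
  b <- sensitivity_sweep(p, sw, env, grid = coarse_grid())
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$parameter, c("s_social", "h_init"))
  expect_true(all(a$max_level_change_pct >= 0))
})
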