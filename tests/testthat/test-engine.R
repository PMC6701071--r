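test_that("euler_step applies the linear stock update", {
  # single outflow
  expect_equal(euler_step(c(S = 1000),
                          data.frame(name = "out", source = "S",
                                     sink = "EXTERNAL", rate = 50),
                          dt = 0.25),
               c(S = 987.5))
  # inflow and outflow together
  flows <- data.frame(name = c("in", "out"),
                      source = c("EXTERNAL", "S"), sink = c("S", "EXTERNAL"),
                      rate = c(40, 20))
  expect_equal(euler_step(c(S = 200), flows, dt = 1), c(S = 220))
  # no flows: identity
  expect_equal(euler_step(c(S = 100), data.frame(name = character(0),
                                                 source = character(0),
                                                 sink = character(0),
                                                 rate = numeric(0)),
                          dt = 0.125),
               c(S = 100))
})

test_that("euler_step rejects negative rates, bad dt, and underflow", {
  f <- data.frame(name = "out", source = "S", sink = "EXTERNAL", rate = 50)
  expect_error(euler_step(c(S = 1000), f, dt = 0), "dt")
  expect_error(euler_step(c(S = 1000), transform(f, rate = -1), "dt" = 1),
               "non-negative")
  expect_error(euler_step(c(S = 10), f, dt = 1), "underflow")
})

test_that("constant trajectory for a stock with zero flows", {
  m <- sd_model(c(S = 42),
                data.frame(name = character(0), source = character(0),
                           sink = character(0)),
                function(state, aux, t) numeric(0))
  tr <- run_simulation(m, time_grid(1992, 2002, 0.5))
  expect_true(all(tr$stocks[, "S"] == 42))
})

test_that("Euler converges to analytic exponential decay", {
  # S' = -0.1 S from 1992 to 2032; at dt = 1/64 within 0.1% of closed form
  # (error measured on the scale of the initial level)
  tr <- run_simulation(decay_model(k = 0.1, s0 = 1000),
                       time_grid(1992, 2032, 1 / 64))
  exact <- 1000 * exp(-0.1 * (tr$times - 1992))
  expect_lt(max(abs(tr$stocks[, "S"] - exact)) / 1000, 1e-3)
  # and the error shrinks linearly with dt (first-order method)
  tr2 <- run_simulation(decay_model(k = 0.1, s0 = 1000),
                        time_grid(1992, 2032, 1 / 128))
  exact2 <- 1000 * exp(-0.1 * (tr2$times - 1992))
  expect_lt(max(abs(tr2$stocks[, "S"] - exact2)),
            0.6 * max(abs(tr$stocks[, "S"] - exact)))
})

test_that("linear chain matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  k <- c(0.25, 0.125)
  A <- matrix(c(-k[1], 0, 0,
                k[1], -k[2], 0,
                0, k[2], 0), 3, 3, byrow = TRUE)
  init <- c(S1 = 1000, S2 = 0, S3 = 0)
  tr <- run_simulation(chain_model(k, init), time_grid(0, 8, 1 / 64))
  for (t in c(2, 4, 8)) {
    exact <- as.numeric(Matrix::expm(A * t) %*% init)
    got <- tr$stocks[which.min(abs(tr$times - t)), ]
    expect_lt(max(abs(got - exact)) / sum(init), 1e-3)
  }
})

test_that("stock-to-stock models conserve total quantity", {
  tr <- run_simulation(chain_model(), time_grid(0, 10, 0.125))
  tot <- rowSums(tr$stocks)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})

test_that("run_simulation signals underflow instead of clamping", {
  # outflow far larger than the stock with a big step
  m <- sd_model(c(S = 10),
                data.frame(name = "out", source = "S", sink = "EXTERNAL"),
                function(state, aux, t) 100)
  expect_error(run_simulation(m, time_grid(0, 2, 1)), "underflow")
})

test_that("halving dt changes the smoking model's endpoint by < 0.5%", {
  env <- default_env()
  p <- behavior_params()
  end_at <- function(dt) {
    tr <- run_simulation(build_model(p, env), time_grid(1992, 2032, dt))
    traj_value(tr, "prevalence.avg", 2032)
  }
  a <- end_at(0.125)
  b <- end_at(0.0625)
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("step_input is left-closed at the switch time", {
  expect_equal(step_input(2014.9, 2015, 0.44, 2.20), 0.44)
  expect_equal(step_input(2015.0, 2015, 0.44, 2.20), 2.20)
  expect_equal(step_input(2020, 2015, 7, 7), 7)
  expect_equal(step_input(c(2014, 2015, 2016), 2015, 0, 1), c(0, 1, 1))
})

test_that("interpolate_series interpolates linearly and extrapolates constants", {
  s <- c(`1992` = 10, `1994` = 20)
  expect_equal(interpolate_series(s, 1993), 15)
  expect_equal(interpolate_series(s, 1991), 10)
  expect_equal(interpolate_series(s, 2000), 20)
  expect_equal(interpolate_series(c(`2000` = 5), 1980), 5)
  expect_error(interpolate_series(data.frame(year = numeric(0), value = numeric(0)),
                                  2000), "empty")
})

test_that("time_grid validates its invariants", {
  expect_error(time_grid(1992, 2032, 0), "dt")
  expect_error(time_grid(2032, 1992, 0.125), "t_start")
  expect_error(time_grid(1992, 2032, 0.3), "integer number of steps")
  g <- time_grid(1992, 2032, 0.125)
  expect_equal(g$n_steps, 320L)
  expect_equal(diff(range(diff(g$times))), 0)
})

test_that("trajectories tidy into long format with parsed cohorts", {
  tr <- base_trajectory()
  df <- as.data.frame(tr)
  expect_named(df, c("time", "variable", "cohort", "value"))
  expect_setequal(unique(df$cohort), c("MIDDLE", "HIGH", NA))
  expect_true("prevalence.avg" %in% paste(df$variable)[is.na(df$cohort)] ||
                "prevalence" %in% df$variable)
  one <- df[df$variable == "never" & df$cohort == "MIDDLE", ]
  expect_equal(one$value, unname(tr$stocks[, "never.MIDDLE"]))
})
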