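## Calibration of free parameters to a historical prevalence series, and the
## validation battery: historical-fit metrics, shape metrics, one-at-a-time
## sensitivity sweeps distinguishing level change from behaviour-mode change.

## Evaluate an expression with a temporary RNG seed, restoring RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_historical <- function(historical) {
  if (!is.data.frame(historical) ||
      !all(c("year", "prevalence") %in% names(historical)))
    stop("historical series must be a data.frame with columns year, cohort, prevalence")
  if (is.null(historical$cohort)) historical$cohort <- "AVERAGED"
  bad <- !historical$cohort %in% c("MIDDLE", "HIGH", "AVERAGED")
  if (any(bad)) stop("cohort must be MIDDLE, HIGH or AVERAGED")
  if (any(historical$prevalence < 0 | historical$prevalence > 1))
    stop("prevalence must be in [0, 1]")
  historical[, c("year", "cohort", "prevalence")]
}

prevalence_var <- function(cohort) {
  c(MIDDLE = "prevalence.MIDDLE", HIGH = "prevalence.HIGH",
    AVERAGED = "prevalence.avg")[cohort]
}

#' Calibration loss (sum of squared errors)
#'
#' Squared error between simulated and observed prevalence summed over the
#' historical records (each matched by year and cohort; `AVERAGED` records
#' compare against the cross-cohort mean).
#'
#' @param simulated An `sd_trajectory` covering the historical years, or a
#'   `data.frame(year, prevalence)` of averaged prevalence.
#' @param historical `data.frame(year, cohort, prevalence)`; a missing
#'   `cohort` column is taken as `AVERAGED`.
#' @return Sum of squared errors (>= 0, 0 iff exact match).
#' @export
loss <- function(simulated, historical) {
  historical <- as_historical(historical)
  if (inherits(simulated, "sd_trajectory")) {
    sim <- vapply(seq_len(nrow(historical)), function(i)
      traj_value(simulated, prevalence_var(historical$cohort[i]),
                 historical$year[i]), numeric(1))
  } else {
    s <- simulated
    if (!all(c("year", "prevalence") %in% names(s)))
      stop("simulated must be an sd_trajectory or data.frame(year, prevalence)")
    if (!all(historical$year %in% s$year))
      stop("simulated series does not cover all historical years")
    sim <- s$prevalence[match(historical$year, s$year)]
  }
  sum((sim - historical$prevalence)^2)
}

#' Simulate the yearly prevalence implied by a parameter set
#'
#' @param params A [behavior_params()].
#' @param env An [env_inputs()].
#' @param initial Initial stocks (default as in [build_model()]).
#' @param grid A [time_grid()].
#' @return `data.frame(year, MIDDLE, HIGH, AVERAGED)` at integer years.
#' @export
simulate_prevalence <- function(params, env, initial = NULL, grid = time_grid()) {
  traj <- run_simulation(build_model(params, env, initial, t0 = grid$t_start), grid)
  years <- seq(ceiling(grid$t_start), floor(grid$t_end))
  data.frame(year = years,
             MIDDLE = traj_value(traj, "prevalence.MIDDLE", years),
             HIGH = traj_value(traj, "prevalence.HIGH", years),
             AVERAGED = traj_value(traj, "prevalence.avg", years))
}

#' Calibrate the smoking model to a historical prevalence series
#'
#' Bounded least-squares fit of a chosen set of free parameters, minimising
#' [loss()] with Levenberg--Marquardt local searches started from multiple
#' seeded random points inside the bounds (plus the incoming parameter values
#' as a warm start). The best start by SSE wins; results are reproducible
#' given `seed`.
#'
#' @param historical `data.frame(year, cohort, prevalence)` of observed
#'   past-30-day prevalence (cohort `AVERAGED` for the usual pooled series).
#' @param env An [env_inputs()].
#' @param free Named list of `c(lower, upper)` bounds, one entry per free
#'   parameter (any scalar field of [behavior_params()]).
#' @param params Fixed values for all other parameters (and warm-start values
#'   for the free ones).
#' @param initial Initial stocks (default as in [build_model()]).
#' @param grid A [time_grid()]; its horizon must cover the historical years.
#' @param n_starts Number of optimisation starts (default 10).
#' @param seed RNG seed for the random starts (default 20190820).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `smoking_fit`; see [coef.smoking_fit()],
#'   [predict.smoking_fit()], [plot.smoking_fit()].
#' @examples
#' \donttest{
#' env <- generate_env_inputs()
#' hist <- generate_target_series()
#' fit <- calibrate(hist, env, free = list(h_init = c(0.01, 0.1)),
#'                  n_starts = 2, grid = time_grid(dt = 0.25))
#' coef(fit)
#' }
#' @export
calibrate <- function(historical, env, free, params = behavior_params(),
                      initial = NULL, grid = time_grid(), n_starts = 10,
                      seed = 20190820, control = list()) {
  historical <- as_historical(historical)
  if (length(free) < 1L) stop("at least one free parameter is required")
  if (is.null(names(free)) || any(!nzchar(names(free))))
    stop("free must be a named list of c(lower, upper) bounds")
  lower <- vapply(free, function(b) b[1], numeric(1))
  upper <- vapply(free, function(b) b[2], numeric(1))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper")
  if (min(historical$year) < grid$t_start || max(historical$year) > grid$t_end)
    stop("grid does not cover the historical years")
  pn <- names(free)

  resid_fn <- function(theta) {
    th <- as.list(setNames(pmax(lower, pmin(upper, theta)), pn))
    p <- tryCatch(do.call(update, c(list(object = params), th)),
                  error = function(e) NULL)
    if (is.null(p)) return(rep(1e3, nrow(historical)))
    tr <- tryCatch(run_simulation(build_model(p, env, initial, t0 = grid$t_start), grid),
                   error = function(e) NULL)
    if (is.null(tr)) return(rep(1e3, nrow(historical)))
    sim <- vapply(seq_len(nrow(historical)), function(i)
      traj_value(tr, prevalence_var(historical$cohort[i]), historical$year[i]),
      numeric(1))
    sim - historical$prevalence
  }

  warm <- vapply(pn, function(nm) {
    v <- params[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) mean(c(lower[nm], upper[nm])) else v
  }, numeric(1))
  warm <- pmax(lower, pmin(upper, warm))
  starts <- with_seed(seed, {
    rand <- matrix(stats::runif((n_starts - 1L) * length(pn),
                                rep(lower, each = max(n_starts - 1L, 0)),
                                rep(upper, each = max(n_starts - 1L, 0))),
                   ncol = length(pn), byrow = FALSE,
                   dimnames = list(NULL, pn))
    rbind(warm, rand, deparse.level = 0)
  })

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200), control))
  degenerate <- all(upper - lower < 1e-12)
  best <- NULL
  n_conv <- 0L
  for (k in seq_len(nrow(starts))) {
    if (degenerate) {
      r <- resid_fn(lower)
      cand <- list(par = lower, sse = sum(r^2), residuals = r, converged = TRUE)
    } else {
      opt <- tryCatch(minpack.lm::nls.lm(par = starts[k, ], lower = lower,
                                         upper = upper, fn = resid_fn,
                                         control = ctrl),
                      error = function(e) NULL)
      if (is.null(opt)) next
      r <- opt$fvec
      cand <- list(par = setNames(coef(opt), pn), sse = sum(r^2),
                   residuals = r, converged = opt$info %in% 1:4)
    }
    if (cand$converged) n_conv <- n_conv + 1L
    if (is.null(best) || cand$sse < best$sse) best <- cand
    if (degenerate) break
  }
  if (is.null(best)) stop("calibration failed: no optimisation start converged")
  if (n_conv == 0L)
    warning("no optimisation start reported convergence; returning best point found")

  full <- do.call(update, c(list(object = params), as.list(best$par)))
  sim <- simulate_prevalence(full, env, initial, grid)
  fitted_vals <- historical
  fitted_vals$fitted <- fitted_vals$prevalence + best$residuals
  avg_years <- sim$year[sim$year >= min(historical$year) &
                          sim$year <= max(historical$year)]
  shape <- shape_metrics(data.frame(year = avg_years,
                                    prevalence = sim$AVERAGED[sim$year %in% avg_years]))
  structure(list(coefficients = best$par, sse = best$sse,
                 rmse = sqrt(best$sse / nrow(historical)),
                 residuals = setNames(best$residuals, historical$year),
                 fitted = fitted_vals, historical = historical,
                 params = full, env = env, initial = initial, grid = grid,
                 free = free, n_starts = n_starts, n_converged = n_conv,
                 seed = seed, shape = shape, simulated = sim,
                 call = match.call()),
            class = "smoking_fit")
}

#' @export
print.smoking_fit <- function(x, digits = 4, ...) {
  cat("Calibrated youth smoking model\n\n")
  cat("Fitted parameters:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nSSE %.3g, RMSE %.4f (prevalence units) over %d observations\n",
              x$sse, x$rmse, length(x$residuals)))
  cat(sprintf("Simulated peak year: %d\n", x$shape$peak_year))
  invisible(x)
}

#' @export
coef.smoking_fit <- function(object, ...) object$coefficients

#' @export
residuals.smoking_fit <- function(object, ...) object$residuals

#' @export
fitted.smoking_fit <- function(object, ...) object$fitted$fitted

#' @export
summary.smoking_fit <- function(object, ...) {
  structure(list(fit = object,
                 resid_summary = summary(object$residuals),
                 bounds = object$free),
            class = "summary.smoking_fit")
}

#' @export
print.summary.smoking_fit <- function(x, ...) {
  print(x$fit)
  cat("\nResiduals:\n")
  print(x$resid_summary)
  cat("\nBounds:\n")
  for (nm in names(x$bounds))
    cat(sprintf("  %-12s [%g, %g]\n", nm, x$bounds[[nm]][1], x$bounds[[nm]][2]))
  cat(sprintf("\n%d/%d starts converged (seed %d)\n",
              x$fit$n_converged, x$fit$n_starts, x$fit$seed))
  invisible(x)
}

#' Predict prevalence from a calibrated model
#'
#' @param object A `smoking_fit`.
#' @param years Years at which to return prevalence (default: the fitted
#'   grid's integer years).
#' @param cohort `"AVERAGED"`, `"MIDDLE"` or `"HIGH"`.
#' @param ... Unused.
#' @return `data.frame(year, prevalence)`.
#' @export
predict.smoking_fit <- function(object, years = NULL,
                                cohort = c("AVERAGED", "MIDDLE", "HIGH"), ...) {
  cohort <- match.arg(cohort)
  sim <- object$simulated
  if (is.null(years)) years <- sim$year
  if (!all(years %in% sim$year)) {
    tr <- run_simulation(build_model(object$params, object$env, object$initial,
                                     t0 = object$grid$t_start), object$grid)
    return(prevalence_series(tr, cohort, years))
  }
  data.frame(year = years,
             prevalence = sim[[switch(cohort, AVERAGED = "AVERAGED",
                                      MIDDLE = "MIDDLE", HIGH = "HIGH")]][match(years, sim$year)])
}

#' Plot observed versus calibrated prevalence
#'
#' @param x A `smoking_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.smoking_fit <- function(x, ...) {
  sim <- x$simulated
  obs <- x$historical[x$historical$cohort == "AVERAGED", ]
  graphics::plot(sim$year, sim$AVERAGED, type = "l", lwd = 2,
                 xlab = "Year", ylab = "Past-30-day smoking prevalence",
                 ylim = range(c(sim$AVERAGED, obs$prevalence), na.rm = TRUE), ...)
  if (nrow(obs)) graphics::points(obs$year, obs$prevalence, pch = 19)
  graphics::legend("topright", legend = c("simulated", "observed"),
                   lty = c(1, NA), pch = c(NA, 19), bty = "n")
  invisible(x)
}

#' Simulate noisy observation series from a calibrated model
#'
#' @param object A `smoking_fit`.
#' @param nsim Number of replicate series.
#' @param seed RNG seed.
#' @param noise_sd Observation noise standard deviation (prevalence units).
#' @param years Observation years (default the historical years).
#' @param ... Unused.
#' @return List of `data.frame(year, cohort, prevalence)` replicates.
#' @export
simulate.smoking_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = 0.005, years = NULL, ...) {
  if (is.null(years)) years <- sort(unique(object$historical$year))
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  lapply(seq_len(nsim), function(i)
    generate_observations_from_model(object$params, object$env, object$initial,
                                     object$grid, noise_sd = noise_sd,
                                     seed = seed + i - 1L, years = years))
}

#' Shape metrics of a prevalence series
#'
#' Peak year (earliest on ties) plus the lengths of the rising and declining
#' phases, computed from the signs of consecutive differences after 3-point
#' median smoothing.
#'
#' @param series `data.frame(year, prevalence)` with at least 3 points, or a
#'   numeric vector named by years.
#' @return Object of class `shape_metrics`: `peak_year`, `rising_span`,
#'   `declining_span` (years).
#' @export
shape_metrics <- function(series) {
  if (is.numeric(series) && !is.null(names(series)))
    series <- data.frame(year = as.numeric(names(series)), prevalence = unname(series))
  if (!is.data.frame(series) || !all(c("year", "prevalence") %in% names(series)))
    stop("series must be data.frame(year, prevalence) or a year-named numeric vector")
  series <- series[order(series$year), ]
  if (nrow(series) < 3L) stop("shape metrics need at least 3 points")
  y <- series$year
  p <- series$prevalence
  peak_year <- y[which.max(p)]
  sm <- stats::runmed(p, 3, endrule = "median")
  d <- diff(sm)
  gaps <- diff(y)
  rising <- sum(gaps[d > 0 & y[-1] <= peak_year])
  declining <- sum(gaps[d < 0 & y[-length(y)] >= peak_year])
  structure(list(peak_year = peak_year, rising_span = rising,
                 declining_span = declining),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("<shape_metrics> peak %d; rising %g yr, declining %g yr\n",
              x$peak_year, x$rising_span, x$declining_span))
  invisible(x)
}

## Sign pattern of yearly differences with a deadband, after median smoothing.
## The first difference is excluded: it reflects the imposed initial
## decomposition of the 1992 stocks, not the model's dynamics.
behavior_pattern <- function(prevalence, deadband = 1e-4) {
  d <- diff(stats::runmed(prevalence, 3, endrule = "median"))
  s <- sign(d)
  s[abs(d) < deadband] <- 0
  s[-1]
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the base simulation over a range of values for each parameter in
#' turn (all others held at base), recording the maximum change in the
#' averaged 2032 prevalence level, the peak-year shift, and whether the
#' behaviour mode is preserved. The mode criterion is operational: the peak
#' year shifts by at most 2 years and the sign pattern of yearly differences
#' (after 3-point median smoothing, with a small deadband, excluding the
#' first post-initialisation year) is unchanged.
#' Sweeps are deterministic.
#'
#' @param base_params A [behavior_params()].
#' @param sweep Named list: each entry `c(low, high, n_points)` for one scalar
#'   parameter. See [default_sweep()].
#' @param env An [env_inputs()].
#' @param initial Initial stocks (default as in [build_model()]).
#' @param grid A [time_grid()].
#' @param eval_year Year at which the level change is measured (default 2032).
#' @param deadband Prevalence-difference deadband treated as "no change" in
#'   the sign pattern (default 1e-4).
#' @return `data.frame` of class `sensitivity_report`: one row per parameter
#'   with `low`, `high`, `n_points`, `max_level_change_pct`,
#'   `max_peak_shift_yr`, `behavior_mode_preserved`.
#' @export
sensitivity_sweep <- function(base_params, sweep, env, initial = NULL,
                              grid = time_grid(), eval_year = 2032,
                              deadband = 1e-4) {
  stopifnot(length(sweep) >= 1L, !is.null(names(sweep)))
  base_traj <- run_simulation(build_model(base_params, env, initial,
                                          t0 = grid$t_start), grid)
  years <- seq(ceiling(grid$t_start), floor(grid$t_end))
  base_prev <- traj_value(base_traj, "prevalence.avg", years)
  base_level <- traj_value(base_traj, "prevalence.avg", eval_year)
  base_peak <- years[which.max(base_prev)]
  base_pat <- behavior_pattern(base_prev, deadband)
  rows <- lapply(names(sweep), function(nm) {
    rng <- sweep[[nm]]
    if (length(rng) < 3L) stop("sweep entries must be c(low, high, n_points)")
    vals <- seq(rng[1], rng[2], length.out = max(as.integer(rng[3]), 1L))
    lev <- peaksh <- numeric(length(vals))
    mode_ok <- logical(length(vals))
    for (i in seq_along(vals)) {
      p <- do.call(update, c(list(object = base_params),
                             setNames(list(vals[i]), nm)))
      tr <- run_simulation(build_model(p, env, initial, t0 = grid$t_start), grid)
      prev <- traj_value(tr, "prevalence.avg", years)
      lev[i] <- 100 * abs(traj_value(tr, "prevalence.avg", eval_year) - base_level) / base_level
      peaksh[i] <- abs(years[which.max(prev)] - base_peak)
      mode_ok[i] <- peaksh[i] <= 2 &&
        identical(behavior_pattern(prev, deadband), base_pat)
    }
    data.frame(parameter = nm, low = rng[1], high = rng[2],
               n_points = length(vals),
               max_level_change_pct = max(lev),
               max_peak_shift_yr = max(peaksh),
               behavior_mode_preserved = all(mode_ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_report", "data.frame"),
            eval_year = eval_year)
}

#' Default sensitivity sweep ranges
#'
#' Two-tier plausible ranges: base hazards, which are pinned down by the
#' historical calibration, are swept over +/- `rel_hazard` of their values;
#' the soft feedback strengths and elasticities, which rest on qualitative
#' information, are swept over the wider +/- `rel_soft` (ranges sorted, so
#' sign-constrained parameters stay in bounds).
#'
#' @param params A [behavior_params()].
#' @param rel_hazard Relative half-width for calibrated hazards (default 0.1).
#' @param rel_soft Relative half-width for soft strengths (default 0.3).
#' @param n Points per parameter (default 5).
#' @param rel Shorthand overriding both half-widths with one value.
#' @return Named list suitable for [sensitivity_sweep()].
#' @export
default_sweep <- function(params = behavior_params(), rel_hazard = 0.1,
                          rel_soft = 0.3, n = 5, rel = NULL) {
  if (!is.null(rel)) rel_hazard <- rel_soft <- rel
  hz <- c("h_init", "h_prog", "h_quit_exp", "h_quit_smk", "h_rel_exp",
          "h_rel_smk")
  soft <- c("s_social", "s_shs", "s_avail", "s_risk", "eps_q", "eps_cess",
            "s_nd", "m_msa", "tau_risk", "w_peer")
  out <- lapply(c(hz, soft), function(nm) {
    v <- params[[nm]]
    rel_w <- if (nm %in% hz) rel_hazard else rel_soft
    r <- sort(c(v * (1 - rel_w), v * (1 + rel_w)))
    if (nm %in% c("w_peer", "m_msa")) r <- pmin(pmax(r, 0), 1)
    c(r[1], r[2], n)
  })
  setNames(out, c(hz, soft))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("One-at-a-time sensitivity sweep (level measured at %d)\n",
              attr(x, "eval_year")))
  df <- as.data.frame(x)
  df$max_level_change_pct <- round(df$max_level_change_pct, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
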