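## Synthetic inputs: a historical-shaped prevalence target, exogenous
## environment series, and model-generated noisy observations for
## parameter-recovery studies. The default shape numbers are illustrative
## stand-ins for the survey series the model family is usually calibrated to;
## they reproduce the qualitative rise--peak--decline of US youth smoking in
## 1992--2014, not any published prevalence values.

#' Shape parameters of the synthetic prevalence target
#'
#' @param p_1992 Prevalence at 1992 (default 0.16).
#' @param p_peak Peak prevalence (default 0.22).
#' @param peak_year Peak year, strictly inside 1992--2014 (default 1997).
#' @param decline_rate Exponential decline rate after the peak, /yr (default
#'   0.045).
#' @param noise_sd Gaussian observation noise sd, prevalence units (default
#'   0, i.e. deterministic).
#' @param seed RNG seed for the noise (default 1).
#' @return Object of class `target_shape_params`.
#' @export
target_shape_params <- function(p_1992 = 0.16, p_peak = 0.22, peak_year = 1997,
                                decline_rate = 0.045, noise_sd = 0, seed = 1) {
  if (!(p_1992 > 0 && p_1992 <= p_peak && p_peak < 1))
    stop("need 0 < p_1992 <= p_peak < 1")
  if (!(peak_year > 1992 && peak_year < 2014))
    stop("peak_year must be strictly inside 1992--2014")
  if (decline_rate <= 0) stop("decline_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(p_1992 = p_1992, p_peak = p_peak, peak_year = peak_year,
                 decline_rate = decline_rate, noise_sd = noise_sd, seed = seed),
            class = "target_shape_params")
}

#' Generate the synthetic historical prevalence target
#'
#' Deterministic base curve: a logistic rise towards `p_peak` (saturating at
#' 98% of the peak in the peak year, with its midpoint before the peak),
#' multiplied by an exponential decline `exp(-decline_rate * (year -
#' peak_year))` after the peak; optional seeded Gaussian noise truncated to
#' \[0, 1\]. With `noise_sd = 0` the output is fully deterministic and its
#' [shape_metrics()] peak matches the requested peak year.
#'
#' @param shape A [target_shape_params()].
#' @param years Observation years (default 1992:2014).
#' @param noise_model `"gaussian"` (additive, truncated) or `"binomial"`
#'   (survey sampling noise with `n_sample` respondents).
#' @param n_sample Respondents per year for the binomial model (default 2000).
#' @return `data.frame(year, cohort, prevalence)` with cohort `"AVERAGED"`.
#' @examples
#' head(generate_target_series())
#' @export
generate_target_series <- function(shape = target_shape_params(),
                                   years = 1992:2014,
                                   noise_model = c("gaussian", "binomial"),
                                   n_sample = 2000) {
  stopifnot(inherits(shape, "target_shape_params"))
  noise_model <- match.arg(noise_model)
  p <- synthetic_target_curve(shape, years)
  if (shape$noise_sd > 0 || noise_model == "binomial") {
    p <- with_seed(shape$seed, {
      if (noise_model == "gaussian") p + stats::rnorm(length(p), 0, shape$noise_sd)
      else stats::rbinom(length(p), n_sample, p) / n_sample
    })
    p <- pmin(pmax(p, 0), 1)
  }
  data.frame(year = years, cohort = "AVERAGED", prevalence = p,
             stringsAsFactors = FALSE)
}

## Closed-form deterministic target curve.
synthetic_target_curve <- function(shape, years) {
  sat <- 0.98  # logistic saturation fraction reached at the peak year
  r1 <- shape$p_peak / shape$p_1992 - 1
  if (r1 <= 0) {  # flat start allowed when p_1992 == p_peak
    rise <- rep(shape$p_peak, length(years))
  } else {
    k <- (log(1 / sat - 1) - log(r1)) / (1992 - shape$peak_year)
    y0 <- shape$peak_year + log(1 / sat - 1) / k
    rise <- shape$p_peak / (1 + exp(-k * (years - y0)))
  }
  rise * exp(-shape$decline_rate * pmax(0, years - shape$peak_year))
}

#' Shape parameters of the synthetic environment series
#'
#' Stand-ins for the state-level exogenous series the model needs but which
#' are not part of this package's data: cigarette price and average income
#' grow exponentially, cohort entry and parental prevalence move linearly.
#' Defaults give a pre-tax price of $1.56/pack in 1992 growing at 2.5%/yr, an
#' income index growing at 2%/yr, 8000 entrants/yr (a cohort population of
#' 32,000), and adult smoking prevalence falling from 25% by 0.4 points/yr.
#'
#' @param price_1992 Pre-tax retail price in 1992, USD/pack.
#' @param price_growth Exponential price growth rate, /yr.
#' @param income_growth Exponential income growth rate, /yr.
#' @param entry_1992 Cohort entry rate in 1992, persons/yr.
#' @param entry_growth Linear relative growth of the entry rate, /yr.
#' @param parent_prev_1992 Parental smoking prevalence in 1992.
#' @param parent_prev_slope Linear change in parental prevalence, /yr.
#' @param seed RNG seed (kept for interface symmetry; the default generator
#'   is deterministic).
#' @return Object of class `env_shape_params`.
#' @export
env_shape_params <- function(price_1992 = 1.56, price_growth = 0.025,
                             income_growth = 0.02, entry_1992 = 8000,
                             entry_growth = 0, parent_prev_1992 = 0.25,
                             parent_prev_slope = -0.004, seed = 1) {
  stopifnot(price_1992 > 0, entry_1992 > 0,
            parent_prev_1992 >= 0, parent_prev_1992 <= 1)
  structure(list(price_1992 = price_1992, price_growth = price_growth,
                 income_growth = income_growth, entry_1992 = entry_1992,
                 entry_growth = entry_growth,
                 parent_prev_1992 = parent_prev_1992,
                 parent_prev_slope = parent_prev_slope, seed = seed),
            class = "env_shape_params")
}

#' Generate synthetic exogenous environment inputs
#'
#' Builds an [env_inputs()] covering the grid: exponential price and income,
#' a constant $0.44/pack excise tax (unchanged over the whole horizon absent
#' a policy), linear entry rate, linear parental prevalence clamped to
#' \[0, 1\], default retailer compliance (0.73 MIDDLE / 0.78 HIGH) and
#' constant $9.80 per-capita programme funding.
#'
#' @param shape An [env_shape_params()].
#' @param grid A [time_grid()].
#' @return An [env_inputs()] object.
#' @export
generate_env_inputs <- function(shape = env_shape_params(), grid = time_grid()) {
  stopifnot(inherits(shape, "env_shape_params"))
  years <- seq(floor(grid$t_start), ceiling(grid$t_end))
  el <- years - 1992
  parent_raw <- shape$parent_prev_1992 + shape$parent_prev_slope * el
  parent <- pmin(pmax(parent_raw, 0), 1)
  clamped <- mean(parent != parent_raw)
  if (clamped > 0.2)
    stop("parental prevalence slope clamps more than 20% of the horizon; choose a shallower slope")
  entry <- shape$entry_1992 * (1 + shape$entry_growth * el)
  if (any(entry <= 0)) stop("entry rate must stay positive over the horizon")
  env_inputs(
    retail_price = data.frame(year = years,
                              value = shape$price_1992 * exp(shape$price_growth * el)),
    excise_tax = data.frame(year = years, value = 0.44),
    income_index = data.frame(year = years, value = exp(shape$income_growth * el)),
    entry_rate = data.frame(year = years, value = entry),
    parental_prevalence = data.frame(year = years, value = parent),
    funding_per_capita = data.frame(year = years, value = 9.80))
}

#' Generate noisy observations from the model itself
#'
#' Ground-truth generator for parameter-recovery studies: runs the smoking
#' model with known parameters, samples the averaged prevalence at integer
#' years, and adds seeded Gaussian observation noise truncated to \[0, 1\].
#'
#' @param true_params A [behavior_params()] (the known truth).
#' @param env An [env_inputs()].
#' @param initial Initial stocks (default as in [build_model()]).
#' @param grid A [time_grid()].
#' @param noise_sd Observation noise sd, prevalence units (default 0.005).
#' @param seed RNG seed (default 1).
#' @param years Observation years (default 1992:2014).
#' @param cohorts `"AVERAGED"` (default: one pooled record per year) or
#'   `"BOTH"` (separate middle- and high-school records per year, as school
#'   surveys report them).
#' @return `data.frame(year, cohort, prevalence)`.
#' @export
generate_observations_from_model <- function(true_params, env, initial = NULL,
                                             grid = time_grid(),
                                             noise_sd = 0.005, seed = 1,
                                             years = 1992:2014,
                                             cohorts = c("AVERAGED", "BOTH")) {
  cohorts <- match.arg(cohorts)
  traj <- run_simulation(build_model(true_params, env, initial,
                                     t0 = grid$t_start), grid)
  out <- if (cohorts == "AVERAGED") {
    data.frame(year = years, cohort = "AVERAGED",
               prevalence = traj_value(traj, "prevalence.avg", years),
               stringsAsFactors = FALSE)
  } else {
    data.frame(year = rep(years, 2),
               cohort = rep(c("MIDDLE", "HIGH"), each = length(years)),
               prevalence = c(traj_value(traj, "prevalence.MIDDLE", years),
                              traj_value(traj, "prevalence.HIGH", years)),
               stringsAsFactors = FALSE)
  }
  if (noise_sd > 0) {
    out$prevalence <- with_seed(seed, out$prevalence +
                                  stats::rnorm(nrow(out), 0, noise_sd))
    out$prevalence <- pmin(pmax(out$prevalence, 0), 1)
  }
  out
}
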