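## Policy levers, named scenarios, and the percent-reduction outcome metric.

#' Define a policy scenario
#'
#' A scenario sets any of three levers as step changes taking effect at
#' `start_year`: the excise tax (USD/pack), comprehensive-programme funding
#' (USD per capita), and per-cohort retailer compliance. `NA` leaves a lever
#' unchanged.
#'
#' @param name Scenario identifier.
#' @param tax_per_pack Excise tax after `start_year`, USD/pack, or `NA`.
#' @param funding_per_capita Programme funding after `start_year`, USD per
#'   capita, or `NA`.
#' @param compliance_middle,compliance_high Retailer compliance after
#'   `start_year`, fractions in \[0, 1), or `NA`.
#' @param start_year Year the policy takes effect (default 2015).
#' @return An object of class `policy_scenario`.
#' @export
policy_scenario <- function(name, tax_per_pack = NA_real_,
                            funding_per_capita = NA_real_,
                            compliance_middle = NA_real_,
                            compliance_high = NA_real_,
                            start_year = 2015) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (!is.na(tax_per_pack) && tax_per_pack < 0) stop("tax must be >= 0")
  if (!is.na(funding_per_capita) && funding_per_capita < 0) stop("funding must be >= 0")
  for (cc in c(compliance_middle, compliance_high))
    if (!is.na(cc) && (cc < 0 || cc >= 1)) stop("compliance must be in [0, 1)")
  structure(list(name = name, tax_per_pack = tax_per_pack,
                 funding_per_capita = funding_per_capita,
                 compliance_middle = compliance_middle,
                 compliance_high = compliance_high,
                 start_year = start_year),
            class = "policy_scenario")
}

#' @export
print.policy_scenario <- function(x, ...) {
  lev <- function(v) if (is.na(v)) "unchanged" else format(v)
  cat(sprintf("<policy_scenario> %s (from %g): tax %s, funding %s, compliance M %s / H %s\n",
              x$name, x$start_year, lev(x$tax_per_pack), lev(x$funding_per_capita),
              lev(x$compliance_middle), lev(x$compliance_high)))
  invisible(x)
}

is_base_scenario <- function(scenario) {
  all(is.na(c(scenario$tax_per_pack, scenario$funding_per_capita,
              scenario$compliance_middle, scenario$compliance_high)))
}

#' Catalogue of the tested policy scenarios
#'
#' The base case plus the five policy runs evaluated by the study design: two
#' excise-tax increases ($0.44 to $1.44 or $2.20 per pack), programme funding
#' raised from $9.80 to $20 per capita, retailer compliance raised to 95% in
#' both cohorts, and all three policies combined (with the higher tax). All
#' start in 2015.
#'
#' @return Named list of [policy_scenario()] objects: `BASE`, `TAX_144`,
#'   `TAX_220`, `FUNDING_20`, `COMPLIANCE_95`, `ALL_COMBINED`.
#' @export
scenario_catalog <- function() {
  list(BASE = policy_scenario("BASE"),
       TAX_144 = policy_scenario("TAX_144", tax_per_pack = 1.44),
       TAX_220 = policy_scenario("TAX_220", tax_per_pack = 2.20),
       FUNDING_20 = policy_scenario("FUNDING_20", funding_per_capita = 20),
       COMPLIANCE_95 = policy_scenario("COMPLIANCE_95",
                                       compliance_middle = 0.95,
                                       compliance_high = 0.95),
       ALL_COMBINED = policy_scenario("ALL_COMBINED", tax_per_pack = 2.20,
                                      funding_per_capita = 20,
                                      compliance_middle = 0.95,
                                      compliance_high = 0.95))
}

#' Apply a policy scenario to the model inputs
#'
#' Installs the scenario's levers as step overrides on the environment
#' series (left-closed at `start_year`); behavioural parameters are never
#' altered (compliance enters only through the availability channel). The
#' base scenario returns the inputs unchanged.
#'
#' @param env An [env_inputs()].
#' @param params A [behavior_params()].
#' @param scenario A [policy_scenario()].
#' @return List with modified `env` and untouched `params`.
#' @export
apply_scenario <- function(env, params, scenario) {
  stopifnot(inherits(scenario, "policy_scenario"))
  if (is_base_scenario(scenario)) return(list(env = env, params = params))
  y <- scenario$start_year
  if (!is.na(scenario$tax_per_pack))
    env <- env_with_step(env, "excise_tax", y, scenario$tax_per_pack)
  if (!is.na(scenario$funding_per_capita))
    env <- env_with_step(env, "funding_per_capita", y, scenario$funding_per_capita)
  if (!is.na(scenario$compliance_middle))
    env <- env_with_step(env, "compliance_middle", y, scenario$compliance_middle)
  if (!is.na(scenario$compliance_high))
    env <- env_with_step(env, "compliance_high", y, scenario$compliance_high)
  list(env = env, params = params)
}

#' Percent reduction in prevalence under a policy
#'
#' `100 * (base - policy) / base`, evaluated on the averaged past-30-day
#' prevalence at `eval_year`.
#'
#' @param base_traj,policy_traj `sd_trajectory` objects covering `eval_year`.
#' @param eval_year Evaluation year (default 2032).
#' @return Percent reduction (positive when the policy lowers prevalence).
#' @export
percent_reduction <- function(base_traj, policy_traj, eval_year = 2032) {
  pb <- traj_value(base_traj, "prevalence.avg", eval_year)
  pp <- traj_value(policy_traj, "prevalence.avg", eval_year)
  if (pb <= 0) stop("base prevalence is zero at the evaluation year")
  100 * (pb - pp) / pb
}

#' Run the policy comparison
#'
#' One base run plus one run per non-base scenario, all sharing parameters,
#' environment and initial stocks; outcomes are the 2032 prevalences and
#' percent reductions relative to base, sorted by reduction (largest first).
#'
#' @param params A [behavior_params()].
#' @param env An [env_inputs()].
#' @param initial Initial stocks (default as in [build_model()]).
#' @param grid A [time_grid()].
#' @param scenarios List of [policy_scenario()]s (default
#'   [scenario_catalog()]).
#' @param eval_year Evaluation year (default 2032).
#' @return A `data.frame` of class `policy_outcomes` with columns `scenario`,
#'   `prevalence_2032`, `base_prevalence_2032`, `pct_reduction`; the
#'   trajectories (including base) are attached as attribute
#'   `"trajectories"`.
#' @export
run_policy_comparison <- function(params = behavior_params(), env,
                                  initial = NULL, grid = time_grid(),
                                  scenarios = scenario_catalog(),
                                  eval_year = 2032) {
  if (inherits(scenarios, "policy_scenario")) scenarios <- list(scenarios)
  for (sc in scenarios) {
    if (!is_base_scenario(sc) &&
        (sc$start_year < grid$t_start || sc$start_year > grid$t_end))
      stop("scenario '", sc$name, "' starts outside the simulation grid")
  }
  base_model <- build_model(params, env, initial, t0 = grid$t_start)
  base_traj <- run_simulation(base_model, grid)
  pb <- traj_value(base_traj, "prevalence.avg", eval_year)
  pol <- Filter(Negate(is_base_scenario), scenarios)
  trajs <- list(BASE = base_traj)
  rows <- lapply(pol, function(sc) {
    inp <- apply_scenario(env, params, sc)
    m <- build_model(inp$params, inp$env, initial, t0 = grid$t_start)
    tr <- run_simulation(m, grid)
    trajs[[sc$name]] <<- tr
    data.frame(scenario = sc$name,
               prevalence_2032 = traj_value(tr, "prevalence.avg", eval_year),
               base_prevalence_2032 = pb,
               pct_reduction = percent_reduction(base_traj, tr, eval_year),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(0), prevalence_2032 = numeric(0),
               base_prevalence_2032 = numeric(0), pct_reduction = numeric(0))
  out <- out[order(-out$pct_reduction), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("policy_outcomes", "data.frame"),
            trajectories = trajs, eval_year = eval_year)
}
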