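## Plain-text interchange: CSV for series/trajectories/outcomes, YAML for
## parameters and scenarios.

#' Read a single exogenous series from CSV
#'
#' @param path CSV with header `year,value`.
#' @return `data.frame(year, value)`.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_series(utils::read.csv(path))
}

#' Read environment inputs from a wide CSV
#'
#' @param path CSV with header
#'   `year,price,tax,income,entry_middle,parent_prev` and optionally
#'   `funding`; missing funding defaults to a constant 9.80 USD per capita.
#' @param compliance,msa_year Passed to [env_inputs()].
#' @return An [env_inputs()] object.
#' @export
read_env_csv <- function(path, compliance = c(MIDDLE = 0.73, HIGH = 0.78),
                         msa_year = 1998) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("year", "price", "tax", "income", "entry_middle", "parent_prev")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("environment CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  funding <- if ("funding" %in% names(d)) d$funding else rep(9.80, nrow(d))
  env_inputs(retail_price = data.frame(year = d$year, value = d$price),
             excise_tax = data.frame(year = d$year, value = d$tax),
             income_index = data.frame(year = d$year, value = d$income),
             entry_rate = data.frame(year = d$year, value = d$entry_middle),
             parental_prevalence = data.frame(year = d$year, value = d$parent_prev),
             funding_per_capita = data.frame(year = d$year, value = funding),
             compliance = compliance, msa_year = msa_year)
}

#' Write environment inputs as a wide CSV
#'
#' @param env An [env_inputs()].
#' @param path Output path.
#' @param years Years to tabulate (default: union of the series' years).
#' @return The path, invisibly.
#' @export
write_env_csv <- function(env, path, years = NULL) {
  if (is.null(years))
    years <- sort(unique(unlist(lapply(env$series[1:6], function(s) s$year))))
  d <- data.frame(year = years,
                  price = env_value(env, "retail_price", years),
                  tax = env_value(env, "excise_tax", years),
                  income = env_value(env, "income_index", years),
                  entry_middle = env_value(env, "entry_rate", years),
                  parent_prev = env_value(env, "parental_prevalence", years),
                  funding = env_value(env, "funding_per_capita", years))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a historical prevalence series from CSV
#'
#' @param path CSV with header `year,cohort,prevalence` (cohort `MIDDLE`,
#'   `HIGH` or `AVERAGED`).
#' @return Validated `data.frame(year, cohort, prevalence)`.
#' @export
read_historical_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_historical(utils::read.csv(path))
}

#' Write a historical prevalence series as CSV
#'
#' @param historical `data.frame(year, cohort, prevalence)`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_historical_csv <- function(historical, path) {
  utils::write.csv(as_historical(historical), path, row.names = FALSE)
  invisible(path)
}

#' Write behavioural parameters as YAML
#'
#' @param params A [behavior_params()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "behavior_params"))
  x <- lapply(unclass(params), function(v) if (length(v) > 1) as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read behavioural parameters from YAML
#'
#' Fields omitted from the file keep their [behavior_params()] defaults.
#'
#' @param path YAML file with fields named as in [behavior_params()].
#' @return A [behavior_params()] object.
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  known <- names(formals(behavior_params))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown parameter field(s) in ", path, ": ", paste(unknown, collapse = ", "))
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  do.call(behavior_params, x)
}

#' Read policy scenarios from YAML
#'
#' The file is either a list of scenario mappings or a single mapping, each
#' with keys `name`, `tax_per_pack`, `funding_per_capita`,
#' `compliance_middle`, `compliance_high`, `start_year` (missing levers stay
#' unchanged).
#'
#' @param path YAML file path.
#' @return Named list of [policy_scenario()] objects.
#' @export
read_scenarios_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  if (!is.null(x$name)) x <- list(x)
  sc <- lapply(x, function(s) {
    if (is.null(s$name)) stop("each scenario in ", path, " needs a 'name'")
    do.call(policy_scenario, s)
  })
  setNames(sc, vapply(sc, `[[`, "", "name"))
}

#' Write policy outcomes as CSV
#'
#' @param outcomes A [run_policy_comparison()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(as.data.frame(outcomes), path, row.names = FALSE)
  invisible(path)
}
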