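## Two-cohort aging-chain model of adolescent smoking states and the feedback
## multipliers that modulate initiation, progression, cessation and relapse.

SMOKING_STATES <- c("never", "cur_exp", "form_exp", "cur_smk", "ex_smk")
COHORTS <- c("MIDDLE", "HIGH")
COHORT_SPAN <- 4  # years per school cohort

#' Names of the smoking stocks
#'
#' Stock identifiers follow the `<state>.<cohort>` convention, with states
#' `never` (never-smokers), `cur_exp`/`form_exp` (current/former
#' experimenters, under 100 lifetime cigarettes), `cur_smk`/`ex_smk`
#' (current/ex smokers, 100+ lifetime cigarettes), and cohorts `MIDDLE` (ages
#' 11--14) and `HIGH` (ages 15--18).
#'
#' @return Character vector of the ten stock names.
#' @export
smoking_stock_names <- function() {
  as.vector(outer(SMOKING_STATES, COHORTS, paste, sep = "."))
}

#' Initial smoking stocks
#'
#' Builds a 1992 initial state whose past-30-day prevalence matches a target
#' in each cohort. The initial decomposition of the population is not
#' observed, so it is parameterised: current users split between experimenters
#' and smokers, and a "past user" pool split between former experimenters and
#' ex-smokers.
#'
#' @param pop_middle,pop_high Cohort populations (persons).
#' @param p0_middle,p0_high Initial past-30-day smoking prevalence per cohort.
#' @param cur_smoker_frac Fraction of current users who are smokers (the rest
#'   are experimenters); default 0.30.
#' @param past_frac Fraction of the cohort who are past users (former
#'   experimenters + ex-smokers); default 0.10.
#' @param past_smoker_frac Fraction of past users who are ex-smokers; default
#'   0.50.
#' @return Named numeric vector over [smoking_stock_names()].
#' @export
initial_stocks <- function(pop_middle = 32000, pop_high = 32000,
                           p0_middle = 0.16, p0_high = 0.16,
                           cur_smoker_frac = 0.30, past_frac = 0.10,
                           past_smoker_frac = 0.50) {
  stopifnot(pop_middle > 0, pop_high > 0,
            p0_middle >= 0, p0_middle <= 1, p0_high >= 0, p0_high <= 1,
            cur_smoker_frac >= 0, cur_smoker_frac <= 1,
            past_frac >= 0, past_frac < 1,
            past_smoker_frac >= 0, past_smoker_frac <= 1)
  one <- function(pop, p0) {
    cur <- p0 * pop
    past <- past_frac * pop
    if (cur + past > pop) stop("initial prevalence plus past-user fraction exceeds 1")
    c(never = pop - cur - past,
      cur_exp = cur * (1 - cur_smoker_frac),
      form_exp = past * (1 - past_smoker_frac),
      cur_smk = cur * cur_smoker_frac,
      ex_smk = past * past_smoker_frac)
  }
  m <- one(pop_middle, p0_middle)
  h <- one(pop_high, p0_high)
  setNames(c(m[SMOKING_STATES], h[SMOKING_STATES]), smoking_stock_names())
}

cohort_stocks <- function(stocks, cohort) {
  cohort <- match.arg(cohort, COHORTS)
  stocks[paste(SMOKING_STATES, cohort, sep = ".")]
}

#' Monthly smoking quantity
#'
#' Monthly quantity is smoking frequency (days smoked per month) times
#' cigarettes smoked per day.
#'
#' @param freq Days smoked per month, in \[0, 30\].
#' @param cpd Cigarettes per day, >= 0.
#' @return Cigarettes per month.
#' @examples
#' monthly_smoking_quantity(20, 5)  # 100
#' @export
monthly_smoking_quantity <- function(freq, cpd) {
  if (any(freq < 0) || any(cpd < 0)) stop("freq and cpd must be non-negative")
  if (any(freq > 31)) stop("freq cannot exceed the days in a month")
  if (any(freq > 30)) stop("freq above 30 days/month not supported (calendar variation ignored)")
  freq * cpd
}

#' Past-30-day smoking prevalence of a cohort
#'
#' Current experimenters and current smokers both smoked within the past 30
#' days; prevalence is their share of the cohort population.
#'
#' @param stocks Named stock vector (see [smoking_stock_names()]).
#' @param cohort `"MIDDLE"` or `"HIGH"`.
#' @return Prevalence fraction in \[0, 1\].
#' @export
smoking_prevalence <- function(stocks, cohort = c("MIDDLE", "HIGH")) {
  cohort <- match.arg(cohort)
  s <- cohort_stocks(stocks, cohort)
  pop <- sum(s)
  if (pop <= 0) stop("cohort population is zero")
  unname((s[paste0("cur_exp.", cohort)] + s[paste0("cur_smk.", cohort)]) / pop)
}

#' Prevalence averaged across cohorts
#'
#' Unweighted mean of the middle-school and high-school prevalences, the
#' model's headline outcome.
#'
#' @inheritParams smoking_prevalence
#' @return Averaged prevalence fraction.
#' @export
averaged_prevalence <- function(stocks) {
  mean(c(smoking_prevalence(stocks, "MIDDLE"), smoking_prevalence(stocks, "HIGH")))
}

#' Social-pressure multiplier (reinforcing loop)
#'
#' The social-pressure index is a peer/parent weighted prevalence,
#' `SP = w_peer * peer + (1 - w_peer) * parent`; the multiplier is the
#' constant-elasticity form `(SP / SP_ref)^s_social`, equal to 1 at the
#' reference index.
#'
#' @param peer_prev Peer (own-cohort) past-30-day prevalence, in \[0, 1\].
#' @param parent_prev Parental smoking prevalence, in \[0, 1\].
#' @param params A [behavior_params()] object with resolved `sp_ref`.
#' @param cohort Which cohort's reference index to use.
#' @return Multiplier >= 0.
#' @export
social_pressure_multiplier <- function(peer_prev, parent_prev, params,
                                       cohort = c("MIDDLE", "HIGH")) {
  cohort <- match.arg(cohort)
  sp_ref <- params$sp_ref[[cohort]]
  if (is.na(sp_ref) || sp_ref <= 0) stop("sp_ref must be resolved and > 0 (build the model first)")
  sp <- params$w_peer * peer_prev + (1 - params$w_peer) * parent_prev
  (sp / sp_ref)^params$s_social
}

#' Secondhand-smoke/nicotine-dependence multiplier (reinforcing loop)
#'
#' Secondhand-smoke exposure primes nicotine dependence among non-smoking
#' youth, raising initiation. The exposure index shares the social-pressure
#' weighting of peer and parental prevalence; the multiplier is the linear
#' gain `1 + s_shs * SHS`, >= 1.
#'
#' @inheritParams social_pressure_multiplier
#' @return Multiplier >= 1.
#' @export
shs_dependence_multiplier <- function(peer_prev, parent_prev, params) {
  shs <- params$w_peer * peer_prev + (1 - params$w_peer) * parent_prev
  1 + params$s_shs * shs
}

#' Income-adjusted cigarette price
#'
#' Total (retail + tax) price divided by the income index, expressing price
#' relative to average income in each simulated year.
#'
#' @param retail_price Pre-tax retail price, USD/pack.
#' @param excise_tax Excise tax, USD/pack.
#' @param income_index Dimensionless income index (> 0, 1 at 1992).
#' @return Income-adjusted price, USD/pack.
#' @examples
#' real_price(3.56, 0.44, 1.25)  # 3.20
#' @export
real_price <- function(retail_price, excise_tax, income_index) {
  if (any(income_index <= 0)) stop("income index must be > 0")
  (retail_price + excise_tax) / income_index
}

#' Quantity and price multipliers (price and dependence channels)
#'
#' Price moves the average monthly smoking quantity with constant elasticity
#' `eps_q` (<= 0); relative quantity in turn moves initiation and progression
#' (elasticities `s_q_init`, `s_q_prog`), and price separately moves cessation
#' (elasticity `eps_cess`). All multipliers equal 1 at the reference price.
#'
#' @param p_real Income-adjusted price, USD/pack (> 0).
#' @param params A [behavior_params()] with resolved `p_ref`.
#' @return List with `Q` (cigarettes/month), `m_init_q`, `m_prog_q`,
#'   `m_cess_p`.
#' @export
quantity_and_price_multipliers <- function(p_real, params) {
  if (any(p_real <= 0)) stop("price must be > 0")
  if (is.na(params$p_ref) || params$p_ref <= 0)
    stop("p_ref must be resolved and > 0 (build the model first)")
  rel_p <- p_real / params$p_ref
  rel_q <- rel_p^params$eps_q
  list(Q = params$q_ref * rel_q,
       m_init_q = rel_q^params$s_q_init,
       m_prog_q = rel_q^params$s_q_prog,
       m_cess_p = rel_p^params$eps_cess)
}

#' Perceived-availability multiplier (retailer compliance channel)
#'
#' Availability is the complement of retailer compliance, floored at 0.01 to
#' keep the constant-elasticity form finite; the multiplier
#' `(A / A_ref)^s_avail` equals 1 at the cohort's reference compliance and
#' falls as compliance rises.
#'
#' @param compliance Retailer compliance fraction in \[0, 1\].
#' @param cohort `"MIDDLE"` or `"HIGH"` (cohorts have different reference
#'   compliance).
#' @param params A [behavior_params()] with resolved `a_ref`.
#' @return Multiplier >= 0.
#' @export
availability_multiplier <- function(compliance, cohort = c("MIDDLE", "HIGH"), params) {
  cohort <- match.arg(cohort)
  if (any(compliance < 0 | compliance > 1)) stop("compliance must be in [0, 1]")
  a_ref <- params$a_ref[[cohort]]
  if (is.na(a_ref) || a_ref <= 0) stop("a_ref must be resolved and > 0 (build the model first)")
  a <- pmax(1 - compliance, 0.01)
  (a / a_ref)^params$s_avail
}

#' Risk-perception smoothing derivative
#'
#' Perceived risk is proxied by a first-order exponential smoothing of
#' current prevalence: `d(smoothed)/dt = (current - smoothed) / tau_risk`.
#' The smoothed prevalence is itself a stock of the model.
#'
#' @param prev_smoothed Current smoothed prevalence (stock value).
#' @param current_prev Current averaged prevalence.
#' @param tau_risk Smoothing delay, years (> 0).
#' @return Time derivative of the smoothed prevalence, /yr.
#' @export
risk_perception_state <- function(prev_smoothed, current_prev, tau_risk) {
  if (tau_risk <= 0) stop("tau_risk must be > 0")
  (current_prev - prev_smoothed) / tau_risk
}

#' Risk-perception multiplier (balancing loops)
#'
#' Initiation-suppressing multiplier
#' `1 / (1 + s_risk * max(0, smoothed/risk_ref - 1) +
#' s_fund_risk * max(0, funding/F_ref - 1))`: equal to 1 at reference
#' conditions and in (0, 1] when smoothed prevalence or programme funding
#' exceed their references. The prevalence deviation is one-sided: the loop
#' counteracts increases in smoking but does not reward declines below the
#' reference level.
#'
#' @param prev_smoothed Smoothed prevalence (>= 0).
#' @param funding_per_capita Programme funding, USD per capita (>= 0).
#' @param params A [behavior_params()] with resolved `risk_ref`.
#' @return Multiplier in (0, 1].
#' @export
risk_perception_multiplier <- function(prev_smoothed, funding_per_capita, params) {
  if (any(prev_smoothed < 0) || any(funding_per_capita < 0))
    stop("inputs must be non-negative")
  if (is.na(params$risk_ref) || params$risk_ref <= 0)
    stop("risk_ref must be resolved and > 0 (build the model first)")
  dev <- pmax(0, prev_smoothed / params$risk_ref - 1)
  fdev <- pmax(0, funding_per_capita / params$f_ref - 1)
  1 / (1 + params$s_risk * dev + params$s_fund_risk * fdev)
}

#' Tobacco marketing index
#'
#' Baseline marketing `m0`, stepped down by the fraction `m_msa` when the
#' 1998 marketing restrictions take effect, and further lowered by programme
#' funding above its reference (`s_fund` gain, floored at 0). The index
#' multiplies the social-pressure channel of initiation.
#'
#' @param t Year.
#' @param funding_per_capita Programme funding, USD per capita.
#' @param params A [behavior_params()].
#' @param env An [env_inputs()] (provides `msa_year`).
#' @return Marketing index >= 0.
#' @export
marketing_index <- function(t, funding_per_capita, params, env) {
  msa <- step_input(t, env$msa_year, 1, 1 - params$m_msa)
  fund <- pmax(0, 1 - params$s_fund * pmax(0, funding_per_capita / params$f_ref - 1))
  params$m0 * msa * fund
}

#' Multipliers fixed at their reference value
#'
#' Convenience set of unit multipliers, useful for inspecting base-hazard
#' flows in isolation.
#'
#' @return Named list in the format [compute_flows()] expects.
#' @export
unit_multipliers <- function() {
  list(m_social = c(MIDDLE = 1, HIGH = 1),
       m_shs = c(MIDDLE = 1, HIGH = 1),
       m_avail = c(MIDDLE = 1, HIGH = 1),
       m_risk = 1, m_init_q = 1, m_prog_q = 1, m_cess_p = 1,
       q_rel = 1, marketing = 1)
}

## Fixed flow table of the two-cohort chain (order matters: rates are built in
## the same order).
smoking_flow_table <- function() {
  rows <- list(c("entry", "EXTERNAL", "never.MIDDLE"))
  for (ch in COHORTS) {
    rows <- c(rows, list(
      c(paste0("initiation.", ch), paste0("never.", ch), paste0("cur_exp.", ch)),
      c(paste0("quit_exp.", ch), paste0("cur_exp.", ch), paste0("form_exp.", ch)),
      c(paste0("relapse_exp.", ch), paste0("form_exp.", ch), paste0("cur_exp.", ch)),
      c(paste0("progression.", ch), paste0("cur_exp.", ch), paste0("cur_smk.", ch)),
      c(paste0("cessation.", ch), paste0("cur_smk.", ch), paste0("ex_smk.", ch)),
      c(paste0("relapse_smk.", ch), paste0("ex_smk.", ch), paste0("cur_smk.", ch))))
  }
  for (s in SMOKING_STATES)
    rows <- c(rows, list(c(paste0("aging.", s), paste0(s, ".MIDDLE"), paste0(s, ".HIGH"))))
  for (s in SMOKING_STATES)
    rows <- c(rows, list(c(paste0("exit.", s), paste0(s, ".HIGH"), "EXTERNAL")))
  m <- do.call(rbind, rows)
  data.frame(name = m[, 1], source = m[, 2], sink = m[, 3],
             stringsAsFactors = FALSE)
}

## Rates for the flow table above, as a plain numeric vector.
smoking_flow_rates <- function(stocks, m, params, entry) {
  rates <- numeric(23)
  rates[1] <- entry
  i <- 2L
  for (ch in COHORTS) {
    never <- stocks[[paste0("never.", ch)]]
    cur_exp <- stocks[[paste0("cur_exp.", ch)]]
    form_exp <- stocks[[paste0("form_exp.", ch)]]
    cur_smk <- stocks[[paste0("cur_smk.", ch)]]
    ex_smk <- stocks[[paste0("ex_smk.", ch)]]
    msoc <- m$m_social[[ch]]
    rates[i] <- never * params$h_init * msoc * m$m_shs[[ch]] * m$m_avail[[ch]] *
      m$m_risk * m$m_init_q * m$marketing
    rates[i + 1L] <- cur_exp * params$h_quit_exp
    rates[i + 2L] <- form_exp * params$h_rel_exp * msoc
    rates[i + 3L] <- cur_exp * params$h_prog * msoc * m$m_avail[[ch]] * m$m_prog_q
    rates[i + 4L] <- cur_smk * params$h_quit_smk * m$m_cess_p * m$q_rel^(-params$s_nd)
    rates[i + 5L] <- ex_smk * params$h_rel_smk * m$q_rel^params$s_nd
    i <- i + 6L
  }
  for (s in SMOKING_STATES) {
    rates[i] <- stocks[[paste0(s, ".MIDDLE")]] / COHORT_SPAN
    i <- i + 1L
  }
  for (s in SMOKING_STATES) {
    rates[i] <- stocks[[paste0(s, ".HIGH")]] / COHORT_SPAN
    i <- i + 1L
  }
  rates
}

#' Flows of the smoking aging chain
#'
#' Computes every flow of the two-cohort chain at one instant: initiation,
#' experimentation quitting and relapse, progression, cessation, smoker
#' relapse, cohort entry, aging (each MIDDLE stock graduates to the matching
#' HIGH stock at 1/4 per year) and exit from HIGH at the same fractional
#' rate. Behavioural flows are base hazards times the supplied effect
#' multipliers; smoker-side and experimenter-side states are never
#' reconnected (lifetime smoking status is one-way).
#'
#' @param stocks Named stock vector over [smoking_stock_names()].
#' @param multipliers Named list as returned by [unit_multipliers()]: per
#'   cohort `m_social`, `m_shs`, `m_avail`; shared `m_risk`, `m_init_q`,
#'   `m_prog_q`, `m_cess_p`, `q_rel` (relative quantity, drives the
#'   dependence channel) and `marketing`.
#' @param params A [behavior_params()].
#' @param env An [env_inputs()] (provides the entry rate).
#' @param t Year.
#' @return `data.frame` with columns `name`, `source`, `sink`, `rate`
#'   (persons/year, all >= 0).
#' @export
compute_flows <- function(stocks, multipliers, params, env, t) {
  tab <- smoking_flow_table()
  tab$rate <- smoking_flow_rates(stocks, multipliers, params,
                                 entry = env_value(env, "entry_rate", t))
  tab
}

## Resolve NA reference values against 1992 (t0) conditions.
resolve_references <- function(params, env, initial, t0) {
  prev0 <- c(MIDDLE = smoking_prevalence(initial, "MIDDLE"),
             HIGH = smoking_prevalence(initial, "HIGH"))
  parent0 <- env_value(env, "parental_prevalence", t0)
  upd <- list()
  if (is.na(params$p_ref))
    upd$p_ref <- real_price(env_value(env, "retail_price", t0),
                            env_value(env, "excise_tax", t0),
                            env_value(env, "income_index", t0))
  sp <- params$sp_ref
  for (ch in COHORTS)
    if (is.na(sp[[ch]]))
      sp[[ch]] <- params$w_peer * prev0[[ch]] + (1 - params$w_peer) * parent0
  upd$sp_ref <- sp
  a <- params$a_ref
  comp0 <- c(MIDDLE = env_value(env, "compliance_middle", t0),
             HIGH = env_value(env, "compliance_high", t0))
  for (ch in COHORTS)
    if (is.na(a[[ch]])) a[[ch]] <- max(1 - comp0[[ch]], 0.01)
  upd$a_ref <- a
  if (is.na(params$risk_ref)) upd$risk_ref <- averaged_prevalence(initial)
  do.call(update, c(list(object = params), upd))
}

#' Build the runnable smoking model
#'
#' Wires parameters, environment series and initial stocks into an
#' [sd_model()] the engine can run: the ten smoking stocks plus the
#' risk-perception smoothing stock, the full flow table, and an auxiliary
#' function that evaluates every effect multiplier each step. Reference
#' values left `NA` in `params` (`p_ref`, `sp_ref`, `a_ref`, `risk_ref`) are
#' anchored at `t0` conditions so all multipliers start at 1.
#'
#' @param params A [behavior_params()].
#' @param env An [env_inputs()].
#' @param initial Named initial stock vector (default [initial_stocks()] with
#'   populations matching the entry rate at `t0`).
#' @param t0 Anchor year for reference conditions (default 1992).
#' @return An `sd_model` with attributes `params` (references resolved),
#'   `env` and `initial`.
#' @export
build_model <- function(params = behavior_params(), env, initial = NULL,
                        t0 = 1992) {
  stopifnot(inherits(params, "behavior_params"), inherits(env, "env_inputs"))
  if (is.null(initial)) {
    pop <- COHORT_SPAN * env_value(env, "entry_rate", t0)
    initial <- initial_stocks(pop_middle = pop, pop_high = pop)
  }
  if (!all(smoking_stock_names() %in% names(initial)))
    stop("initial stocks must cover ", paste(smoking_stock_names(), collapse = ", "))
  initial <- initial[smoking_stock_names()]
  params <- resolve_references(params, env, initial, t0)
  init <- c(initial, risk = averaged_prevalence(initial))

  flows <- rbind(smoking_flow_table(),
                 data.frame(name = c("risk_in", "risk_out"),
                            source = c("EXTERNAL", "risk"),
                            sink = c("risk", "EXTERNAL"),
                            stringsAsFactors = FALSE))

  aux_fn <- function(state, t) {
    prev_m <- smoking_prevalence(state, "MIDDLE")
    prev_h <- smoking_prevalence(state, "HIGH")
    prev_avg <- (prev_m + prev_h) / 2
    parent <- env_value(env, "parental_prevalence", t)
    funding <- env_value(env, "funding_per_capita", t)
    p_real <- real_price(env_value(env, "retail_price", t),
                         env_value(env, "excise_tax", t),
                         env_value(env, "income_index", t))
    qp <- quantity_and_price_multipliers(p_real, params)
    c(prevalence.MIDDLE = prev_m,
      prevalence.HIGH = prev_h,
      prevalence.avg = prev_avg,
      parent_prev = parent,
      p_real = p_real,
      q_rel = qp$Q / params$q_ref,
      m_social.MIDDLE = social_pressure_multiplier(prev_m, parent, params, "MIDDLE"),
      m_social.HIGH = social_pressure_multiplier(prev_h, parent, params, "HIGH"),
      m_shs.MIDDLE = shs_dependence_multiplier(prev_m, parent, params),
      m_shs.HIGH = shs_dependence_multiplier(prev_h, parent, params),
      m_avail.MIDDLE = availability_multiplier(env_value(env, "compliance_middle", t), "MIDDLE", params),
      m_avail.HIGH = availability_multiplier(env_value(env, "compliance_high", t), "HIGH", params),
      m_risk = risk_perception_multiplier(state[["risk"]], funding, params),
      m_init_q = qp$m_init_q,
      m_prog_q = qp$m_prog_q,
      m_cess_p = qp$m_cess_p,
      marketing = marketing_index(t, funding, params, env),
      entry = env_value(env, "entry_rate", t),
      funding = funding)
  }

  rates_fn <- function(state, aux, t) {
    m <- list(m_social = c(MIDDLE = aux[["m_social.MIDDLE"]], HIGH = aux[["m_social.HIGH"]]),
              m_shs = c(MIDDLE = aux[["m_shs.MIDDLE"]], HIGH = aux[["m_shs.HIGH"]]),
              m_avail = c(MIDDLE = aux[["m_avail.MIDDLE"]], HIGH = aux[["m_avail.HIGH"]]),
              m_risk = aux[["m_risk"]], m_init_q = aux[["m_init_q"]],
              m_prog_q = aux[["m_prog_q"]], m_cess_p = aux[["m_cess_p"]],
              q_rel = aux[["q_rel"]], marketing = aux[["marketing"]])
    d_risk <- risk_perception_state(state[["risk"]], aux[["prevalence.avg"]], params$tau_risk)
    c(smoking_flow_rates(state, m, params, aux[["entry"]]),
      max(0, d_risk), max(0, -d_risk))
  }

  model <- sd_model(init, flows, rates_fn, aux_fn)
  attr(model, "params") <- params
  attr(model, "env") <- env
  attr(model, "initial") <- initial
  model
}

#' Yearly prevalence series from a trajectory
#'
#' @param traj An `sd_trajectory` from the smoking model.
#' @param cohort `"AVERAGED"` (default), `"MIDDLE"` or `"HIGH"`.
#' @param years Years at which to sample (default: integer years on the
#'   simulated horizon).
#' @return `data.frame(year, prevalence)`.
#' @export
prevalence_series <- function(traj, cohort = c("AVERAGED", "MIDDLE", "HIGH"),
                              years = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(years))
    years <- seq(ceiling(min(traj$times)), floor(max(traj$times)))
  var <- switch(cohort, AVERAGED = "prevalence.avg",
                MIDDLE = "prevalence.MIDDLE", HIGH = "prevalence.HIGH")
  data.frame(year = years, prevalence = traj_value(traj, var, years))
}
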