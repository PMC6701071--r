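## Behavioural parameters and exogenous environment inputs for the youth
## smoking model.

#' Behavioural parameters of the youth smoking model
#'
#' Base hazards (per year) for the transitions of the smoking aging chain and
#' the strengths of the feedback channels that modulate them. Every effect is
#' a multiplicative modifier on a base hazard, normalised to 1 at reference
#' conditions anchored at the start of the historical window (1992), so that
#' switched-off channels (strength 0) leave the linear chain untouched.
#'
#' The hazard and strength defaults are the package's standard calibration to
#' the bundled synthetic prevalence target (see
#' [generate_target_series()]); elasticity magnitudes are in the range
#' reported for youth smoking in the econometric literature, and the softer
#' gains are set so the three policy levers rank tax > programme funding >
#' retailer compliance, the ordering established in tobacco-control research.
#'
#' @param h_init Base initiation hazard, /yr (never-smoker to current
#'   experimenter).
#' @param h_prog Base progression hazard, /yr (current experimenter to current
#'   smoker, i.e. crossing 100 lifetime cigarettes).
#' @param h_quit_exp Base hazard of experimentation pausing, /yr (current to
#'   former experimenter).
#' @param h_quit_smk Base cessation hazard, /yr (current smoker to ex-smoker).
#' @param h_rel_exp Relapse hazard of former experimenters, /yr.
#' @param h_rel_smk Relapse hazard of ex-smokers, /yr.
#' @param s_social Social-pressure elasticity (reinforcing loop: peer and
#'   parental smoking raise initiation, progression and experimenter relapse).
#' @param s_shs Secondhand-smoke-to-dependence initiation gain (linear gain on
#'   the shared exposure index).
#' @param s_avail Perceived-availability elasticity (retailer compliance
#'   channel).
#' @param s_risk Risk-perception gain (balancing loop: smoothed prevalence
#'   above its 1992 anchor suppresses initiation).
#' @param eps_q Price elasticity of monthly smoking quantity (<= 0).
#' @param s_q_init,s_q_prog Elasticities of initiation/progression with
#'   respect to relative smoking quantity.
#' @param eps_cess Price elasticity of cessation (>= 0).
#' @param s_nd Nicotine-dependence elasticity: relative quantity attenuates
#'   cessation and fuels relapse.
#' @param w_peer Weight of peer (vs parental) prevalence in the social
#'   pressure and secondhand-smoke indices, in \[0, 1\].
#' @param tau_risk Risk-perception smoothing delay, years (> 0).
#' @param m_msa Fractional reduction of the marketing index from the 1998
#'   Master Settlement Agreement marketing restrictions, in \[0, 1\].
#' @param s_fund Programme-funding-to-marketing gain.
#' @param s_fund_risk Programme-funding-to-risk-perception gain.
#' @param m0 Baseline marketing index (pre-restriction), dimensionless.
#' @param p_ref Reference income-adjusted cigarette price, USD/pack; `NA`
#'   means "derive from the environment at 1992 when the model is built".
#' @param q_ref Reference monthly smoking quantity, cigarettes/month.
#' @param sp_ref Named vector (`MIDDLE`, `HIGH`) of reference social-pressure
#'   indices; `NA` derived at model build from 1992 conditions.
#' @param a_ref Named vector (`MIDDLE`, `HIGH`) of reference perceived
#'   availability (1 - reference compliance); `NA` derived at model build.
#' @param f_ref Reference comprehensive-programme funding, USD per capita.
#' @param risk_ref Reference smoothed prevalence anchoring the risk-perception
#'   loop; `NA` derived from the initial stocks.
#' @return An object of class `behavior_params` (a validated named list).
#' @seealso [update.behavior_params()], [build_model()]
#' @export
behavior_params <- function(h_init = 0.133,
                            h_prog = 0.25,
                            h_quit_exp = 0.90,
                            h_quit_smk = 0.15,
                            h_rel_exp = 0.35,
                            h_rel_smk = 0.06,
                            s_social = 0.80,
                            s_shs = 0.5,
                            s_avail = 0.0055,
                            s_risk = 0.16,
                            eps_q = -0.9,
                            s_q_init = 0.14,
                            s_q_prog = 0.14,
                            eps_cess = 0.95,
                            s_nd = 0.45,
                            w_peer = 0.7,
                            tau_risk = 3,
                            m_msa = 0.41,
                            s_fund = 0.013,
                            s_fund_risk = 0.010,
                            m0 = 1,
                            p_ref = NA_real_,
                            q_ref = 100,
                            sp_ref = c(MIDDLE = NA_real_, HIGH = NA_real_),
                            a_ref = c(MIDDLE = NA_real_, HIGH = NA_real_),
                            f_ref = 9.80,
                            risk_ref = NA_real_) {
  p <- list(h_init = h_init, h_prog = h_prog, h_quit_exp = h_quit_exp,
            h_quit_smk = h_quit_smk, h_rel_exp = h_rel_exp,
            h_rel_smk = h_rel_smk, s_social = s_social, s_shs = s_shs,
            s_avail = s_avail, s_risk = s_risk, eps_q = eps_q,
            s_q_init = s_q_init, s_q_prog = s_q_prog, eps_cess = eps_cess,
            s_nd = s_nd, w_peer = w_peer, tau_risk = tau_risk, m_msa = m_msa,
            s_fund = s_fund, s_fund_risk = s_fund_risk, m0 = m0,
            p_ref = p_ref, q_ref = q_ref,
            sp_ref = expand_cohort(sp_ref, "sp_ref"),
            a_ref = expand_cohort(a_ref, "a_ref"),
            f_ref = f_ref, risk_ref = risk_ref)
  validate_behavior_params(p)
  structure(p, class = "behavior_params")
}

expand_cohort <- function(x, what) {
  if (length(x) == 1L) x <- c(MIDDLE = unname(x), HIGH = unname(x))
  if (!all(c("MIDDLE", "HIGH") %in% names(x)))
    stop(what, " must be named with cohorts MIDDLE and HIGH")
  x[c("MIDDLE", "HIGH")]
}

validate_behavior_params <- function(p) {
  hz <- c("h_init", "h_prog", "h_quit_exp", "h_quit_smk", "h_rel_exp", "h_rel_smk")
  for (h in hz) if (p[[h]] < 0) stop(h, " must be >= 0")
  if (p$w_peer < 0 || p$w_peer > 1) stop("w_peer must be in [0, 1]")
  if (p$m_msa < 0 || p$m_msa > 1) stop("m_msa must be in [0, 1]")
  if (p$eps_q > 0) stop("eps_q (price elasticity of quantity) must be <= 0")
  if (p$eps_cess < 0) stop("eps_cess (price elasticity of cessation) must be >= 0")
  if (p$tau_risk <= 0) stop("tau_risk must be > 0")
  for (r in c("q_ref", "f_ref", "m0"))
    if (p[[r]] <= 0) stop(r, " must be > 0")
  for (r in c("p_ref", "risk_ref"))
    if (!is.na(p[[r]]) && p[[r]] <= 0) stop(r, " must be > 0")
  for (r in c("sp_ref", "a_ref"))
    if (any(!is.na(p[[r]]) & p[[r]] <= 0)) stop(r, " must be > 0")
  invisible(p)
}

#' Update behavioural parameters
#'
#' @param object A `behavior_params` object.
#' @param ... Named fields to replace (revalidated).
#' @return A new `behavior_params` object.
#' @export
update.behavior_params <- function(object, ...) {
  new <- utils::modifyList(unclass(object), list(...))
  for (r in c("sp_ref", "a_ref")) new[[r]] <- expand_cohort(new[[r]], r)
  validate_behavior_params(new)
  structure(new, class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("<behavior_params>\n")
  cat("  hazards (/yr): init", x$h_init, "prog", x$h_prog,
      "quit_exp", x$h_quit_exp, "quit_smk", x$h_quit_smk,
      "rel_exp", x$h_rel_exp, "rel_smk", x$h_rel_smk, "\n")
  cat("  loop strengths: s_social", x$s_social, "s_shs", x$s_shs,
      "s_avail", x$s_avail, "s_risk", x$s_risk, "s_nd", x$s_nd, "\n")
  cat("  price channel: eps_q", x$eps_q, "s_q_init", x$s_q_init,
      "s_q_prog", x$s_q_prog, "eps_cess", x$eps_cess, "\n")
  cat("  marketing/funding: m_msa", x$m_msa, "s_fund", x$s_fund,
      "s_fund_risk", x$s_fund_risk, "\n")
  cat("  references: p_ref", x$p_ref, "q_ref", x$q_ref, "f_ref", x$f_ref,
      "risk_ref", x$risk_ref, "\n")
  invisible(x)
}

#' Exogenous environment inputs
#'
#' Year-indexed exogenous series driving the model: pre-tax retail cigarette
#' price, excise tax, an income index (1 at 1992) used to express prices in
#' income-adjusted terms, the cohort entry rate, adult/parental smoking
#' prevalence, and per-capita comprehensive-programme funding, plus per-cohort
#' retailer compliance. Series are linearly interpolated on the simulation
#' grid and extrapolated as constants beyond their endpoints. Policy levers
#' are applied as step overrides (see [apply_scenario()]).
#'
#' @param retail_price Pre-tax price series, USD/pack (`data.frame(year,
#'   value)` or named numeric vector).
#' @param excise_tax Excise tax series, USD/pack.
#' @param income_index Dimensionless income index series (1 at 1992).
#' @param entry_rate Persons/yr entering the MIDDLE cohort.
#' @param parental_prevalence Adult/parental smoking prevalence series
#'   (fractions in \[0, 1\]).
#' @param funding_per_capita Comprehensive-programme funding series, USD per
#'   capita.
#' @param compliance Named vector (`MIDDLE`, `HIGH`) of retailer compliance
#'   fractions in \[0, 1\]. Defaults follow the Methods reading of the source
#'   surveys: 0.73 for middle school, 0.78 for high school (the reverse
#'   assignment can be supplied explicitly).
#' @param msa_year Year marketing restrictions take effect (default 1998).
#' @return An object of class `env_inputs`.
#' @export
env_inputs <- function(retail_price, excise_tax, income_index, entry_rate,
                       parental_prevalence, funding_per_capita,
                       compliance = c(MIDDLE = 0.73, HIGH = 0.78),
                       msa_year = 1998) {
  compliance <- expand_cohort(compliance, "compliance")
  if (any(compliance < 0 | compliance > 1))
    stop("compliance fractions must be in [0, 1]")
  series <- list(retail_price = as_series(retail_price),
                 excise_tax = as_series(excise_tax),
                 income_index = as_series(income_index),
                 entry_rate = as_series(entry_rate),
                 parental_prevalence = as_series(parental_prevalence),
                 funding_per_capita = as_series(funding_per_capita),
                 compliance_middle = data.frame(year = 1992, value = unname(compliance["MIDDLE"])),
                 compliance_high = data.frame(year = 1992, value = unname(compliance["HIGH"])))
  for (nm in names(series)) {
    if (nrow(series[[nm]]) == 0L) stop("series '", nm, "' is empty")
  }
  pp <- series$parental_prevalence$value
  if (any(pp < 0 | pp > 1)) stop("parental_prevalence must be in [0, 1]")
  fns <- lapply(series, function(s) {
    if (nrow(s) == 1L) {
      v <- s$value
      function(t) rep(v, length(t))
    } else {
      stats::approxfun(s$year, s$value, rule = 2)
    }
  })
  structure(list(series = series, fns = fns, steps = list(), msa_year = msa_year),
            class = "env_inputs")
}

#' Evaluate an environment series at a time
#'
#' @param env An `env_inputs` object.
#' @param name One of `retail_price`, `excise_tax`, `income_index`,
#'   `entry_rate`, `parental_prevalence`, `funding_per_capita`,
#'   `compliance_middle`, `compliance_high`.
#' @param t Time(s).
#' @return Value(s), with any policy step override applied.
#' @export
env_value <- function(env, name, t) {
  fn <- env$fns[[name]]
  if (is.null(fn)) stop("no environment series named '", name, "'")
  v <- fn(t)
  st <- env$steps[[name]]
  if (!is.null(st)) v <- step_input(t, st$t_switch, v, st$after)
  v
}

## Attach a step override to a series (used by policy scenarios).
env_with_step <- function(env, name, t_switch, after) {
  if (is.null(env$fns[[name]])) stop("no environment series named '", name, "'")
  env$steps[[name]] <- list(t_switch = t_switch, after = after)
  env
}

#' @export
print.env_inputs <- function(x, ...) {
  spans <- vapply(x$series, function(s) paste(range(s$year), collapse = "-"), "")
  cat("<env_inputs>\n")
  for (nm in names(x$series)) {
    stepped <- if (!is.null(x$steps[[nm]]))
      sprintf("  [step to %g at %g]", x$steps[[nm]]$after, x$steps[[nm]]$t_switch) else ""
    cat(sprintf("  %-20s %s%s\n", nm, spans[[nm]], stepped))
  }
  cat("  msa_year:", x$msa_year, "\n")
  invisible(x)
}
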