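## Generic deterministic stock-and-flow engine: fixed-grid explicit Euler over
## named stocks, with auxiliaries evaluated before flows at every step.

#' Simulation time grid
#'
#' Defines the uniform time grid a simulation runs on. The default horizon is
#' 1992--2032 with a step of 1/8 year; the step must divide the horizon into an
#' integer number of steps.
#'
#' @param t_start First year (continuous time, default 1992).
#' @param t_end Last year (default 2032).
#' @param dt Step length in years (a fraction of a year, default 0.125).
#' @return An object of class `time_grid` with elements `t_start`, `t_end`,
#'   `dt`, `n_steps` and the vector of grid `times`.
#' @examples
#' time_grid(1992, 2032, 0.25)
#' @export
time_grid <- function(t_start = 1992, t_end = 2032, dt = 0.125) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(dt),
            length(t_start) == 1L, length(t_end) == 1L, length(dt) == 1L)
  if (dt <= 0) stop("dt must be > 0")
  if (t_start >= t_end) stop("t_start must be < t_end")
  n <- (t_end - t_start) / dt
  if (abs(n - round(n)) > 1e-8)
    stop("(t_end - t_start)/dt must be an integer number of steps")
  n <- as.integer(round(n))
  structure(list(t_start = t_start, t_end = t_end, dt = dt, n_steps = n,
                 times = t_start + dt * (0:n)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %s to %s, dt = %g yr (%d steps)\n",
              format(x$t_start), format(x$t_end), x$dt, x$n_steps))
  invisible(x)
}

#' Step input (piecewise-constant switch)
#'
#' Returns `before` for times strictly before `t_switch` and `after` from
#' `t_switch` onwards (left-closed convention: a policy implemented in a given
#' year acts from the start of that year).
#'
#' @param t Time(s) at which to evaluate (vectorised).
#' @param t_switch Switch time.
#' @param before,after Values before/after the switch.
#' @return Value(s) of the step function at `t`.
#' @examples
#' step_input(2014.9, 2015, 0.44, 2.20)  # 0.44
#' step_input(2015.0, 2015, 0.44, 2.20)  # 2.20
#' @export
step_input <- function(t, t_switch, before, after) {
  ifelse(t < t_switch, before, after)
}

## Normalise a year->value series to an ordered data.frame(year, value).
as_series <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("year", "value") %in% names(series)))
      stop("series data frame must have columns 'year' and 'value'")
    s <- series[, c("year", "value")]
  } else if (is.numeric(series) && !is.null(names(series))) {
    s <- data.frame(year = as.numeric(names(series)), value = unname(series))
  } else {
    stop("series must be a data.frame(year, value) or a named numeric vector")
  }
  if (anyNA(s$year) || anyNA(s$value)) stop("series contains missing values")
  s[order(s$year), , drop = FALSE]
}

#' Interpolate a yearly series at arbitrary times
#'
#' Linear interpolation between bracketing years with constant extrapolation
#' beyond the endpoints, so yearly exogenous inputs are defined on sub-year
#' simulation grids.
#'
#' @param series A `data.frame(year, value)` or a named numeric vector whose
#'   names are years.
#' @param t Time(s) at which to evaluate (vectorised).
#' @return Interpolated value(s).
#' @examples
#' interpolate_series(c(`1992` = 10, `1994` = 20), 1993)  # 15
#' @export
interpolate_series <- function(series, t) {
  s <- as_series(series)
  if (nrow(s) == 0L) stop("empty series")
  if (nrow(s) == 1L) return(rep(s$value, length(t)))
  stats::approx(s$year, s$value, xout = t, rule = 2)$y
}

#' Define a stock-and-flow model
#'
#' Assembles a model specification the engine can run: initial stock levels, a
#' flow table (each flow moves quantity from a source stock to a sink stock, or
#' across the model boundary via `"EXTERNAL"`), a rate function, and an
#' optional auxiliary function. Per step the engine evaluates auxiliaries,
#' then flow rates, then updates the stocks.
#'
#' @param init Named numeric vector of initial stock levels (all >= 0).
#' @param flows `data.frame` with columns `name`, `source`, `sink`; sources and
#'   sinks are stock names or `"EXTERNAL"`.
#' @param rates_fn `function(state, aux, t)` returning a numeric vector of
#'   non-negative rates, one per row of `flows`, in the same order.
#' @param aux_fn Optional `function(state, t)` returning a named numeric vector
#'   of auxiliary values (multipliers, prices, prevalences) recorded in the
#'   trajectory.
#' @return An object of class `sd_model`.
#' @export
sd_model <- function(init, flows, rates_fn, aux_fn = NULL) {
  stopifnot(is.numeric(init), !is.null(names(init)))
  if (anyDuplicated(names(init))) stop("stock identifiers must be unique")
  if (any(init < 0)) stop("initial stock levels must be non-negative")
  stopifnot(is.data.frame(flows),
            all(c("name", "source", "sink") %in% names(flows)))
  if (anyDuplicated(flows$name)) stop("flow names must be unique")
  ok <- c(names(init), "EXTERNAL")
  bad <- setdiff(unique(c(flows$source, flows$sink)), ok)
  if (length(bad))
    stop("unknown stock(s) in flow table: ", paste(bad, collapse = ", "))
  stopifnot(is.function(rates_fn), is.null(aux_fn) || is.function(aux_fn))
  ## incidence matrix: stocks x flows, -1 out of source, +1 into sink
  inc <- matrix(0, nrow = length(init), ncol = nrow(flows),
                dimnames = list(names(init), flows$name))
  for (j in seq_len(nrow(flows))) {
    if (flows$source[j] != "EXTERNAL") inc[flows$source[j], j] <- inc[flows$source[j], j] - 1
    if (flows$sink[j] != "EXTERNAL") inc[flows$sink[j], j] <- inc[flows$sink[j], j] + 1
  }
  structure(list(init = init, flows = flows[, c("name", "source", "sink")],
                 rates_fn = rates_fn, aux_fn = aux_fn, inc = inc),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cat(sprintf("<sd_model> %d stocks, %d flows\n", length(x$init), nrow(x$flows)))
  invisible(x)
}

#' Advance stocks by one explicit-Euler step
#'
#' For each stock, new level = old level + dt * (inflows - outflows). A stock
#' driven below zero within the step signals an integration-underflow error
#' (the step is too large or a flow equation is malformed) rather than being
#' clamped.
#'
#' @param state Named numeric vector of stock levels.
#' @param flows `data.frame` with columns `source`, `sink`, `rate`
#'   (persons/year, non-negative); source/sink are stock names or
#'   `"EXTERNAL"`.
#' @param dt Step length in years (> 0).
#' @return Updated named numeric state vector.
#' @examples
#' euler_step(c(S = 1000), data.frame(name = "out", source = "S",
#'                                    sink = "EXTERNAL", rate = 50), 0.25)
#' @export
euler_step <- function(state, flows, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(flows$rate < 0)) stop("flow rates must be non-negative")
  net <- setNames(numeric(length(state)), names(state))
  src <- flows$source %in% names(state)
  if (any(src)) {
    o <- rowsum(flows$rate[src], flows$source[src])
    net[rownames(o)] <- net[rownames(o)] - o[, 1]
  }
  snk <- flows$sink %in% names(state)
  if (any(snk)) {
    i <- rowsum(flows$rate[snk], flows$sink[snk])
    net[rownames(i)] <- net[rownames(i)] + i[, 1]
  }
  new <- state + dt * net
  neg <- new < -1e-9 * pmax(abs(state), 1)
  if (any(neg))
    stop("integration underflow: stock(s) ", paste(names(state)[neg], collapse = ", "),
         " would go negative; reduce dt or check flow equations")
  pmax(new, 0)
}

#' Run a stock-and-flow simulation
#'
#' Integrates a model over a time grid with explicit Euler. At each grid point
#' auxiliaries are evaluated first, then flow rates, then the stocks are
#' advanced; the returned trajectory records stocks, all auxiliaries
#' (including every effect multiplier), and all flow rates at every grid
#' point.
#'
#' @param model An `sd_model`.
#' @param grid A `time_grid`.
#' @return An object of class `sd_trajectory` with elements `times`, `stocks`,
#'   `aux`, `flows` (matrices with one row per grid point), `flow_table` and
#'   `dt`.
#' @export
run_simulation <- function(model, grid) {
  stopifnot(inherits(model, "sd_model"), inherits(grid, "time_grid"))
  times <- grid$times
  n1 <- length(times)
  dt <- grid$dt
  state <- model$init
  aux <- if (is.null(model$aux_fn)) numeric(0) else model$aux_fn(state, times[1])
  if (length(aux) && is.null(names(aux))) stop("aux_fn must return a named vector")
  S <- matrix(NA_real_, n1, length(state), dimnames = list(NULL, names(state)))
  AX <- matrix(NA_real_, n1, length(aux), dimnames = list(NULL, names(aux)))
  FL <- matrix(NA_real_, n1, nrow(model$flows), dimnames = list(NULL, model$flows$name))
  inc <- model$inc
  for (i in seq_len(n1)) {
    t <- times[i]
    if (i > 1L && !is.null(model$aux_fn)) aux <- model$aux_fn(state, t)
    rates <- model$rates_fn(state, aux, t)
    if (length(rates) != nrow(model$flows))
      stop("rates_fn must return one rate per flow")
    if (any(!is.finite(rates)))
      stop(sprintf("non-finite flow rate at t = %.4g: %s (missing exogenous input?)",
                   t, paste(model$flows$name[!is.finite(rates)], collapse = ", ")))
    if (any(rates < 0))
      stop(sprintf("negative flow rate at t = %.4g: %s",
                   t, paste(model$flows$name[rates < 0], collapse = ", ")))
    S[i, ] <- state
    if (length(aux)) AX[i, ] <- aux
    FL[i, ] <- rates
    if (i < n1) {
      state <- state + dt * drop(inc %*% rates)
      neg <- state < -1e-9 * pmax(abs(S[i, ]), 1)
      if (any(neg))
        stop(sprintf("integration underflow: stock(s) %s negative at t = %.4g; reduce dt or check flow equations",
                     paste(colnames(S)[neg], collapse = ", "), t + dt))
      state[state < 0] <- 0
    }
  }
  structure(list(times = times, stocks = S, aux = AX, flows = FL,
                 flow_table = model$flows, dt = dt),
            class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("<sd_trajectory> %s to %s (dt = %g): %d stocks, %d auxiliaries, %d flows\n",
              format(min(x$times)), format(max(x$times)), x$dt,
              ncol(x$stocks), ncol(x$aux), ncol(x$flows)))
  invisible(x)
}

#' Extract a recorded variable from a trajectory
#'
#' Looks the variable up among stocks, then auxiliaries, then flow rates, and
#' linearly interpolates between grid points. Times outside the simulated
#' horizon signal a coverage error.
#'
#' @param traj An `sd_trajectory`.
#' @param name Variable name.
#' @param t Time(s) at which to evaluate; defaults to all grid points.
#' @return Numeric vector of values at `t`.
#' @export
traj_value <- function(traj, name, t = NULL) {
  stopifnot(inherits(traj, "sd_trajectory"))
  col <- if (name %in% colnames(traj$stocks)) traj$stocks[, name]
         else if (name %in% colnames(traj$aux)) traj$aux[, name]
         else if (name %in% colnames(traj$flows)) traj$flows[, name]
         else stop("no variable named '", name, "' in trajectory")
  if (is.null(t)) return(col)
  if (any(t < min(traj$times) - 1e-9) || any(t > max(traj$times) + 1e-9))
    stop("requested time outside the simulated horizon")
  stats::approx(traj$times, col, xout = t, rule = 2)$y
}

#' Tidy a trajectory into long format
#'
#' @param x An `sd_trajectory`.
#' @param row.names,optional Unused, for generic consistency.
#' @param ... Unused.
#' @return A `data.frame` with columns `time`, `variable`, `cohort`
#'   (`MIDDLE`/`HIGH`/`NA` parsed from the variable suffix) and `value`,
#'   covering stocks and auxiliaries.
#' @export
as.data.frame.sd_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  m <- cbind(x$stocks, x$aux)
  vars <- colnames(m)
  cohort <- ifelse(grepl("\\.MIDDLE$", vars), "MIDDLE",
                   ifelse(grepl("\\.HIGH$", vars), "HIGH", NA_character_))
  base <- sub("\\.(MIDDLE|HIGH)$", "", vars)
  data.frame(time = rep(x$times, times = length(vars)),
             variable = rep(base, each = length(x$times)),
             cohort = rep(cohort, each = length(x$times)),
             value = as.vector(m),
             stringsAsFactors = FALSE)
}

#' Write a trajectory as tidy CSV
#'
#' @param traj An `sd_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
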