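# Shared fixtures, built in code. Expensive base objects are memoised so the
# suite builds them once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_env <- function() fixture("env", function() generate_env_inputs())

default_target <- function() fixture("target", function() generate_target_series())

default_grid <- function() time_grid(1992, 2032, 0.125)

coarse_grid <- function() time_grid(1992, 2032, 0.25)

base_trajectory <- function() {
  fixture("base_traj", function()
    run_simulation(build_model(behavior_params(), default_env()), default_grid()))
}

base_outcomes <- function() {
  fixture("outcomes", function()
    run_policy_comparison(behavior_params(), default_env(), grid = default_grid()))
}

# A tiny single-stock decay model for engine tests.
decay_model <- function(k = 0.1, s0 = 1000) {
  sd_model(init = c(S = s0),
           flows = data.frame(name = "out", source = "S", sink = "EXTERNAL"),
           rates_fn = function(state, aux, t) k * state[["S"]])
}

# Pure stock-to-stock linear chain S1 -> S2 -> S3 with hazards k.
chain_model <- function(k = c(0.5, 0.25), init = c(S1 = 1000, S2 = 0, S3 = 0)) {
  flows <- data.frame(name = c("f12", "f23"),
                      source = c("S1", "S2"), sink = c("S2", "S3"))
  sd_model(init, flows, function(state, aux, t)
    c(k[1] * state[["S1"]], k[2] * state[["S2"]]))
}
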