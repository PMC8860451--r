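# sessions are expensive to synthesise; build each fixture once per test run
.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.session_cache[[key]])) {
    assign(key, force(expr), envir = .session_cache)
  }
  .session_cache[[key]]
}

# mid-size ramp-mode session at a reduced rate: enough trials for model fits
ramp_session_250 <- function() {
  cached("ramp250", simulate_session(
    generative_params(n_trials = 150),
    task_config(sampling_rate = 250), seed = 42))
}

step_session_250 <- function() {
  cached("step250", simulate_session(
    generative_params(n_trials = 150, dynamics_mode = "step"),
    task_config(sampling_rate = 250), seed = 43))
}

session_dff <- function(s, channel = "gcamp") {
  key <- paste0("dff_", channel, "_", rlang::hash(s$seed))
  cached(key, compute_dff(
    remove_singularities(s$channels[[channel]]), "moving_average",
    s$trials, fs = s$config$sampling_rate))
}

ramp_intervals_100 <- function() {
  cached("iv_ramp", {
    s <- ramp_session_250()
    ramping_intervals(s, session_dff(s), out_rate = 100)
  })
}

step_intervals_100 <- function() {
  cached("iv_step", {
    s <- step_session_250()
    ramping_intervals(s, session_dff(s), out_rate = 100)
  })
}

# tiny deterministic trial table for unit tests that only need bookkeeping
toy_trials <- function(licks, cfg = task_config(), seed = 1) {
  build_trial_timeline(licks, cfg, seed = seed)
}
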