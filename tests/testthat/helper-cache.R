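## Shared fixtures: the expensive simulation runs are computed once per test
## session and reused across files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

steady_normal <- function() {
  cached("steady_normal", run_to_steady_state(model_config()))
}

condition_normal <- function() {
  cached("condition_normal", pvloopva:::.analyze_condition("normal", 80))
}

condition_stiff <- function() {
  cached("condition_stiff", pvloopva:::.analyze_condition("stiff", 80))
}

phase1_table <- function() cached("phase1", run_phase1())
phase2_table <- function() cached("phase2", run_phase2())

## last complete beat window of a steady trajectory
last_beat <- function(ts, heart_rate) {
  period <- 60 / heart_rate
  k <- floor(max(ts$time) / period + 1e-9) - 1
  ts[ts$time >= k * period - 1e-9 & ts$time < (k + 1) * period - 1e-9, ]
}

## equilibrium state: every chamber at its unstressed volume, every
## compartment at its unstressed volume (all pressures zero)
equilibrium_state <- function(config) {
  y <- c(config$chambers$V0, config$compartments$unstressed_volume)
  names(y) <- c(rownames(config$chambers), config$compartments$name)
  y
}
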