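## Experiment drivers: graded compliance settings, proportional vascular
## scaling, the VCO maneuver, and the Phase I / Phase II study loops.

## The five graded vascular-aging settings: equivalent arterial compliance
## C_A (ml/mmHg) and total peripheral resistance R_T (mmHg·s/ml).
.compliance_levels <- data.frame(
  level = c("normal", "90pct", "80pct", "60pct", "stiff"),
  C_A = c(0.7, 0.63, 0.56, 0.42, 0.19),
  R_T = c(1.28, 1.41, 1.54, 1.805, 3.66),
  stringsAsFactors = FALSE
)

#' Graded aortic-compliance settings
#'
#' Returns the packaged (C_A, R_T) pair for one of the five vascular-aging
#' levels: `normal` (0.7, 1.28), `90pct` (0.63, 1.41), `80pct` (0.56, 1.54),
#' `60pct` (0.42, 1.805) and `stiff` (0.19, 3.66).
#'
#' @param level one of `"normal"`, `"90pct"`, `"80pct"`, `"60pct"`,
#'   `"stiff"`.
#' @return list with `level`, `C_A` (ml/mmHg) and `R_T` (mmHg·s/ml).
#' @examples
#' compliance_setting("stiff")$C_A  # 0.19
#' @export
compliance_setting <- function(level) {
  i <- match(level, .compliance_levels$level)
  if (is.na(i))
    stop("unknown compliance level '", level, "'; valid levels: ",
         paste(.compliance_levels$level, collapse = ", "))
  as.list(.compliance_levels[i, ])
}

#' Scale the arterial tree to a target compliance and resistance
#'
#' Every arterial compartment's compliance is multiplied by
#' `C_A_target / C_A_current` and every arterial-path resistance (arch
#' outflow plus the distal branch inflow/outflow pairs) by
#' `R_T_target / R_T_current`, so the proximal/distal split ratios are
#' preserved and the series/parallel reduction lands exactly on the target.
#' The venous and pulmonary sides are untouched.
#'
#' @param config a `cv_config`.
#' @param setting a setting from [compliance_setting()] (or any list with
#'   `C_A` and `R_T`).
#' @return the rescaled `cv_config` (with `R_T` updated).
#' @export
apply_vascular_scaling <- function(config, setting) {
  validate_config(config)
  ca_now <- equivalent_arterial_compliance(config)
  rt_now <- total_peripheral_resistance(config)
  if (ca_now <= 0) stop("current equivalent compliance is singular")
  cf <- setting$C_A / ca_now
  rf <- setting$R_T / rt_now
  cp <- config$compartments
  art <- cp$name %in% .arterial_comps
  cp$compliance[art] <- cp$compliance[art] * cf
  cp$resistance_out[cp$name == "aortic_arch"] <-
    cp$resistance_out[cp$name == "aortic_arch"] * rf
  dist <- cp$name %in% .distal_comps
  cp$resistance_in[dist] <- cp$resistance_in[dist] * rf
  cp$resistance_out[dist] <- cp$resistance_out[dist] * rf
  config$compartments <- cp
  config$R_T <- setting$R_T
  validate_config(config)
  config
}

#' Simulated vena caval occlusion experiment
#'
#' Brings the model to periodic steady state at the requested compliance
#' setting and pacing rate, then ramps the thoracic-vein outflow resistance
#' (the VCO) starting at the next beat onset and continues for `window`
#' seconds.  The returned trajectory concatenates both segments; the
#' attribute `vco_start` marks the boundary.
#'
#' @param setting a compliance setting (from [compliance_setting()]), or a
#'   level name.
#' @param heart_rate pacing rate, bpm.
#' @param vco occlusion schedule from [vco_params()]; its `start_time` is
#'   replaced by the steady-state boundary.
#' @param window post-occlusion simulation window, s.
#' @param config base configuration to scale (defaults to the packaged one;
#'   its heart rate is overridden).
#' @return a `cv_timeseries` spanning the last steady beats and the
#'   occlusion, with attributes `vco_start`, `converged` and `level`.
#' @export
run_vco_experiment <- function(setting, heart_rate = 80,
                               vco = vco_params(resistance_multiplier = 100,
                                                ramp_duration = 8),
                               window = 12,
                               config = model_config()) {
  if (is.character(setting)) setting <- compliance_setting(setting)
  cfg <- config
  cfg$heart_rate <- heart_rate
  cfg <- apply_vascular_scaling(cfg, setting)
  ss <- run_to_steady_state(cfg)
  period <- 60 / heart_rate
  t_start <- ceiling(ss$time / period - 1e-9) * period
  cfg$vco <- vco
  cfg$vco$start_time <- t_start
  ts2 <- simulate_model(cfg, (t_start - ss$time) + window, ss$state,
                        t0 = ss$time)
  ## keep the last 2 steady beats for context + the occlusion window
  keep_from <- t_start - 2 * period
  pre <- ss$timeseries[ss$timeseries$time >= keep_from - 1e-9, , drop = FALSE]
  ts <- rbind(pre, ts2[-1, , drop = FALSE])
  structure(ts, class = c("cv_timeseries", "data.frame"),
            heart_rate = heart_rate, vco_start = t_start,
            converged = ss$converged,
            level = if (!is.null(setting$level)) setting$level else NA)
}

## Analyse one condition end to end: VCO run -> beats -> metrics -> fits.
## Returns the study-table row plus the per-beat metrics.
.analyze_condition <- function(level, heart_rate, config = model_config(),
                               vco = vco_params(resistance_multiplier = 100,
                                                ramp_duration = 8),
                               window = 12) {
  ts <- run_vco_experiment(level, heart_rate, vco = vco, window = window,
                           config = config)
  sched <- pacing_schedule(heart_rate,
                           max(ts$time) - min(ts$time) + 60 / heart_rate)
  beats <- segment_beats(ts, sched)
  fam <- harvest_vco_family(beats)
  ## occlusion beats are genuinely open loops (preload falls beat to beat);
  ## the closure warning is expected here, so muffle just that class
  quiet <- function(expr) withCallingHandlers(expr,
    cv_open_loop_warning = function(w) invokeRestart("muffleWarning"))
  mets <- quiet(lapply(fam, beat_metrics, v0_for_pva = NA))
  fits <- fit_relations(mets)
  v0 <- fits$espvr$intercept_volume
  mets <- quiet(lapply(fam, beat_metrics, v0_for_pva = v0))
  steady <- mets[[1]]
  row <- summarize_condition(steady, fits, level = level,
                             heart_rate = heart_rate)
  list(row = row, metrics = mets, fits = fits, timeseries = ts)
}

#' Phase I study: five compliance levels at 80 bpm
#'
#' Runs the VCO experiment at each of the five graded compliance settings at
#' 80 bpm and assembles the condition-by-metric study table (steady-state
#' beat metrics plus the four fitted relation slopes and mechanical
#' efficiency).
#'
#' @param config base configuration.
#' @param levels character vector of levels (default all five).
#' @return a `data.frame` of class `cv_study_table`, one row per level.
#' @export
run_phase1 <- function(config = model_config(),
                       levels = .compliance_levels$level) {
  rows <- lapply(levels, function(l) {
    r <- tryCatch(.analyze_condition(l, 80, config = config),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning("condition '", l, "' failed: ", conditionMessage(r))
      return(.failed_row(l, 80))
    }
    r$row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_study_table", "data.frame")
  attr(out, "phase") <- 1L
  out
}

#' Phase II study: normal and stiff settings at 60, 100 and 140 bpm
#'
#' @param config base configuration.
#' @param heart_rates pacing rates, bpm.
#' @param levels compliance levels (default normal and stiff).
#' @return a `cv_study_table` with one row per (level, heart rate), 6 rows by
#'   default.
#' @export
run_phase2 <- function(config = model_config(),
                       heart_rates = c(60, 100, 140),
                       levels = c("normal", "stiff")) {
  rows <- list()
  for (l in levels) for (hr in heart_rates) {
    r <- tryCatch(.analyze_condition(l, hr, config = config),
                  error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(r, "error")) {
      warning("condition '", l, "' at ", hr, " bpm failed: ",
              conditionMessage(r))
      .failed_row(l, hr)
    } else r$row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_study_table", "data.frame")
  attr(out, "phase") <- 2L
  out
}

.failed_row <- function(level, heart_rate) {
  row <- summarize_condition(NULL, NULL, level = level,
                             heart_rate = heart_rate)
  row$flagged <- TRUE
  row
}
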