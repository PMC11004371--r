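## Closed-loop circuit: valve law, mass-flow balance, simulation drivers.

#' Ideal-diode valve flow
#'
#' Forward Ohmic flow when the upstream pressure exceeds the downstream
#' pressure, zero otherwise; never negative (no regurgitation, no inertance).
#'
#' @param p_upstream,p_downstream pressures, mmHg.
#' @param r_open open-valve resistance, mmHg·s/ml (> 0).
#' @return flow, ml/s.
#' @examples
#' valve_flow(100, 80, 0.01)  # 2000
#' valve_flow(80, 100, 0.01)  # 0
#' @export
valve_flow <- function(p_upstream, p_downstream, r_open) {
  if (any(r_open <= 0)) stop("r_open must be > 0")
  pmax(p_upstream - p_downstream, 0) / r_open
}

#' Thoracic-vein resistance under the occlusion schedule
#'
#' Baseline before `start_time`; monotone non-decreasing ramp to
#' `baseline * multiplier` at `start_time + ramp_duration`; constant
#' afterwards.  The exponential profile is geometric
#' (`baseline * multiplier^f`), so at mid-ramp the resistance sits at the
#' geometric midpoint.
#'
#' @param t time, s (vectorized).
#' @param params a schedule from [vco_params()].
#' @param baseline_r baseline resistance, mmHg·s/ml.
#' @return resistance, mmHg·s/ml.
#' @export
vco_resistance <- function(t, params, baseline_r) {
  m <- params$resistance_multiplier
  if (m <= 1 || !is.finite(params$start_time))
    return(rep(baseline_r, length(t)))
  f <- pmin(pmax((t - params$start_time) / params$ramp_duration, 0), 1)
  if (identical(params$profile, "linear"))
    baseline_r * (1 + (m - 1) * f)
  else
    baseline_r * m^f
}

#' Mass-flow balance: time derivative of the state
#'
#' Reference R implementation of the model equations (the simulator runs the
#' identical compiled version).  Each compartment's rate is inflow minus
#' outflow; the rates of a closed loop sum to zero exactly.
#'
#' @param state named numeric vector of 15 volumes (ml): chambers
#'   la, lv, ra, rv then the 11 compartments in packaged order.
#' @param t time, s.
#' @param config a `cv_config`.
#' @return list with `rates` (ml/s, same names as `state`), `pressures`
#'   (mmHg: chambers then compartments) and `flows` (ml/s: the four valve
#'   flows plus the thoracic-vein return flow).
#' @export
state_derivative <- function(state, t, config) {
  if (any(!is.finite(state)))
    stop("non-finite state component: ",
         paste(names(state)[!is.finite(state)], collapse = ", "),
         " at t = ", t, " (solver divergence)")
  p <- .pack_parms(config)
  period <- 60 / p[1]
  g <- 1 + p[2] * (p[1] - 80) / 80
  act <- config$activation
  e <- function(i, emax_gain, onset, scl) {
    ph <- ((t + onset) %% period) / period
    a <- normalized_activation(ph, period, act$sys_k * scl, act$max_fraction,
                               act$peak_fraction, act$rise1_level)
    p[10 + i] + (emax_gain * p[6 + i] - p[10 + i]) * a
  }
  ela <- c(e(0, 1, p[3], 0.7), e(1, g, 0, 1), e(2, 1, p[3], 0.7), e(3, g, 0, 1))
  pch <- pmax(ela * (state[1:4] - p[14:17]), p[5])
  pc <- (state[5:15] - p[30:40]) / p[19:29]

  rtv <- vco_resistance(t, config$vco, p[57])

  q_pv_la <- (pc[11] - pch[1]) / p[59]
  q_mv <- valve_flow(pch[1], pch[2], p[41])
  q_av <- valve_flow(pch[2], pc[1], p[42])
  q_aa <- (pc[1] - pc[2]) / p[45]
  q_in <- (pc[2] - pc[3:7]) / p[46:50]
  q_out <- (pc[3:7] - pc[8]) / p[51:55]
  q_sv <- (pc[8] - pc[9]) / p[56]
  q_tv <- (pc[9] - pch[3]) / rtv
  q_tc <- valve_flow(pch[3], pch[4], p[43])
  q_pu <- valve_flow(pch[4], pc[10], p[44])
  q_pa <- (pc[10] - pc[11]) / p[58]

  rates <- c(q_pv_la - q_mv, q_mv - q_av, q_tv - q_tc, q_tc - q_pu,
             q_av - q_aa, q_aa - sum(q_in), q_in - q_out,
             sum(q_out) - q_sv, q_sv - q_tv, q_pu - q_pa, q_pa - q_pv_la)
  names(rates) <- c(.chamber_names, .comp_names)
  list(rates = rates,
       pressures = stats::setNames(c(pch, pc), c(.chamber_names, .comp_names)),
       flows = c(q_mv = unname(q_mv), q_av = unname(q_av),
                 q_tc = unname(q_tc), q_pu = unname(q_pu),
                 q_tv = unname(q_tv)))
}

.ts_outnames <- c("p_la", "p_lv", "p_ra", "p_rv",
                  paste0("p_", .comp_names),
                  "q_av", "q_mv", "q_tc", "q_pu", "r_tv")

#' Simulate the closed loop
#'
#' Integrates the mass-flow balance with deSolve's `lsoda` (compiled
#' right-hand side), sampling the output at `config$solver$sample_dt`
#' (default 1 kHz, the resolution the dP/dt metrics need).
#'
#' @param config a `cv_config`.
#' @param duration simulated time, s.
#' @param initial initial state (15 volumes, ml); defaults to
#'   [initial_state()].  Must sum to `config$total_blood_volume` (within
#'   0.1%).
#' @param t0 start time, s (the pacing clock is absolute: beat onsets sit at
#'   multiples of the period).
#' @return a `cv_timeseries`: a data frame with `time` plus volume (`v_*`),
#'   pressure (`p_*`) and flow (`q_*`) columns, `p_ao` being the aortic-arch
#'   pressure; attributes `heart_rate` and `vco_start`.
#' @export
simulate_model <- function(config, duration, initial = initial_state(config),
                           t0 = 0) {
  validate_config(config)
  if (duration <= 0) stop("duration must be > 0")
  tb <- sum(initial)
  if (abs(tb - config$total_blood_volume) / config$total_blood_volume > 0.001)
    stop(sprintf("initial volumes sum to %.1f ml, not total_blood_volume %.1f",
                 tb, config$total_blood_volume))
  dt <- config$solver$sample_dt
  times <- seq(t0, t0 + duration, by = dt)
  y0 <- stats::setNames(as.numeric(initial), c(.chamber_names, .comp_names))
  out <- deSolve::ode(y0, times, func = "cv_derivs", parms = .pack_parms(config),
                      dllname = "pvloopva", initfunc = "cv_initmod",
                      nout = 20, outnames = .ts_outnames, method = "lsoda",
                      rtol = config$solver$rel_tol, atol = config$solver$abs_tol)
  m <- unclass(out)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    j <- bad[1, ]
    stop(sprintf("solver divergence: non-finite '%s' at t = %.4f s",
                 colnames(m)[j[2]], m[j[1], 1]))
  }
  df <- as.data.frame(m)
  names(df)[2:16] <- paste0("v_", c(.chamber_names, .comp_names))
  df$p_ao <- df$p_aortic_arch
  structure(df, class = c("cv_timeseries", "data.frame"),
            heart_rate = config$heart_rate,
            vco_start = if (is.finite(config$vco$start_time) &&
                            config$vco$resistance_multiplier > 1)
              config$vco$start_time else NA_real_)
}

#' Total blood volume of a state or trajectory
#'
#' @param x either a state vector of volumes (ml) or a `cv_timeseries`
#'   (in which case a per-sample vector is returned).
#' @return total volume, ml.
#' @examples
#' total_blood_volume(c(10, 20, 30))  # 60
#' @export
total_blood_volume <- function(x) {
  if (inherits(x, "cv_timeseries")) {
    vcols <- grep("^v_", names(x), value = TRUE)
    unname(rowSums(x[, vcols, drop = FALSE]))
  } else {
    sum(x)
  }
}

#' Run the model to periodic steady state
#'
#' Simulates in blocks of beats and declares convergence when, over 5
#' consecutive beats, the relative spread (max-min over mean) of EDV, ESV and
#' mean aortic pressure is each below `tol` (default 0.5%).  Gives up at
#' `max_time` simulated seconds with a recorded warning rather than an error.
#'
#' @param config a `cv_config` (its VCO schedule is ignored here; steady
#'   state is always reached without the occlusion).
#' @param max_time maximum simulated time, s.
#' @param tol relative beat-to-beat tolerance.
#' @param initial starting state.
#' @return list with `timeseries` (full trajectory), `state` (final volumes),
#'   `converged` (flag), `criterion` (`"beat_metrics_converged"` or
#'   `"max_time_reached"`), `time` (end of the trajectory, s) and
#'   `n_beats` (beats simulated).
#' @export
run_to_steady_state <- function(config, max_time = 180, tol = 0.005,
                                initial = initial_state(config)) {
  validate_config(config)
  cfg <- config
  cfg$vco <- vco_params(start_time = Inf, resistance_multiplier = 1)
  period <- 60 / cfg$heart_rate
  block <- 5 * period
  t_now <- 0
  state <- initial
  chunks <- list()
  hist <- NULL   # per-beat EDV, ESV, mean AoP
  converged <- FALSE
  while (t_now < max_time - 1e-9) {
    ts <- simulate_model(cfg, min(block, max_time - t_now), state, t0 = t_now)
    state <- as.numeric(ts[nrow(ts), 2:16])
    names(state) <- c(.chamber_names, .comp_names)
    ## drop the duplicated first sample on continuation chunks
    chunks[[length(chunks) + 1L]] <-
      if (length(chunks)) ts[-1, , drop = FALSE] else ts
    t_now <- ts$time[nrow(ts)]
    k0 <- floor(ts$time[1] / period + 1e-9)
    k1 <- floor(t_now / period - 1e-9)
    for (k in k0:k1) {
      w <- ts[ts$time >= k * period - 1e-9 &
              ts$time < (k + 1) * period - 1e-9, ]
      if (nrow(w) < 2) next
      hist <- rbind(hist, c(EDV = w$v_lv[1], ESV = min(w$v_lv),
                            AoP = mean(w$p_ao)))
    }
    if (!is.null(hist) && nrow(hist) >= 5) {
      recent <- hist[(nrow(hist) - 4):nrow(hist), , drop = FALSE]
      spread <- apply(recent, 2, function(v) (max(v) - min(v)) / mean(v))
      if (all(spread < tol)) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning(sprintf("no periodic steady state within %.0f s (tol %.2g)",
                    max_time, tol))
  ts_all <- do.call(rbind, chunks)
  attr(ts_all, "heart_rate") <- cfg$heart_rate
  attr(ts_all, "vco_start") <- NA_real_
  class(ts_all) <- c("cv_timeseries", "data.frame")
  list(timeseries = ts_all, state = state, converged = converged,
       criterion = if (converged) "beat_metrics_converged"
                   else "max_time_reached",
       time = t_now, n_beats = if (is.null(hist)) 0L else nrow(hist))
}

#' Write / read a trajectory as CSV
#'
#' Column schema: `time_s, p_lv_mmHg, v_lv_ml, p_ao_mmHg, q_av_ml_s,
#' q_mv_ml_s` followed by any further pressure/volume/flow columns carried by
#' the trajectory.  `read_timeseries()` restores a `cv_timeseries`; the
#' heart rate must be supplied (or stored) because the CSV carries only data
#' columns.
#'
#' @param ts a `cv_timeseries`.
#' @param path file path.
#' @param heart_rate pacing rate of the recording, bpm.
#' @return `write_timeseries()` the path, invisibly; `read_timeseries()` a
#'   `cv_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  core <- data.frame(time_s = ts$time, p_lv_mmHg = ts$p_lv,
                     v_lv_ml = ts$v_lv, p_ao_mmHg = ts$p_ao,
                     q_av_ml_s = ts$q_av, q_mv_ml_s = ts$q_mv)
  extra_p <- setdiff(grep("^p_", names(ts), value = TRUE),
                     c("p_lv", "p_ao", "p_aortic_arch"))
  for (nm in extra_p) core[[paste0(nm, "_mmHg")]] <- ts[[nm]]
  utils::write.csv(core, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, heart_rate) {
  df <- utils::read.csv(path)
  need <- c("time_s", "p_lv_mmHg", "v_lv_ml", "p_ao_mmHg")
  if (!all(need %in% names(df)))
    stop("CSV lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(time = df$time_s, p_lv = df$p_lv_mmHg,
                    v_lv = df$v_lv_ml, p_ao = df$p_ao_mmHg)
  if ("q_av_ml_s" %in% names(df)) out$q_av <- df$q_av_ml_s
  if ("q_mv_ml_s" %in% names(df)) out$q_mv <- df$q_mv_ml_s
  structure(out, class = c("cv_timeseries", "data.frame"),
            heart_rate = heart_rate, vco_start = NA_real_)
}

#' @export
print.cv_timeseries <- function(x, ...) {
  cat(sprintf("cv_timeseries: %d samples, %.2f-%.2f s, %g bpm\n",
              nrow(x), x$time[1], x$time[nrow(x)],
              attr(x, "heart_rate")))
  if (is.finite(attr(x, "vco_start") %||% NA))
    cat(sprintf("  VCO active from t = %.2f s\n", attr(x, "vco_start")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
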