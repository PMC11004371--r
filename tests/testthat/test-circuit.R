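test_that("valve flow is an ideal diode", {
  expect_equal(valve_flow(100, 80, 0.01), 2000)
  expect_equal(valve_flow(80, 100, 0.01), 0)
  expect_equal(valve_flow(95, 95, 0.02), 0)
  expect_error(valve_flow(100, 80, 0), "r_open")
})

test_that("the mass-flow balance is zero at equilibrium and conservative", {
  cfg <- model_config()
  y_eq <- equilibrium_state(cfg)
  cfg$total_blood_volume <- sum(y_eq)
  d <- state_derivative(y_eq, 0.95, cfg)   # diastole: no activation either
  expect_true(all(abs(d$pressures) < 1e-12))
  expect_true(all(abs(d$rates) < 1e-12))

  ## Ohmic transfer between two compartments: raise the systemic vein by
  ## 10 mmHg over the thoracic vein; flow = dP / R_sv_out
  y <- y_eq
  cp <- cfg$compartments
  i_sv <- match("systemic_vein", cp$name)
  y[["systemic_vein"]] <- y[["systemic_vein"]] + 10 * cp$compliance[i_sv]
  cfg2 <- cfg; cfg2$total_blood_volume <- sum(y)
  d2 <- state_derivative(y, 0.95, cfg2)
  expect_equal(unname(d2$rates[["thoracic_vein"]]),
               10 / cp$resistance_out[i_sv], tolerance = 1e-12)

  ## closed loop: rates sum to zero for random valid states
  set.seed(42)
  for (i in 1:25) {
    yr <- y_eq * stats::runif(length(y_eq), 0.8, 1.3)
    cfgr <- cfg; cfgr$total_blood_volume <- sum(yr)
    dr <- state_derivative(yr, stats::runif(1, 0, 0.75), cfgr)
    expect_lt(abs(sum(dr$rates)), 1e-9 * max(abs(dr$rates), 1))
  }
  expect_error(state_derivative(replace(y_eq, 2, NaN), 0, cfg), "non-finite")
})

test_that("the reference R derivative reproduces the compiled trajectory", {
  cfg <- model_config()
  y0 <- initial_state(cfg)
  rfun <- function(t, y, p) list(unname(state_derivative(y, t, cfg)$rates))
  o1 <- deSolve::lsoda(y0, seq(0, 1.5, by = 0.001), rfun, NULL,
                       rtol = 1e-8, atol = 1e-8)
  o2 <- simulate_model(cfg, 1.5)
  expect_lt(max(abs(o1[, "lv"] - o2$v_lv)), 0.01)
  expect_lt(max(abs(o1[, "aortic_arch"] - o2$v_aortic_arch)), 0.01)
})

test_that("simulated trajectories conserve blood volume and report consistent pressures", {
  cfg <- model_config()
  ts <- cached("sim60", simulate_model(cfg, 60))
  tot <- total_blood_volume(ts)
  drift <- abs(tot[length(tot)] - tot[1]) / tot[1]
  expect_lt(drift, 0.001)          # < 0.1% per simulated minute
  ## compartment pressure equals (V - Vu)/C at every sample
  cp <- cfg$compartments
  i <- match("aortic_arch", cp$name)
  expect_lt(max(abs(ts$p_aortic_arch -
                    (ts$v_aortic_arch - cp$unstressed_volume[i]) /
                      cp$compliance[i])), 1e-6)
  expect_true(all(is.finite(as.matrix(ts))))
})

test_that("a lone compartment drains with the closed-form RC time constant", {
  cfg <- model_config()
  cp <- cfg$compartments
  ## pin every compartment but the aortic arch with an enormous compliance
  ## (pressure fixed ~0) and park the chambers at their unstressed volumes
  ## with valves shut; the arch then discharges through its outflow
  ## resistance alone: V(t) = Vu + dV0 * exp(-t / (R*C)).
  cp$compliance[cp$name != "aortic_arch"] <- 1e7
  cfg$compartments <- cp
  y <- equilibrium_state(cfg)
  i_aa <- match("aortic_arch", cp$name)
  C <- cp$compliance[i_aa]; R <- cp$resistance_out[i_aa]
  dv0 <- 50 * C   # charge the arch to 50 mmHg
  y[["aortic_arch"]] <- y[["aortic_arch"]] + dv0
  cfg$total_blood_volume <- sum(y)
  cfg$solver$sample_dt <- 1e-4
  tau <- R * C
  ts <- simulate_model(cfg, 5 * tau, initial = y)
  vu <- cp$unstressed_volume[i_aa]
  v_pred <- vu + dv0 * exp(-ts$time / tau)
  expect_lt(max(abs(ts$v_aortic_arch - v_pred) / dv0), 0.005)
  ## at t = tau, 63.2% of the excess has discharged
  i_tau <- which.min(abs(ts$time - tau))
  frac <- 1 - (ts$v_aortic_arch[i_tau] - vu) / dv0
  expect_equal(frac, 1 - exp(-1), tolerance = 0.005)
})

test_that("constant-elastance chambers relax toward a flowless equilibrium", {
  cfg <- model_config()
  cfg$chambers$E_max <- cfg$chambers$E_min * (1 + 1e-9)
  ts <- simulate_model(cfg, 40)
  late <- ts[ts$time > 39, ]
  expect_lt(max(abs(late$q_av), abs(late$q_mv)), 1)
  ## open-path pressures equalize: arch vs systemic artery
  expect_lt(max(abs(late$p_aortic_arch - late$p_systemic_artery)), 0.5)
})

test_that("simulation rejects invalid durations and mismatched volumes", {
  cfg <- model_config()
  expect_error(simulate_model(cfg, 0), "duration")
  y <- initial_state(cfg); y[1] <- y[1] + 100
  expect_error(simulate_model(cfg, 1, initial = y), "total_blood_volume")
})

test_that("the paced loop settles to a periodic steady state", {
  ss <- steady_normal()
  expect_true(ss$converged)
  expect_identical(ss$criterion, "beat_metrics_converged")
  expect_lt(ss$time, 180)
  ## periodicity: successive beats of lv volume within 0.5 ml
  ts <- ss$timeseries
  period <- 60 / 80
  w <- ts[ts$time >= ss$time - 2 * period, ]
  n <- sum(w$time < ss$time - period + 1e-9)
  v1 <- w$v_lv[1:n]
  v2 <- w$v_lv[(nrow(w) - n + 1):nrow(w)]
  expect_lt(max(abs(v1 - v2)), 0.5)
})

test_that("restarting from the steady state converges within six beats", {
  ss <- steady_normal()
  again <- run_to_steady_state(model_config(), initial = ss$state)
  expect_true(again$converged)
  expect_lte(again$n_beats, 6)
})

test_that("total blood volume sums chambers and compartments", {
  expect_equal(total_blood_volume(c(0, 0, 0)), 0)
  expect_equal(total_blood_volume(c(10, 20, 30)), 60)
  ts <- condition_normal()$timeseries
  tot <- total_blood_volume(ts)
  expect_equal(tot[length(tot)], tot[1], tolerance = 0.001)
})
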