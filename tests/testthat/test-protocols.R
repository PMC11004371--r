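test_that("the five graded compliance settings carry the exact pairs", {
  expected <- list(normal = c(0.7, 1.28), `90pct` = c(0.63, 1.41),
                   `80pct` = c(0.56, 1.54), `60pct` = c(0.42, 1.805),
                   stiff = c(0.19, 3.66))
  for (lev in names(expected)) {
    s <- compliance_setting(lev)
    expect_identical(c(s$C_A, s$R_T), expected[[lev]], label = lev)
  }
  expect_error(compliance_setting("soft"), "normal, 90pct, 80pct, 60pct, stiff")
})

test_that("vascular scaling is proportional, exact and idempotent", {
  cfg <- model_config()
  ## identity: scaling to the current equivalents leaves the tree unchanged
  same <- apply_vascular_scaling(cfg, list(C_A = 0.7, R_T = 1.28))
  expect_equal(same$compartments$compliance, cfg$compartments$compliance,
               tolerance = 1e-12)
  ## halving the target compliance halves every arterial compliance
  half <- apply_vascular_scaling(cfg, list(C_A = 0.35, R_T = 1.28))
  art <- cfg$compartments$name %in% pvloopva:::.arterial_comps
  expect_equal(half$compartments$compliance[art],
               cfg$compartments$compliance[art] / 2, tolerance = 1e-12)
  expect_equal(equivalent_arterial_compliance(half), 0.35, tolerance = 1e-9)
  ## normal -> stiff hits the printed targets exactly
  stiff <- apply_vascular_scaling(cfg, compliance_setting("stiff"))
  expect_equal(equivalent_arterial_compliance(stiff), 0.19, tolerance = 1e-9)
  expect_equal(total_peripheral_resistance(stiff), 3.66, tolerance = 1e-9)
  ## venous side untouched
  ven <- !art
  expect_identical(stiff$compartments$compliance[ven],
                   cfg$compartments$compliance[ven])
  ## idempotent: re-applying the same setting changes nothing
  stiff2 <- apply_vascular_scaling(stiff, compliance_setting("stiff"))
  expect_equal(stiff2$compartments, stiff$compartments, tolerance = 1e-12)
})

test_that("the occlusion resistance ramp is monotone with the stated profile", {
  p <- vco_params(start_time = 10, ramp_duration = 8,
                  resistance_multiplier = 100)
  expect_equal(vco_resistance(5, p, 0.015), 0.015)
  expect_equal(vco_resistance(30, p, 0.015), 1.5)
  ## geometric midpoint of the exponential profile
  expect_equal(vco_resistance(14, p, 0.015), 0.15, tolerance = 1e-12)
  t <- seq(0, 30, by = 0.1)
  expect_true(all(diff(vco_resistance(t, p, 0.015)) >= 0))
  pl <- vco_params(start_time = 10, ramp_duration = 8,
                   resistance_multiplier = 100, profile = "linear")
  expect_equal(vco_resistance(14, pl, 0.015), 0.015 * 50.5, tolerance = 1e-12)
  expect_error(vco_params(start_time = 0, resistance_multiplier = 5), ">= 10")
})

test_that("the occlusion produces a monotone falling preload", {
  r <- condition_normal()
  edv <- vapply(r$metrics, `[[`, numeric(1), "EDV")
  ## beat 1 is the steady reference; the following occlusion beats fall
  expect_gte(length(edv), 9)
  expect_true(all(diff(edv[-1]) < 0))
  expect_true(attr(r$timeseries, "converged"))
})

test_that("a degenerate occlusion (multiplier 1) leaves the beats unchanged", {
  ts <- run_vco_experiment("normal", 80,
                           vco = vco_params(start_time = 0,
                                            resistance_multiplier = 1),
                           window = 6)
  sched <- pacing_schedule(80, 20)
  ## no marked occlusion -> segment everything and inspect EDV stability
  beats <- segment_beats(ts, sched)
  edv <- vapply(beats, function(b) b$v_lv[1], numeric(1))
  expect_lt(max(edv) - min(edv), 0.5)
})

test_that("the stiff aorta raises the first-beat end-systolic pressure", {
  pes_n <- condition_normal()$metrics[[1]]$Pes
  pes_s <- condition_stiff()$metrics[[1]]$Pes
  expect_gt(pes_s, pes_n)
  ## and the stiff steady EDV exceeds the normal steady EDV
  expect_gt(condition_stiff()$metrics[[1]]$EDV,
            condition_normal()$metrics[[1]]$EDV)
})

test_that("phase tables have the full condition-by-metric shape", {
  p1 <- phase1_table()
  expect_s3_class(p1, "cv_study_table")
  expect_equal(nrow(p1), 5)
  expect_true(all(pvloopva:::.study_cols %in% names(p1)))
  expect_false(any(p1$flagged))
  p2 <- phase2_table()
  expect_equal(nrow(p2), 6)
  expect_false(any(p2$flagged))
  expect_setequal(p2$heart_rate, c(60, 100, 140))
})
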