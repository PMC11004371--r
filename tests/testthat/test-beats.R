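## synthetic periodic trajectory for segmentation tests
.synthetic_ts <- function(duration, hr, dt = 0.005) {
  period <- 60 / hr
  t <- seq(0, duration, by = dt)
  structure(data.frame(
    time = t,
    p_lv = 60 + 50 * sin(2 * pi * t / period - pi / 2),
    v_lv = 80 + 30 * cos(2 * pi * t / period),
    p_ao = 100 + 20 * sin(2 * pi * t / period)),
    class = c("cv_timeseries", "data.frame"),
    heart_rate = hr, vco_start = NA_real_)
}

test_that("segmentation yields one beat per complete pacing interval", {
  expect_length(segment_beats(.synthetic_ts(10, 60), pacing_schedule(60, 10)),
                10)
  expect_length(segment_beats(.synthetic_ts(3, 80), pacing_schedule(80, 3)),
                4)
  expect_error(segment_beats(.synthetic_ts(1, 60), pacing_schedule(60, 1)),
               "2 pacing periods")
  ## periodic signal: every beat attains the global volume maximum
  beats <- segment_beats(.synthetic_ts(10, 60), pacing_schedule(60, 10))
  vmax <- max(.synthetic_ts(10, 60)$v_lv)
  for (b in beats) expect_lt(abs(max(b$v_lv) - vmax), 1e-9)
})

test_that("beat metrics recover the construction of an analytic loop", {
  b <- make_rect_loop(50, 100, 10, 110, 400)
  m <- beat_metrics(b)
  expect_equal(m$EDV, 100)
  expect_equal(m$ESV, 50)
  expect_equal(m$SV, 50)
  expect_equal(m$SV, m$EDV - m$ESV)
  expect_equal(m$SW, 5000)
})

test_that("dP/dt_max matches the analytic derivative of a sinusoid", {
  period <- 0.75
  t <- seq(0, period - 1e-4, by = 1e-4)
  b <- structure(list(index = 0L, t = t,
                      p_lv = 50 + 50 * sin(2 * pi * t / period),
                      v_lv = 100 - 20 * sin(2 * pi * t / period),
                      p_ao = NULL, q_av = NULL,
                      is_steady_state = TRUE, is_vco = FALSE),
                 class = "cv_beat")
  m <- suppressWarnings(beat_metrics(b))
  expect_equal(m$dPdt_max, 100 * pi / period, tolerance = 1e-3)
  expect_error(beat_metrics(structure(list(t = c(0, 0.1, 0.1),
                                           p_lv = 1:3, v_lv = 3:1),
                                      class = "cv_beat")),
               "strictly increasing")
})

test_that("stroke work is the orientation-invariant polygon area", {
  b <- make_rect_loop(50, 100, 10, 110, 400)
  expect_equal(stroke_work(b), 5000, tolerance = 1e-9)
  rev_b <- b; rev_b$v_lv <- rev(b$v_lv); rev_b$p_lv <- rev(b$p_lv)
  expect_equal(stroke_work(rev_b), 5000, tolerance = 1e-9)
  ## degenerate loop with no volume excursion has zero area
  flat <- list(v_lv = rep(60, 50), p_lv = seq(0, 100, length.out = 50))
  expect_equal(suppressWarnings(stroke_work(flat)), 0)
  ## an open loop warns and is closed
  open_b <- b
  open_b$v_lv <- open_b$v_lv[1:300]; open_b$p_lv <- open_b$p_lv[1:300]
  expect_warning(stroke_work(open_b), class = "cv_open_loop_warning")
})

test_that("pressure-volume area adds the end-systolic triangle", {
  expect_equal(pv_area(5000, 100, 60, 10), 7500)
  expect_equal(pv_area(5000, 0, 60, 10), 5000)
  expect_equal(pv_area(5000, 100, 10, 10), 5000)
  expect_warning(out <- pv_area(5000, 100, 5, 10), "clamped")
  expect_equal(out, 5000)
})

test_that("mechanical efficiency and dynamic compliance follow their ratios", {
  expect_equal(mechanical_efficiency(5000, 5000), 100)
  expect_equal(mechanical_efficiency(1, 2), 50)
  expect_equal(mechanical_efficiency(5000, 7500), 200 / 3)
  expect_error(mechanical_efficiency(1, 0), "PVA")
  expect_equal(round(dynamic_compliance(46.5, 81.7), 2), 0.57)
  expect_equal(round(dynamic_compliance(52.7, 133.6), 2), 0.39)
  expect_equal(dynamic_compliance(0, 50), 0)
  expect_error(dynamic_compliance(40, 0), "Pes")
})

test_that("every simulated beat satisfies the energetic inequalities", {
  for (cond in list(condition_normal(), condition_stiff())) {
    for (m in cond$metrics) {
      expect_gt(m$EDV, m$ESV)
      expect_equal(m$SV, m$EDV - m$ESV)
      expect_gte(m$PVA, m$SW - 1e-9)
      expect_lte(m$ME, 100)
      expect_gt(m$ME, 0)
    }
  }
})

test_that("an isolated elastance chamber lands on its end-systolic line", {
  b <- make_elastance_beat(e_max = 2, e_min = 0.06, v0 = 10)
  m <- beat_metrics(b)
  ratio <- m$Pes / (m$ESV - 10)
  expect_gte(ratio, 1.96)
  expect_lte(ratio, 2.04)
})
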