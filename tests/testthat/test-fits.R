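test_that("ordinary least squares recovers an exact line", {
  x <- seq(20, 80, by = 5)
  f <- linear_lsq(x, 2 * (x - 10))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$volume_intercept, 10, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(linear_lsq(c(1, 2), c(1, 2)), "3 points")
  expect_error(linear_lsq(rep(5, 10), 1:10), "constant")
})

test_that("least squares agrees with the normal-equations oracle", {
  set.seed(7)
  x <- stats::runif(50, 40, 120)
  y <- 1.7 * (x - 12) + stats::rnorm(50, 0, 3)
  f <- linear_lsq(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)   # closed-form normal equations
  expect_equal(f$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f$slope, beta[2], tolerance = 1e-10)
})

test_that("zero-noise fixture families are recovered exactly", {
  spec <- fixture_spec(espvr_slope = 1.8, v0 = 15, prsw_slope = 75, vw = 20,
                       pva_slope = 92, v_pva = 25, dpdt_slope = 17)
  fam <- make_vco_family(spec)
  fits <- fit_relations(fam)
  expect_equal(fits$espvr$slope, 1.8, tolerance = 1e-8)
  expect_equal(fits$espvr$intercept_volume, 15, tolerance = 1e-6)
  expect_equal(fits$prsw$slope, 75, tolerance = 1e-8)
  expect_equal(fits$prsw$intercept_volume, 20, tolerance = 1e-6)
  expect_equal(fits$dpdt_edv$slope, 17, tolerance = 1e-8)
  expect_equal(fits$pva_edv$slope, 92, tolerance = 1e-8)
  expect_equal(fits$pva_edv$intercept_volume, 25, tolerance = 1e-6)
  for (f in fits) expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("slopes survive 2% measurement noise over twenty seeds", {
  slopes <- sapply(1:20, function(s) {
    fam <- make_vco_family(fixture_spec(noise_sd_fraction = 0.02, seed = s))
    fits <- fit_relations(fam)
    c(espvr = fits$espvr$slope, prsw = fits$prsw$slope,
      dpdt = fits$dpdt_edv$slope, pva = fits$pva_edv$slope)
  })
  truth <- c(espvr = 1.8, prsw = 75, dpdt = 17, pva = 92)
  rel <- abs(rowMeans(slopes) - truth) / truth
  expect_true(all(rel < 0.05))
})

test_that("relation fits on a simulated occlusion carry sensible diagnostics", {
  fits <- condition_normal()$fits
  for (f in fits) {
    expect_gte(f$n_beats, 3)
    expect_gte(f$r_squared, 0)
    expect_lte(f$r_squared, 1)
  }
  ## the end-systolic points of the paced chamber line up with the
  ## commanded peak elastance (within 10%)
  cfg <- model_config()
  expect_equal(fits$espvr$slope, cfg$chambers["lv", "E_max"],
               tolerance = 0.1)
  expect_gt(fits$espvr$r_squared, 0.98)
})

test_that("condition summaries tolerate missing fits", {
  steady <- condition_normal()$metrics[[1]]
  fits <- condition_normal()$fits
  row <- summarize_condition(steady, fits, level = "normal", heart_rate = 80)
  expect_false(row$flagged)
  expect_equal(row$SV_ml, steady$SV)
  row2 <- summarize_condition(steady, fits[c("espvr", "prsw", "dpdt_edv")],
                              level = "normal", heart_rate = 80)
  expect_true(row2$flagged)
  expect_true(is.na(row2$EDV_PVA))
  expect_equal(row2$PRSW, fits$prsw$slope)
})
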