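test_that("average_density averages the final window only", {
  tab <- ts_table(data.frame(t = seq(0, 1, 0.01), rho = rep(1.40, 101)),
                  units = c("ns", "g/cm^3"))
  r <- average_density(tab, 0.5)
  expect_equal(r$value, 1.40)
  expect_equal(r$error, 0)
  expect_equal(r$provenance$window_ns, 0.5)
  ## linear ramp over the window: mean is the midpoint (arithmetic oracle)
  t <- seq(0, 1, length.out = 501)
  rho <- 1.30 + 0.1 * (t - 0.5) / 0.5
  rho[t < 0.5] <- 1.30
  tab2 <- ts_table(data.frame(t = t, rho = rho), c("ns", "g/cm^3"))
  expect_equal(average_density(tab2, 0.5)$value,
               mean(rho[t >= 0.5]), tolerance = 1e-12)
  expect_equal(average_density(tab2, 0.5)$value, 1.35, tolerance = 1e-4)
  short <- ts_table(data.frame(t = seq(0, 0.4, 0.01), rho = rep(1.4, 41)))
  expect_error(average_density(short, 0.5), "window exceeds series")
})

test_that("build_vt_series sorts, reciprocates and validates", {
  vt <- build_vt_series(c(300), c(1.4))
  expect_equal(vt$specific_volume, 1 / 1.4, tolerance = 1e-12)
  vt2 <- build_vt_series(c(400, 300, 350), c(1.2, 1.4, 1.3))
  expect_equal(vt2$temperature, c(300, 350, 400))
  expect_equal(vt2$density, c(1.4, 1.3, 1.2))
  expect_error(build_vt_series(c(300, 325), c(0, 1.4)), "positive")
  expect_error(build_vt_series(c(300, 300), c(1.4, 1.4)), "duplicate")
})

test_that("broken-stick regression recovers an exact hinge to machine precision", {
  vt <- gen_vt_curve(400, 1e-4, 3e-4, 0.54, seq(150, 600, 25))
  r <- broken_stick_tg(vt, c(150, 275), c(475, 600))
  expect_equal(r$tg, 400, tolerance = 1e-12)
  ## windows that do not straddle the hinge also recover it exactly
  r2 <- broken_stick_tg(vt, c(150, 375), c(425, 600))
  expect_equal(r2$tg, 400, tolerance = 1e-9)
  expect_equal(r$low_fit$slope, 1e-4, tolerance = 1e-12)
  expect_equal(r$high_fit$slope, 3e-4, tolerance = 1e-12)
})

test_that("degenerate windows raise the documented errors", {
  vt <- gen_vt_curve(400, 1e-4, 3e-4, 0.54, seq(150, 600, 25))
  expect_error(broken_stick_tg(vt, c(150, 160), c(475, 600)),
               "fewer than 2 points")
  flat <- gen_vt_curve(400, 2e-4, 2e-4, 0.54, seq(150, 600, 25))
  expect_error(broken_stick_tg(flat), "parallel")
})

test_that("noisy Tg matches the closed-form OLS-intersection oracle", {
  vt <- gen_vt_curve(400, 1e-4, 3e-4, 0.54, seq(150, 600, 25),
                     noise_sd = 5e-4, seed = 17)
  r <- broken_stick_tg(vt)
  expect_equal(r$tg,
               oracle_tg(vt$temperature, vt$specific_volume,
                         c(150, 275), c(475, 600)),
               tolerance = 1e-9)
})

test_that("Tg is invariant under affine maps of the specific volume", {
  for (s in 1:5) {
    vt <- gen_vt_curve(380 + 10 * s, 1e-4, 3e-4, 0.54, seq(150, 600, 25),
                       noise_sd = 5e-4, seed = s)
    tg0 <- broken_stick_tg(vt)$tg
    ## shift: V + c  (density 1/(V + c)); scale: V * a
    for (tf in list(function(v) v + 0.05, function(v) v * 1.7)) {
      vt2 <- vt_series(data.frame(temperature = vt$temperature,
                                  density = 1 / tf(vt$specific_volume)))
      expect_equal(broken_stick_tg(vt2)$tg, tg0, tolerance = 1e-8)
    }
  }
})

test_that("thermal expansion reproduces direct arithmetic", {
  vt <- build_vt_series(c(300, 325), c(1.4000, 1.3953))
  a <- thermal_expansion(vt, 300, 325)
  oracle <- (1 / 1.3953 - 1 / 1.4000) / (25 * (1 / 1.4000))
  expect_equal(a$value, oracle, tolerance = 1e-15)
  expect_equal(a$value, 1.35e-4, tolerance = 0.01)  # ~1.347e-4
  same <- build_vt_series(c(300, 325), c(1.4, 1.4))
  expect_equal(thermal_expansion(same, 300, 325)$value, 0)
  expect_error(thermal_expansion(vt, 325, 300), "exceed")
  expect_error(thermal_expansion(vt, 300, 350), "not in series")
})

test_that("alpha of an exponential volume curve meets the finite-difference bound", {
  alpha <- 4e-4
  temps <- seq(250, 500, 25)
  vt <- vt_series(data.frame(temperature = temps,
                             density = 1 / (0.5 * exp(alpha * temps))))
  ## leading-order finite-difference bound alpha*dT/2, with 5% headroom for
  ## the higher-order terms of (exp(alpha dT) - 1)/dT
  for (T1 in seq(250, 475, 25)) {
    a <- thermal_expansion(vt, T1, T1 + 25)$value
    expect_lt(abs(a - alpha) / alpha, alpha * 25 / 2 * 1.05)
  }
})

test_that("midpoint normalization is available and recorded", {
  vt <- build_vt_series(c(300, 325), c(1.4000, 1.3953))
  lo <- thermal_expansion(vt, 300, 325)
  mid <- thermal_expansion(vt, 300, 325, normalization = "midpoint")
  V1 <- 1 / 1.4; V2 <- 1 / 1.3953
  expect_equal(mid$value, (V2 - V1) / (25 * (V1 + V2) / 2), tolerance = 1e-15)
  expect_identical(mid$provenance$normalization, "midpoint")
  ## conventions differ by O(alpha * dT / 2) ~ 0.2%, far below reported precision
  expect_lt(abs(mid$value - lo$value) / lo$value, 5e-3)
})
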