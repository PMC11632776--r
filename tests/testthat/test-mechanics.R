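test_that("stress is the negated axial pressure in GPa", {
  tab <- ts_table(data.frame(strain = c(0, 0.5), Pz = c(-30000, 0)),
                  units = c("dimensionless", "bar"))
  cur <- stress_from_pressure(tab)
  expect_equal(cur$stress, c(3.0, 0))
  ## a table already in GPa passes through with only the sign flip
  tab2 <- ts_table(data.frame(strain = c(0, 0.5), Pz = c(-2, -1)),
                   units = c("dimensionless", "GPa"))
  expect_equal(stress_from_pressure(tab2)$stress, c(2, 1))
  bad <- ts_table(data.frame(strain = c(0, 1), Pz = c(0, 1)),
                  units = c("dimensionless", "kPa"))
  expect_error(stress_from_pressure(bad), "bar or GPa")
  ## round trip with the generator encoded as pressure
  ss <- gen_stress_strain(2, 0.1, 0.5, seq(0, 0.3, 0.01))
  enc <- ts_table(data.frame(strain = ss$strain, Pz = -ss$stress * 1e4),
                  units = c("dimensionless", "bar"))
  expect_equal(stress_from_pressure(enc)$stress, ss$stress, tolerance = 1e-12)
})

test_that("strain from box lengths is exact arithmetic", {
  tab <- ts_table(data.frame(t = 0:3, L = c(5, 5.15, 7.5, 10)),
                  units = c("ns", "nm"))
  expect_equal(strain_series(tab, 5), c(0, 0.03, 0.5, 1))
  expect_error(strain_series(tab, 0), "positive")
})

test_that("reflect-and-average smoothing preserves linear curves exactly", {
  eps <- seq(0, 1, 0.0025)
  for (a in c(0.5, 2.5, -1)) {
    cur <- smooth_reflect(stress_strain(eps, a * eps))
    expect_lt(max(abs(cur$smoothed - a * eps)), 1e-12)
  }
  cur <- smooth_reflect(stress_strain(eps, 2.5 * eps))
  expect_identical(cur$smoothed[1L], 0)
  expect_error(smooth_reflect(stress_strain(eps, eps), half_width = 2),
               "span")
  expect_error(smooth_reflect(stress_strain(eps, eps), half_width = 0),
               "positive")
})

test_that("smoothing equals the brute-force window-average oracle", {
  eps <- seq(0, 0.5, 0.005)
  set.seed(21)
  sig <- 3 * eps + rnorm(length(eps), 0, 0.05)
  cur <- smooth_reflect(stress_strain(eps, sig), half_width = 0.025)
  expect_equal(cur$smoothed, oracle_smooth(eps, sig, 0.025),
               tolerance = 1e-12)
  ## slope of the smoothed curve stays within 1% of truth
  sel <- cur$strain >= 0.05 & cur$strain <= 0.45
  slope <- unname(oracle_ols(cur$strain[sel], cur$smoothed[sel])["slope"])
  expect_lt(abs(slope - 3) / 3, 0.01)
})

test_that("Young's modulus is the closed-form zero-intercept slope", {
  strains <- seq(0, 0.06, length.out = 400)
  ss <- gen_stress_strain(3.0, 0.2, 1.0, strains, noise_sd = 0.05, seed = 33)
  cur <- smooth_reflect(stress_strain(ss$strain, ss$stress))
  E <- youngs_modulus(cur)
  sel <- cur$strain >= 0.003 & cur$strain <= 0.03
  oracle <- sum(cur$smoothed[sel] * cur$strain[sel]) / sum(cur$strain[sel]^2)
  expect_equal(E$value, oracle, tolerance = 1e-12)
  expect_lt(abs(E$value - 3) / 3, 0.1)  # noise-limited recovery
  expect_error(youngs_modulus(cur, 0.00001, 0.00002), "fewer than 2")
})

test_that("maximum stress reports the vertex with the smallest-strain tie-break", {
  eps <- seq(0, 1, 0.001)
  cur <- stress_strain(eps, 4 * eps * (1 - eps))
  m <- max_stress(cur)
  expect_equal(m$value, 1.0, tolerance = 1e-9)
  expect_equal(m$provenance$strain_at_max, 0.5)
  ## two equal maxima: the smaller strain wins
  flat <- stress_strain(c(0, 0.2, 0.4, 0.6, 0.8), c(0, 1, 0.5, 1, 0.2))
  expect_equal(max_stress(flat, 0.03, 0.97)$provenance$strain_at_max, 0.2)
  ## monotone curve: last grid point at or below the upper bound
  mono <- stress_strain(eps, eps^1.5)
  expect_equal(max_stress(mono)$provenance$strain_at_max,
               max(eps[eps <= 0.97]))
  expect_error(max_stress(cur, 2, 3), "no points")
})

test_that("Poisson's ratio from the transverse response", {
  d <- gen_box_deformation(0.3, 8, seq(0, 0.04, length.out = 80))
  expect_equal(poisson_ratio(d)$value, 0.3, tolerance = 1e-12)
  ## constant transverse length: nu = 0
  d0 <- gen_box_deformation(0, 8, seq(0, 0.04, length.out = 80))
  expect_equal(poisson_ratio(d0)$value, 0, tolerance = 1e-12)
  ## a single transverse direction is accepted with a warning
  d1 <- d; d1$L_trans_y <- NULL
  expect_warning(r <- poisson_ratio(d1), "single transverse")
  expect_equal(r$value, 0.3, tolerance = 1e-12)
  expect_error(poisson_ratio(d, 0.5, 0.6), "fewer than 2")
})

test_that("bulk modulus follows Lame's relation with the degenerate guard", {
  expect_equal(bulk_modulus(3, 1 / 3)$value, 3.0, tolerance = 1e-12)
  expect_equal(bulk_modulus(3, 0)$value, 1.0, tolerance = 1e-12)
  flagged <- bulk_modulus(3, 0.4996)
  expect_true(is.na(flagged$value))
  expect_match(flagged$provenance$flag, "near-incompressible")
  expect_error(bulk_modulus(3, 0.51), "non-physical")
  expect_error(bulk_modulus(-1, 0.3), "non-negative")
  ## monotone increasing in nu on [0, 0.5)
  nus <- seq(0, 0.45, 0.05)
  Ks <- vapply(nus, function(n) bulk_modulus(2, n)$value, numeric(1))
  expect_true(all(diff(Ks) > 0))
})

test_that("direction aggregation gives mean and population sd", {
  ec <- function(E, s, n, K, d) elastic_constants(E, s, n, K, d)
  same <- lapply(c("x", "y", "z"), function(d) ec(2, 0.3, 0.30, 2, d))
  agg <- aggregate_directions(same)
  expect_equal(agg$aggregate$nu$mean, 0.30)
  expect_equal(agg$aggregate$nu$sd, 0)
  three <- list(ec(2, 0.3, 0.29, 2, "x"), ec(2, 0.3, 0.30, 2, "y"),
                ec(2, 0.3, 0.31, 2, "z"))
  agg2 <- aggregate_directions(three)
  expect_equal(agg2$aggregate$nu$mean, 0.30)
  expect_equal(agg2$aggregate$nu$sd, sqrt(mean(c(-0.01, 0, 0.01)^2)))
  expect_equal(agg2$aggregate$nu$sd, 0.0082, tolerance = 0.01)
  expect_error(aggregate_directions(three[1:2]), "exactly 3")
})

test_that("energy deltas subtract the undeformed reference", {
  tab <- ts_table(data.frame(strain = c(0, 0.1, 0.2),
                             bonded = c(10, 12, 9),
                             lj = c(5, 5, 5)),
                  units = c("dimensionless", "kJ/mol", "kJ/mol"))
  d <- delta_energy(tab)
  expect_equal(unname(unlist(d[1L, -1L])), c(0, 0))
  expect_equal(d$bonded, c(0, 2, -1))
  expect_equal(d$lj, c(0, 0, 0))
})
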