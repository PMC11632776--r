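test_that("detection is strict at both thresholds and handles images", {
  expect_equal(nrow(detect_hbonds(gen_hbond_geometry(0.3499, 29.9))), 1L)
  expect_equal(nrow(detect_hbonds(gen_hbond_geometry(0.35, 10))), 0L)
  expect_equal(nrow(detect_hbonds(gen_hbond_geometry(0.30, 30))), 0L)
  ## donor and acceptor split across the periodic boundary
  fr <- gen_hbond_geometry(0.30, 10, box = c(3, 3, 3))
  fr$atoms$x <- (fr$atoms$x + 1.6) %% 3     # shove the pair across the +x face
  b <- detect_hbonds(fr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 0.30, tolerance = 1e-9)
})

test_that("detection is invariant under rigid translation modulo the box", {
  fr <- gen_hbond_geometry(0.32, 20)
  for (s in 1:5) {
    set.seed(s)
    shift <- runif(3, -5, 5)
    fr2 <- fr
    fr2$atoms$x <- (fr$atoms$x + shift[1]) %% fr$box[1]
    fr2$atoms$y <- (fr$atoms$y + shift[2]) %% fr$box[2]
    fr2$atoms$z <- (fr$atoms$z + shift[3]) %% fr$box[3]
    b <- detect_hbonds(fr2)
    expect_equal(nrow(b), 1L)
    expect_equal(b$distance, 0.32, tolerance = 1e-9)
  }
})

test_that("an explicit donor selection without attached hydrogen errors", {
  fr <- gen_hbond_geometry(0.30, 10)
  ## select the acceptor oxygen (no H) as the only donor candidate
  expect_error(detect_hbonds(fr, donor_pattern = "^OA", require_h = TRUE),
               "without attached hydrogen.*OA")
})

test_that("track_bonds builds the union universe with per-frame indicators", {
  f1 <- gen_hbond_geometry(0.30, 10)   # bonded
  f2 <- gen_hbond_geometry(0.34, 10)   # still bonded
  f3 <- gen_hbond_geometry(0.40, 10)   # broken
  ev <- track_bonds(list(f1, f2, f3), times = c(0, 0.1, 0.2))
  expect_equal(dim(ev$matrix), c(1L, 3L))
  expect_equal(ev$matrix[1L, ], c(1L, 1L, 0L))
  expect_identical(ev$groups, "polymer-polymer")
  ## single frame reduces to detect_hbonds
  ev1 <- track_bonds(list(f1))
  expect_equal(ev1$matrix, matrix(1L, 1L, 1L))
  expect_error(track_bonds(list(f1, config_frame(f1$atoms[1:2, ], f1$box))),
               "atom-count mismatch")
  expect_equal(bonds_per_monomer(ev, 2), (1 + 1 + 0) / 3 / 2)
})

test_that("existence function matches hand-computable cases", {
  ## all bonds present always: C(t) = 1
  ev <- bond_events(matrix(1L, 4, 5), times = 0:4)
  expect_equal(existence_function(ev)$C_HB, rep(1, 5))
  ## present at frame 0 only (absorbing break): C(0)=1, C(t>0)=0
  m <- cbind(rep(1L, 3), matrix(0L, 3, 4))
  c2 <- existence_function(bond_events(m, times = 0:4))
  expect_equal(c2$C_HB, c(1, 0, 0, 0, 0))
  ## tiny case against the definition, computed by hand:
  ## h = (1,0,1): lag1 num = h1 h2 + h2 h3 = 0, den = h1 + h2 = 1
  ## lag2 num = h1 h3 = 1, den = h1 = 1
  c3 <- existence_function(bond_events(matrix(c(1L, 0L, 1L), 1L), times = 0:2))
  expect_equal(c3$C_HB, c(1, 0, 1))
  expect_error(existence_function(bond_events(matrix(0L, 2, 3), times = 0:2)),
               "empty bond population")
})

test_that("Markov event matrices decay as the survival law e^(-kt)", {
  n <- 10000L
  ev <- gen_bond_events(n, 201, 0.01, k_break = 1, k_reform = 0, seed = 11)
  cb <- existence_function(ev)
  for (tq in c(0.5, 1.0, 1.5)) {
    p <- exp(-tq)
    got <- cb$C_HB[abs(cb$time - tq) < 1e-9]
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_true(all(cb$C_HB >= 0 & cb$C_HB <= 1))
  expect_equal(cb$C_HB[1L], 1)
})

test_that("single-exponential data yields unit integral regardless of weight split", {
  tt <- seq(0, 10, 0.05)
  fit <- fit_decay(ts_table(data.frame(t = tt, C = exp(-tt))))
  expect_true(fit$converged)
  expect_equal(fit$K1 * fit$tau1 + fit$K2 * fit$tau2, 1.0, tolerance = 1e-3)
})

test_that("constant C is flagged rather than extrapolated", {
  fit <- fit_decay(ts_table(data.frame(t = 0:9, C = rep(1, 10))))
  expect_false(fit$converged)
  expect_match(fit$flags, "tau unbounded")
  expect_error(lifetime_halflife(fit), "not converged")
})

test_that("bi-exponential ground truth is recovered through the integral", {
  tt <- seq(0, 10, 0.025)
  truth <- 0.6 * exp(-tt / 0.5) + 0.4 * exp(-tt / 8)
  set.seed(1)
  cc <- pmin(1, pmax(0, truth + rnorm(length(tt), 0, 0.005)))
  fit <- fit_decay(ts_table(data.frame(t = tt, C = cc)))
  expect_true(fit$converged)
  integral <- fit$K1 * fit$tau1 + fit$K2 * fit$tau2
  expect_lt(abs(integral - 3.5) / 3.5, 0.05)
})

test_that("lifetime and half-life have their closed forms", {
  f1 <- structure(list(K1 = 1, tau1 = 2, K2 = 0, tau2 = 2, converged = TRUE,
                       flags = character(0)), class = "decay_fit")
  r1 <- lifetime_halflife(f1)
  expect_equal(r1$lifetime, 2)
  expect_equal(r1$half_life, 2 * log(2), tolerance = 1e-9)
  f2 <- structure(list(K1 = 0.5, tau1 = 1, K2 = 0.5, tau2 = 10,
                       converged = TRUE, flags = character(0)),
                  class = "decay_fit")
  r2 <- lifetime_halflife(f2)
  expect_equal(r2$lifetime, 5.5)
  bis <- oracle_bisect(function(t) 0.5 * exp(-t) + 0.5 * exp(-t / 10) - 0.5,
                       0, 10)
  expect_equal(r2$half_life, bis, tolerance = 1e-8)
  expect_equal(r2$half_life, 1.80, tolerance = 0.01)
  ## C(0) < 0.5: half-life 0 with a flag
  f3 <- structure(list(K1 = 0.25, tau1 = 1, K2 = 0.15, tau2 = 5,
                       converged = TRUE, flags = character(0)),
                  class = "decay_fit")
  r3 <- lifetime_halflife(f3)
  expect_equal(r3$half_life, 0)
  expect_match(r3$flags, "C\\(0\\) < 0.5")
})

test_that("half-life never exceeds lifetime for mixture survival decays", {
  set.seed(42)
  for (i in 1:25) {
    K1 <- runif(1, 0.2, 0.8); K2 <- min(1 - K1, runif(1, 0.1, 0.8))
    fit <- structure(list(K1 = K1, tau1 = runif(1, 0.1, 3),
                          K2 = K2, tau2 = runif(1, 0.1, 20),
                          converged = TRUE, flags = character(0)),
                     class = "decay_fit")
    r <- lifetime_halflife(fit)
    expect_lte(r$half_life, r$lifetime)
  }
})

test_that("integral convention for the half-life is available", {
  f <- structure(list(K1 = 1, tau1 = 2, K2 = 0, tau2 = 2, converged = TRUE,
                      flags = character(0)), class = "decay_fit")
  r <- lifetime_halflife(f, halflife_convention = "integral")
  ## integral of exp(-t/2) from 0 to 2 ln 2 = 2 * (1 - 1/2) = 1
  expect_equal(r$half_life, 1, tolerance = 1e-9)
})

test_that("end-to-end kinetics recovery: lifetime within 10% of 1/k_break", {
  ev <- gen_bond_events(10000, 401, 0.01, k_break = 1, k_reform = 0,
                        seed = 3)
  fit <- fit_decay(existence_function(ev))
  expect_true(fit$converged)
  lt <- lifetime_halflife(fit)
  expect_lt(abs(lt$lifetime - 1) / 1, 0.10)
})
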