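test_that("rate constant objects validate inputs and derive kappa/lambda", {
  expect_error(rate_constants(kn = -1), "non-negative")
  expect_error(rate_constants(nc = 0.5), "nc")
  rc <- rate_constants(kn = 8e-9, nc = 1, kplus = 10, k2 = 8e-5)
  expect_equal(kappa_rate(rc, 100), sqrt(2 * 10 * 8e-5 * 100))
  expect_equal(lambda_rate(rc, 100), sqrt(2 * 10 * 8e-9 * 100))
  # zero iff constituents zero
  expect_identical(kappa_rate(rate_constants(kplus = 10), 100), 0)
  expect_identical(lambda_rate(rate_constants(k2 = 1, kplus = 10), 100), 0)
  # fragmentation enters kappa like order-0 secondary nucleation
  rf <- rate_constants(kplus = 10, kminus = 8e-5)
  expect_equal(kappa_rate(rf, 100), kappa_rate(rc, 100))
})

test_that("simulation limits: frozen system and pure seeded elongation", {
  times <- seq(0, 10, by = 0.1)
  frozen <- simulate_fibril_mass(rate_constants(), 10, M0 = 1, P0 = 0.01,
                                 times)
  expect_equal(frozen$M, rep(1, length(times)), tolerance = 1e-8)
  expect_equal(frozen$P, rep(0.01, length(times)), tolerance = 1e-8)

  t_long <- seq(0, 100, by = 0.5)
  elong <- simulate_fibril_mass(rate_constants(kplus = 1), 10, M0 = 0.5,
                                P0 = 0.05, t_long)
  expect_true(all(diff(elong$M) > 0))
  # fastest growth at t = 0: no lag phase
  expect_gt(elong$M[2] - elong$M[1], elong$M[3] - elong$M[2])
  expect_equal(elong$M[length(t_long)], 10, tolerance = 1e-3)
  # closed form is exact in this limit
  cf <- closed_form_fibril_mass(rate_constants(kplus = 1), 10, M0 = 0.5,
                                P0 = 0.05, t_long)
  truth <- 1 - (1 - 0.05) * exp(-2 * 1 * 0.05 * t_long)
  expect_equal(cf$fraction_aggregated, truth, tolerance = 1e-4)
})

test_that("simulation rejects invalid inputs with context", {
  rc <- study_rates()
  expect_error(simulate_fibril_mass(rc, -1, times = 0:10), "positive")
  expect_error(simulate_fibril_mass(rc, 10, M0 = 10, times = 0:10),
               "M0")
  expect_error(simulate_fibril_mass(rc, 10, times = c(0, 2, 1)),
               "increasing")
  expect_error(simulate_fibril_mass(rc, 10, times = c(1, 2, 3)),
               "start at 0")
})

test_that("trajectories conserve mass and are monotone", {
  rc <- study_rates()
  times <- seq(0, 60, by = 0.25)
  for (cond in list(c(M0 = 0, P0 = 0), c(M0 = 1, P0 = 5e-4),
                    c(M0 = 2, P0 = 1e-3))) {
    for (mt in c(25, 100)) {
      traj <- simulate_fibril_mass(rc, mt, cond[["M0"]], cond[["P0"]],
                                   times)
      expect_lt(max(abs(traj$m + traj$M - mt)), 1e-6 * mt)
      expect_true(all(diff(traj$M) >= -1e-9 * mt))
      expect_true(all(diff(traj$m) <= 1e-9 * mt))
      expect_true(all(diff(traj$P) >= -1e-12))
    }
  }
})

test_that("closed form matches the ODE within 5% in its validity regime", {
  times <- seq(0, 80, by = 0.1)
  for (lam_over_kap in c(0.01, 0.1)) {
    rc <- default_rates(lambda = 0.4 * lam_over_kap)
    for (seed_pct in c(0, 1, 2)) {
      M0 <- seed_pct
      traj <- simulate_fibril_mass(rc, 100, M0, M0 / 2000, times)
      cf <- closed_form_fibril_mass(rc, 100, M0, M0 / 2000, times)
      expect_lt(max(abs(traj$M / 100 - cf$fraction_aggregated)), 0.05)
    }
  }
})

test_that("closed form endpoints and half-time agree with the ODE", {
  rc <- study_rates()
  times <- seq(0, 80, by = 0.1)
  cf <- closed_form_fibril_mass(rc, 100, 0, 0, times)
  expect_equal(cf$fraction_aggregated[1], 0)
  expect_gt(cf$fraction_aggregated[length(times)], 0.999)
  ht_ode <- half_time(as_normalized_trace(
    simulate_fibril_mass(rc, 100, 0, 0, times)))
  expect_lt(abs(half_time(cf) - ht_ode) / ht_ode, 0.05)
  # no-dynamics regime is flagged
  expect_error(closed_form_fibril_mass(rate_constants(), 100, 0, 0, times),
               "no dynamics")
})

test_that("half-time and lag time interpolate crossings", {
  tr <- logistic_trace(midpoint = 5)
  expect_equal(half_time(tr), 5, tolerance = 1e-6)
  shifted <- normalized_trace(tr$times + 2, tr$fraction_aggregated)
  expect_equal(half_time(shifted), 7, tolerance = 1e-6)
  expect_lt(lag_time(tr), half_time(tr))
  # heavily seeded trace already past the lag threshold
  started <- normalized_trace(0:10, seq(0.3, 1, length.out = 11))
  expect_identical(lag_time(started), 0)
  flat <- normalized_trace(0:10, rep(0.1, 11))
  expect_error(half_time(flat), "never reaches")
})

test_that("seeding shortens the half-time only via secondary processes", {
  times <- seq(0, 60, by = 0.1)
  rc <- study_rates()
  ht <- vapply(c(0, 0.5, 1), function(pct) {
    M0 <- pct
    half_time(as_normalized_trace(
      simulate_fibril_mass(rc, 100, M0, M0 / 2000, times)))
  }, 0)
  expect_true(all(diff(ht) < 0))
  # primary + elongation only: 1% seeds shift the half-time by < 5%
  rp <- rate_constants(kn = 5e-4, nc = 1, kplus = 0.1)
  t_long <- seq(0, 60, by = 0.1)
  ht0 <- half_time(as_normalized_trace(
    simulate_fibril_mass(rp, 100, 0, 0, t_long)))
  ht1 <- half_time(as_normalized_trace(
    simulate_fibril_mass(rp, 100, 1, 1 / 2000, t_long)))
  expect_lt(abs(ht1 - ht0) / ht0, 0.05)
})

test_that("scaling exponent is -1/2 for secondary processes, -nc/2 for primary", {
  expect_equal(scaling_exponent(rep(10, 4), c(25, 50, 100, 200)), 0)
  expect_error(scaling_exponent(c(1, 2), c(25, 50)), "3 distinct")
  expect_error(scaling_exponent(c(-1, 1, 1), c(25, 50, 100)), "positive")

  conc <- c(25, 50, 100, 200)
  ht_sec <- vapply(conc, function(m) {
    half_time(as_normalized_trace(
      simulate_fibril_mass(study_rates(), m, 0, 0, seq(0, 120, by = 0.1))))
  }, 0)
  expect_equal(scaling_exponent(ht_sec, conc), -0.5, tolerance = 0.05)

  ht_frag <- vapply(conc, function(m) {
    half_time(as_normalized_trace(
      simulate_fibril_mass(study_rates("fragmentation"), m, 0, 0,
                           seq(0, 120, by = 0.1))))
  }, 0)
  expect_equal(scaling_exponent(ht_frag, conc), -0.5, tolerance = 0.05)

  rp <- rate_constants(kn = 5e-8, nc = 2, kplus = 10)
  ht_pri <- vapply(conc, function(m) {
    half_time(as_normalized_trace(
      simulate_fibril_mass(rp, m, 0, 0, seq(0, 200, by = 0.2))))
  }, 0)
  expect_equal(scaling_exponent(ht_pri, conc), -1, tolerance = 0.1)
})
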