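test_that("fibril-catalysed oligomer kinetics freeze without fibrils", {
  # M(t) = 0 throughout: both source and sink vanish, S stays at S0
  times <- seq(0, 10, by = 0.1)
  empty <- simulate_fibril_mass(rate_constants(), 10, M0 = 0, P0 = 0,
                                times)
  pars <- oligomer_params("secondary", k_form = 1, k_diss = 1)
  sol <- integrate_oligomers(pars, empty, S0 = 2)
  expect_equal(sol$S, rep(2, length(times)), tolerance = 1e-9)
})

test_that("the steady state S* = (k_form/k_diss) m^n_o is held exactly", {
  # frozen bulk state: constant m and M > 0; M cancels from the balance
  times <- seq(0, 20, by = 0.1)
  frozen <- simulate_fibril_mass(rate_constants(), 10, M0 = 4, P0 = 0.01,
                                 times)
  pars <- oligomer_params("secondary", k_form = 0.02, k_diss = 0.5,
                          n_o = 1)
  S_star <- 0.02 / 0.5 * 6
  sol <- integrate_oligomers(pars, frozen, S0 = S_star)
  expect_equal(sol$S, rep(S_star, length(times)), tolerance = 1e-6)
})

test_that("oligomer solutions are linear in the formation rate", {
  bulk <- make_bulk_pair()$unseeded
  p1 <- oligomer_params("secondary", k_form = 1e-3, k_diss = 0.2)
  p2 <- oligomer_params("secondary", k_form = 2e-3, k_diss = 0.2)
  s1 <- integrate_oligomers(p1, bulk)
  s2 <- integrate_oligomers(p2, bulk)
  expect_equal(s2$S, 2 * s1$S, tolerance = 1e-9)
})

test_that("fast dissociation makes oligomers track the monomer quasi-steady state", {
  bulk <- make_bulk_pair()$unseeded
  pars <- oligomer_params("secondary", k_form = 1.44e-3, k_diss = 2)
  sol <- integrate_oligomers(pars, bulk)
  qss <- 1.44e-3 / 2 * bulk$m
  mid <- bulk$M / 100 > 0.2 & bulk$M / 100 < 0.98
  expect_lt(max(abs(sol$S[mid] - qss[mid]) / qss[mid]), 0.05)
})

test_that("oligomers peak before the bulk half-time, earlier when seeded", {
  pair <- make_bulk_pair()
  pars <- default_oligomer_params()
  su <- integrate_oligomers(pars, pair$unseeded)
  ss <- integrate_oligomers(pars, pair$seeded)
  ht <- half_time(as_normalized_trace(pair$unseeded))
  pk_u <- oligomer_peak_time(su, half_time = ht)
  expect_false(pk_u$boundary)
  expect_lt(pk_u$ratio, 1)
  pk_s <- oligomer_peak_time(ss)
  expect_lt(pk_s$peak_time, pk_u$peak_time)
  # monotone series: boundary maximum is flagged
  mono <- data.frame(times = 1:10, S = as.numeric(1:10))
  expect_warning(pk <- oligomer_peak_time(mono), "boundary")
  expect_true(pk$boundary)
})

test_that("noise-free oligomer series refit to within 2%", {
  bulk <- make_bulk_pair()$unseeded
  pars <- default_oligomer_params()
  ser <- gen_oligomer_series(pars, bulk, n_replicates = 1, noise = 0,
                             seed = 1)
  # with zero noise and one replicate the series equals the model solution
  expect_equal(ser$S,
               integrate_oligomers(pars, bulk, times = ser$times)$S,
               tolerance = 1e-12)
  fit <- fit_oligomer_series(ser, bulk, "secondary", seed = 1)
  expect_lt(abs(fit$k_form - pars$k_form) / pars$k_form, 0.02)
  expect_lt(abs(fit$k_diss - pars$k_diss) / pars$k_diss, 0.02)
})

test_that("formation rate has < 20% median error at 10% noise", {
  bulk <- make_bulk_pair()$unseeded
  pars <- default_oligomer_params()
  errs <- vapply(1:20, function(r) {
    ser <- gen_oligomer_series(pars, bulk, seed = 500 + r)
    fit <- fit_oligomer_series(ser, bulk, "secondary", n_starts = 2,
                               seed = r)
    abs(fit$k_form - pars$k_form) / pars$k_form
  }, 0)
  expect_lt(stats::median(errs), 0.20)
})

test_that("suppressing dissociation on fast-dissociation data is flagged", {
  bulk <- make_bulk_pair()$unseeded
  ser <- gen_oligomer_series(default_oligomer_params(), bulk, seed = 31)
  fit <- fit_oligomer_series(ser, bulk, "secondary", fix_k_diss = 0,
                             seed = 31)
  expect_true(fit$late_misfit)
})

test_that("the paired seeded design identifies the oligomer origin", {
  pair <- make_bulk_pair()
  n_each <- 20
  acc <- vapply(c("secondary", "primary"), function(truth) {
    pars <- if (truth == "secondary") {
      default_oligomer_params()
    } else {
      oligomer_params("primary", k_form = 2e-4, k_diss = 0.5)
    }
    hits <- vapply(seq_len(n_each), function(r) {
      su <- gen_oligomer_series(pars, pair$unseeded, seed = 700 + r)
      ss <- gen_oligomer_series(pars, pair$seeded, seed = 900 + r)
      sel <- select_oligomer_model(su, pair$unseeded, ss, pair$seeded,
                                   n_starts = 2, seed = r)
      sel$selected == truth
    }, TRUE)
    sum(hits)
  }, 0)
  expect_gte(acc[["secondary"]], 18)
  expect_gte(acc[["primary"]], 18)
})

test_that("a single condition with frozen fibril mass is indeterminate", {
  # constant m and M make the two mechanisms exactly interconvertible
  # (k_form*M and k_diss*M absorb into the primary-mode constants), so
  # neither fit can win
  frozen <- simulate_fibril_mass(rate_constants(), 10, M0 = 4, P0 = 0.01,
                                 seq(0, 20, by = 0.1))
  pars <- oligomer_params("secondary", k_form = 0.02, k_diss = 0.5)
  ser <- gen_oligomer_series(pars, frozen,
                             times = seq(1, 19, length.out = 10),
                             noise = 0.05, seed = 41)
  sel <- select_oligomer_model(ser, frozen, seed = 41)
  expect_identical(sel$selected, "indeterminate")
})
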