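test_that("closed-form curves obey their limits and reductions", {
  t <- seq(0, 100, 0.5)
  # t = 0 returns the baseline for both models
  expect_equal(monophasic_curve(0, A = 2, kobs = 0.3, offset = 1.5), 1.5)
  expect_equal(biphasic_curve(0, 0.4, 2, 0.6, 0.05, offset = -0.2), -0.2)
  # kobs = 0 freezes the monophasic curve at baseline
  expect_equal(monophasic_curve(t, A = 2, kobs = 0, offset = 1), rep(1, length(t)))
  # A2 = 0 reduces the biphasic model to the monophasic one
  expect_equal(biphasic_curve(t, 0.7, 1.2, 0, 0.05, 0.1),
               monophasic_curve(t, 0.7, 1.2, 0.1))
  # asymptote: offset + A1 + A2 once the slow phase has run > 25 lifetimes
  t_late <- 26 / 0.05
  expect_equal(biphasic_curve(t_late, 0.4, 2, 0.6, 0.05, 0.3), 0.3 + 1,
               tolerance = 1e-9)
  # half-rise time of the monophasic curve is ln 2 / kobs
  kobs <- 0.37
  expect_equal(monophasic_curve(log(2) / kobs, A = 1, kobs = kobs), 0.5)
  # noiseless curves are non-decreasing
  expect_true(all(diff(biphasic_curve(t, 0.4, 2, 0.6, 0.05)) >= 0))
  expect_error(monophasic_curve(-1, 1, 1), "non-negative")
  expect_error(biphasic_curve(t, 1, -1, 1, 0.1), ">= 0")
})

test_that("mechanistic scheme conserves mass and has trivial null limits", {
  cond <- assay_conditions(E0 = 1, S0 = 1)
  times <- seq(0, 100, 1)
  # no reaction and no substrate both give identically zero signal
  pc0 <- simulate_full_scheme(rate_constants(0, 0, 0, 0), cond, times)
  expect_equal(pc0$signal, rep(0, length(times)))
  pcS <- simulate_full_scheme(rate_constants(10, 100, 5, 0.1),
                              assay_conditions(E0 = 1, S0 = 0), times)
  expect_equal(pcS$signal, rep(0, length(times)), tolerance = 1e-12)
  # mass balances at every reported time
  pc <- simulate_full_scheme(rate_constants(10, 100, 5, 0.05), cond, times)
  expect_true(all(mass_balance_error(pc) < 1e-9))
  # signal monotone non-decreasing
  expect_true(all(diff(pc$signal) >= -1e-12))
  expect_error(rate_constants(-1, 1, 1, 1), "non-negative")
  expect_error(simulate_full_scheme(rate_constants(1, 1, 1, 1), cond, 5),
               "2 strictly increasing")
})

test_that("ODE output matches the pseudo-first-order closed form", {
  # S0 << E0 and k_on E0 << k_off (with k_acyl << k_off): binding
  # pre-equilibrates and the curve is A (1 - exp(-k t)) with
  # k = k_acyl k_on E0 / k_off
  r <- rate_constants(k_on = 0.01, k_off = 100, k_acyl = 0.02,
                      k_deacyl = 10)
  cond <- assay_conditions(E0 = 1, S0 = 0.001)
  k <- r$k_acyl * r$k_on / r$k_off * cond$E0
  times <- seq(0, 4 / k, length.out = 200)
  pc <- simulate_full_scheme(r, cond, times)
  cf <- monophasic_curve(times, cond$S0, k)
  expect_lt(max(abs(pc$signal - cf)) / max(cf), 1e-3)
})

test_that("second-order conversion divides by total enzyme in molar", {
  expect_equal(to_second_order(1, E0_uM = 1e6), 1)  # E0 = 1 M: identity
  expect_equal(to_second_order(0.007, E0_uM = 1), 7e3)
  expect_equal(to_second_order(0, E0_uM = 1), 0)
  expect_error(to_second_order(1, 0), "E0")
})

test_that("noiseless fits round-trip the generator parameters", {
  t <- seq(0, 100, length.out = 60)
  tr_m <- progress_curve(t, monophasic_curve(t, A = 1, kobs = 0.5))
  fm <- fit_curve(tr_m, "monophasic", seed = 1)
  expect_equal(fm$A1, 1, tolerance = 1e-6)
  expect_equal(fm$kobs1, 0.5, tolerance = 1e-6)
  expect_equal(fm$offset, 0, tolerance = 1e-6)
  expect_identical(fm$unidentifiable, character(0))

  tr_b <- progress_curve(t, biphasic_curve(t, 0.4, 2, 0.6, 0.05, 0.1))
  fb <- fit_curve(tr_b, "biphasic", seed = 1)
  expect_equal(c(fb$A1, fb$kobs1, fb$A2, fb$kobs2, fb$offset),
               c(0.4, 2, 0.6, 0.05, 0.1), tolerance = 1e-6)
  expect_gt(fb$r_squared, 1 - 1e-9)
})

test_that("fits are deterministic given the seed and canonically labelled", {
  tr <- generate_trace(list(A1 = 0.4, kobs1 = 2, A2 = 0.6, kobs2 = 0.05),
                       n_points = 60, t_max = 100, noise_sd = 0.02, seed = 3)
  f1 <- fit_curve(tr, "biphasic", seed = 7)
  f2 <- fit_curve(tr, "biphasic", seed = 7)
  expect_identical(f1[c("A1", "kobs1", "A2", "kobs2", "offset")],
                   f2[c("A1", "kobs1", "A2", "kobs2", "offset")])
  # relabelling invariant over many noisy traces
  for (s in 1:10) {
    tr_s <- generate_trace(list(A1 = 0.5, kobs1 = 1, A2 = 0.5, kobs2 = 0.2),
                           n_points = 40, t_max = 50, noise_sd = 0.05,
                           seed = s)
    f <- fit_curve(tr_s, "biphasic", n_starts = 10, seed = s)
    expect_gte(f$kobs1, f$kobs2)
  }
  expect_error(fit_curve(tr, "biphasic", n_starts = 5), "seed")
})

test_that("degenerate constant traces flag rates as unidentifiable", {
  t <- seq(0, 50, length.out = 30)
  tr <- generate_trace(list(A1 = 0, kobs1 = 1, offset = 3),
                       n_points = 30, t_max = 50, noise_sd = 0.01, seed = 2)
  f <- fit_curve(tr, "monophasic", seed = 2)
  expect_lt(f$A1, 0.05)
  expect_equal(f$offset, 3, tolerance = 0.05)
  expect_true("kobs1" %in% f$unidentifiable)
})

test_that("too-short traces are rejected with the required minimum", {
  tr <- progress_curve(1:6, monophasic_curve(1:6, 1, 0.5))
  expect_error(fit_curve(progress_curve(1:4, 1:4), "monophasic", seed = 1),
               ">= 5")
  expect_error(fit_curve(tr, "biphasic", seed = 1), ">= 7")
})

test_that("F-test selects the generating model and defaults to parsimony", {
  # clearly biphasic trace (40-fold rate separation)
  tr_b <- generate_trace(list(A1 = 0.4, kobs1 = 2, A2 = 0.6, kobs2 = 0.05),
                         n_points = 60, t_max = 100, noise_sd = 0.02,
                         seed = 11)
  sel_b <- select_model(tr_b, n_starts = 10, seed = 11)
  expect_identical(sel_b$model, "biphasic")
  expect_lt(sel_b$p_value, 0.05)
  expect_lt(sel_b$aicc_bi, sel_b$aicc_mono)

  # monophasic trace retained
  tr_m <- generate_trace(list(A1 = 1, kobs1 = 0.1), n_points = 60,
                         t_max = 100, noise_sd = 0.02, seed = 12)
  sel_m <- select_model(tr_m, n_starts = 10, seed = 12)
  expect_identical(sel_m$model, "monophasic")

  # pure noise around a constant: parsimony keeps the monophasic model
  tr_c <- generate_trace(list(A1 = 0, kobs1 = 1, offset = 2),
                         n_points = 40, t_max = 50, noise_sd = 0.05,
                         seed = 13)
  expect_identical(select_model(tr_c, n_starts = 10, seed = 13)$model,
                   "monophasic")
})

test_that("variant kinetics populate constants exclusively by source model", {
  t <- seq(0, 100, length.out = 60)
  fb <- fit_curve(progress_curve(t, biphasic_curve(t, 0.4, 2, 0.6, 0.05)),
                  "biphasic", seed = 1)
  vb <- variant_kinetics(fb, E0_uM = 1, variant_id = "evolved")
  expect_equal(vb$k2_obs1, 2e6, tolerance = 1e-5)
  expect_equal(vb$k2_obs2, 5e4, tolerance = 1e-5)
  expect_true(is.na(vb$kcat_over_KM))
  expect_equal(vb$burst_amplitude, 0.4, tolerance = 1e-5)

  fm <- fit_curve(progress_curve(t, monophasic_curve(t, 1, 0.007)),
                  "monophasic", seed = 1)
  vm <- variant_kinetics(fm, E0_uM = 1)
  expect_equal(vm$kcat_over_KM, 7e3, tolerance = 1e-5)
  expect_true(is.na(vm$k2_obs1) && is.na(vm$k2_obs2))
})
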