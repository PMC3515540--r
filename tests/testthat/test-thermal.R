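test_that("subtract_baseline removes a pure straight line", {
  tc <- seq(15, 90, by = 0.25)
  t <- thermogram(tc, 2 + 0.03 * tc)
  ex <- subtract_baseline(t, c(15, 40), c(80, 90))
  expect_lt(max(abs(ex$cp)), 1e-10)
})

test_that("subtract_baseline recovers an injected peak on a sloped line", {
  tc <- seq(15, 90, by = 0.25)
  tr <- transition_fit(59, 154, 154)
  peak <- two_state_excess_cp(tc, tr)
  t <- thermogram(tc, 1.5 + 0.02 * tc + peak)
  ex <- subtract_baseline(t, c(15, 40), c(80, 90))
  expect_lt(max(abs(ex$cp - peak)), 0.01 * max(peak))
  # chord connection also available
  ex2 <- subtract_baseline(t, c(15, 40), c(80, 90), method = "chord")
  expect_lt(max(abs(ex2$cp - peak)), 0.02 * max(peak))
})

test_that("subtract_baseline validates its ranges", {
  t <- thermogram(seq(15, 90, by = 0.5), rnorm(151, 1, 0.01))
  expect_error(subtract_baseline(t, c(15, 45), c(40, 90)), "overlap")
  expect_error(subtract_baseline(t, c(15, 45), c(15, 45)), "overlap")
  expect_error(subtract_baseline(t, c(5, 40), c(80, 90)), "outside")
  expect_error(subtract_baseline(t, c(15, 16), c(80, 90)), "at least 5")
})

test_that("integrate_dHcal matches closed-form areas", {
  tc <- seq(15, 90, by = 0.25)
  expect_equal(integrate_dHcal(thermogram(tc, rep(0, length(tc))), 20, 80), 0)
  # triangular peak of height 3 over base 20 (centered at 50)
  tri <- pmax(0, 3 * (1 - abs(tc - 50) / 10))
  a <- integrate_dHcal(thermogram(tc, tri), 40, 60)
  expect_lt(abs(a - 3 * 20 / 2) / (3 * 20 / 2), 0.005)
  # two-state transition with the wild-type first-transition parameters
  tr <- transition_fit(59, 154, 154)
  ex <- thermogram(tc, two_state_excess_cp(tc, tr))
  expect_lt(abs(integrate_dHcal(ex, 34, 84) - 154) / 154, 0.01)
  expect_error(integrate_dHcal(ex, 60, 60), "empty")
  expect_error(integrate_dHcal(ex, 10, 60), "outside")
})

test_that("two_state_excess_cp has the closed-form peak and integrates to dH_cal", {
  tr <- transition_fit(59, 154, 120)
  Tm_K <- 59 + 273.15
  expect_equal(two_state_excess_cp(59, tr),
               154 * 120 / (4 * Rgas_kcal * Tm_K^2), tolerance = 1e-12)
  expect_lt(two_state_excess_cp(15, tr), 1e-6)
  tc <- seq(19, 99, by = 0.05)
  for (dHvH in c(30, 100, 300)) {
    tr <- transition_fit(59, 154, dHvH)
    ex <- thermogram(tc, two_state_excess_cp(tc, tr))
    expect_lt(abs(integrate_dHcal(ex, 19, 99) - 154) / 154, 0.01)
  }
})

test_that("fit_dsc deconvolves noiseless simulations", {
  trs <- sis1_dsc_transitions()
  ex <- gen_dsc(sim_spec("dsc_two_transition",
                         truth = list(transitions = trs), seed = 1))$scan1
  fit <- fit_dsc(ex, 2)
  tms <- vapply(fit$transitions, `[[`, numeric(1), "Tm_C")
  expect_lt(abs(tms[1] - 59.0), 0.1)
  expect_lt(abs(tms[2] - 67.7), 0.1)
  expect_true(all(diff(tms) > 0))  # returned Tm-ascending

  # area additivity: total integrated excess heat = sum of fitted dH_cal
  # (integrated on a scan wide enough to hold the broad second peak's tails)
  exw <- gen_dsc(sim_spec("dsc_two_transition",
                          truth = list(transitions = trs),
                          grid = seq(5, 105, by = 0.25), seed = 1))$scan1
  fit <- fit_dsc(exw, 2)
  total <- integrate_dHcal(exw, 5, 105)
  expect_lt(abs(total - sum(vapply(fit$transitions, `[[`, numeric(1),
                                   "dH_cal"))) / total, 0.01)

  # single-transition exact recovery
  tr1 <- list(transition_fit(59, 154, 120))
  ex1 <- gen_dsc(sim_spec("dsc_two_transition",
                          truth = list(transitions = tr1), seed = 1))$scan1
  f1 <- fit_dsc(ex1, 1)
  expect_lt(abs(f1$transitions[[1]]$Tm_C - 59) / 59, 1e-4)
  expect_lt(abs(f1$transitions[[1]]$dH_cal - 154) / 154, 1e-4)
  expect_lt(abs(f1$transitions[[1]]$dH_vH - 120) / 120, 1e-4)

  expect_error(fit_dsc(ex, 0), "n_transitions")
})

test_that("fit_dsc recovers all six parameters when transitions are separated", {
  trs <- list(transition_fit(53.8, 70.3, 90), transition_fit(65.6, 48.2, 60))
  ex <- gen_dsc(sim_spec("dsc_two_transition",
                         truth = list(transitions = trs), seed = 1))$scan1
  fit <- fit_dsc(ex, 2)
  truth <- c(53.8, 70.3, 90, 65.6, 48.2, 60)
  got <- unlist(lapply(fit$transitions, function(tr)
    c(tr$Tm_C, tr$dH_cal, tr$dH_vH)))
  expect_lt(max(abs(got - truth) / truth), 1e-3)
})

test_that("constrained van't Hoff mode ties dH_vH to dH_cal", {
  trs <- sis1_dsc_transitions()
  ex <- gen_dsc(sim_spec("dsc_two_transition",
                         truth = list(transitions = trs), seed = 1))$scan1
  fit <- fit_dsc(ex, 2, constrain_vh = TRUE)
  for (tr in fit$transitions) expect_identical(tr$dH_vH, tr$dH_cal)
  expect_lt(abs(fit$transitions[[1]]$Tm_C - 59.0), 0.1)
})

test_that("reversibility_fraction scales with the rescan area", {
  tc <- seq(15, 90, by = 0.25)
  peak <- two_state_excess_cp(tc, transition_fit(59, 154, 154))
  s1 <- thermogram(tc, peak)
  expect_equal(reversibility_fraction(s1, s1)$fraction, 1.0)
  expect_true(reversibility_fraction(s1, s1)$reversible)
  r06 <- reversibility_fraction(s1, thermogram(tc, 0.6 * peak))
  expect_equal(r06$fraction, 0.6, tolerance = 1e-9)
  expect_false(r06$reversible)
  r0 <- reversibility_fraction(s1, thermogram(tc, rep(0, length(tc))))
  expect_equal(r0$fraction, 0)
  expect_error(reversibility_fraction(thermogram(tc, rep(0, length(tc))), s1),
               "not positive")
})

test_that("fit_kirchhoff is exact on collinear input and sane on noise", {
  Tm <- c(51, 53, 55, 57, 59)
  dH <- 154 + 4.0 * (Tm - 59)
  fit <- fit_kirchhoff(Tm, dH)
  expect_equal(fit$dCp, 4.0, tolerance = 1e-12)
  expect_equal(fit$dH_ref, 154, tolerance = 1e-10)
  expect_identical(fit$Tm_ref_C, 59)  # highest Tm is the reference

  # constant dH: zero slope
  expect_equal(fit_kirchhoff(Tm, rep(100, 5))$dCp, 0, tolerance = 1e-12)

  # noisy series recovered within 2 SE
  ser <- gen_kirchhoff_series(sim_spec("kirchhoff_line",
    truth = list(dCp = 4.0, dH_ref = 154, Tm_ref_C = 59,
                 Tm_shifts = -seq(0, 8, length.out = 8)),
    noise_sd = 2, seed = 5))
  nf <- fit_kirchhoff(ser)
  expect_lt(abs(nf$dCp - 4.0), 2 * nf$se_dCp)

  expect_error(fit_kirchhoff(c(55, 55, 55), c(1, 2, 3)), "rank-deficient")
  expect_error(fit_kirchhoff(c(55, 56), c(1, 2)), "at least 3")
})

test_that("per_residue_dcp reproduces the per-domain normalization", {
  expect_equal(per_residue_dcp(4.0, 235), 17.0)
  expect_equal(per_residue_dcp(3.8, 252), 15.1)
  expect_equal(per_residue_dcp(1.7, 121), 14.0)
  # exact inverse at full precision
  expect_identical(per_residue_dcp(4.0, 235, digits = NULL) * 235 / 1000, 4.0)
  expect_error(per_residue_dcp(4.0, 0), "positive")
})

test_that("fit_tm_sigmoid finds melting midpoints", {
  tc <- seq(20, 90, by = 0.5)
  y <- logistic_curve(tc, 0, 1, 60, 2.5)
  fit <- fit_tm_sigmoid(data.frame(temp_C = tc, signal = y))
  expect_lt(abs(fit$midpoint - 60), 1e-6)

  noisy <- gen_logistic_series(sim_spec("logistic_series",
    truth = list(lower = 0, upper = 1, midpoint = 60.1, width = 2.5),
    grid = tc, noise_sd = 0.02, seed = 9), kind = "thermal_cd")
  nf <- fit_tm_sigmoid(noisy)
  expect_lt(abs(nf$midpoint - 60.1), 0.5)

  # truncated upper plateau inflates the midpoint uncertainty
  short <- tc[tc <= 61]
  sf <- fit_tm_sigmoid(short, logistic_curve(short, 0, 1, 60, 2.5) +
                         gen_logistic_series(sim_spec("logistic_series",
                           truth = list(lower = 0, upper = 0, midpoint = 50,
                                        width = 1),
                           grid = short, noise_sd = 0.02, seed = 2))$y)
  expect_gt(sf$se_midpoint, 5 * nf$se_midpoint)
})
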