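test_that("three_state_fraction matches limiting cases and the Boltzmann oracle", {
  # at the first midpoint with the second transition switched off, N and I
  # are equally populated
  p <- three_state_params(7.2, 2.1, 40, 1e-6, 0, 0.5, 1)
  Cm1 <- 7.2 / 2.1
  expect_equal(three_state_fraction(Cm1, p), 0.25, tolerance = 1e-9)
  fr <- three_state_fraction(Cm1, p, what = "fractions")
  expect_equal(unname(fr[1, "fN"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fr[1, "fI"]), 0.5, tolerance = 1e-9)

  # fully unfolded limit
  p2 <- sis1_chem_params()
  expect_equal(three_state_fraction(50, p2), 1.0, tolerance = 1e-9)

  # spot value against the direct partition-function oracle
  expect_equal(three_state_fraction(4.0, p2, 293.15),
               oracle_three_state(4.0, p2, 293.15), tolerance = 1e-13)
})

test_that("model equals the Boltzmann oracle and conserves fractions over random draws", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_three_state_params()
    d <- runif(5, 0, 8)
    expect_lt(max(abs(three_state_fraction(d, p) - oracle_three_state(d, p))),
              1e-12)
    fr <- three_state_fraction(d, p, what = "fractions")
    expect_lt(max(abs(rowSums(fr) - 1)), 1e-12)
  }
})

test_that("signal is non-decreasing in denaturant when plateaus are ordered", {
  set.seed(202)
  d <- seq(0, 8, by = 0.05)
  for (i in 1:20) {
    p <- random_three_state_params()
    ys <- sort(runif(3, -5, 5))
    p$Y_N <- ys[1]; p$Y_I <- ys[2]; p$Y_U <- ys[3]
    expect_true(all(diff(three_state_fraction(d, p)) >= -1e-12))
  }
})

test_that("three_state_fraction rejects invalid parameters", {
  p <- sis1_chem_params()
  p$dG_NI <- NaN
  expect_error(three_state_fraction(1, p), "non-finite")
  p <- sis1_chem_params()
  p$m_NI <- -1
  expect_error(three_state_fraction(1, p), "positive")
})

test_that("raw_to_fraction maps baselines to 0/1 and midpoints to 0.5", {
  d <- seq(0, 6, by = 0.5)
  nb <- c(-10, -0.5); ub <- c(2, 0.3)
  yN <- nb[1] + nb[2] * d
  yU <- ub[1] + ub[2] * d
  cN <- chem_unfold_curve(d, yN, signal_kind = "raw")
  cU <- chem_unfold_curve(d, yU, signal_kind = "raw")
  expect_equal(raw_to_fraction(cN, nb, ub)$signal, rep(0, length(d)))
  expect_equal(raw_to_fraction(cU, nb, ub)$signal, rep(1, length(d)))
  cM <- chem_unfold_curve(d, (yN + yU) / 2, signal_kind = "raw")
  expect_equal(raw_to_fraction(cM, nb, ub)$signal, rep(0.5, length(d)))
  expect_identical(attr(raw_to_fraction(cM, nb, ub), "signal_kind"), "fraction")
  # coinciding baselines are rejected
  expect_error(raw_to_fraction(cN, nb, nb), "degenerate")
})

test_that("compute_cm reproduces summary-table ratios", {
  expect_equal(compute_cm(4.8, 2.4), 2.0)
  expect_equal(round(compute_cm(6.0, 3.3), 1), 1.8)
  x <- c(0.7, 3.2, 11)
  expect_equal(compute_cm(x, x), rep(1, 3))
  expect_error(compute_cm(4, 0), "positive")
  expect_error(compute_cm(4, -2), "positive")
})

test_that("fit_three_state recovers noiseless generator truth to < 1e-4", {
  p <- sis1_chem_params()
  curve <- gen_chem_unfold(sim_spec("chem_three_state",
                                    truth = list(params = p), seed = 1))
  fit <- fit_three_state(curve)
  expect_true(fit$converged)
  for (nm in names(p))
    expect_lt(abs(fit$params[[nm]] - p[[nm]]) / max(abs(p[[nm]]), 1), 1e-4)
  # Cm identities hold to machine precision
  expect_identical(fit$Cm_NI, fit$params$dG_NI / fit$params$m_NI)
  expect_identical(fit$Cm_IU, fit$params$dG_IU / fit$params$m_IU)
  expect_true(fit$Cm_NI < fit$Cm_IU)
})

test_that("fit_three_state recovers dG_NI within 0.5 kcal/mol at sigma = 0.01", {
  p <- sis1_chem_params()
  curve <- gen_chem_unfold(sim_spec("chem_three_state",
                                    truth = list(params = p),
                                    noise_sd = 0.01, seed = 7))
  fit <- fit_three_state(curve)
  expect_lt(abs(fit$params$dG_NI - 7.2), 0.5)
  expect_true(is.finite(fit$se[["dG_NI"]]))
})

test_that("under-determined or invalid curves are rejected", {
  expect_error(fit_three_state(chem_unfold_curve(1:4, c(0, 0.2, 0.8, 1))),
               "at least 8")
  expect_error(chem_unfold_curve(c(1, 1, 2), c(0, 0.5, 1)), "increasing")
  expect_error(chem_unfold_curve(1:3, 1:3, temperature_K = -5), "positive")
})

test_that("Y_I can be fixed instead of fitted", {
  p <- sis1_chem_params()
  curve <- gen_chem_unfold(sim_spec("chem_three_state",
                                    truth = list(params = p),
                                    noise_sd = 0.005, seed = 3))
  fit <- fit_three_state(curve, fix_yi = 0.5)
  expect_identical(fit$params$Y_I, 0.5)
  expect_identical(unname(fit$se["Y_I"]), 0)
  expect_lt(abs(fit$params$dG_NI - 7.2), 0.5)
})

test_that("fit methods are coherent", {
  p <- sis1_chem_params()
  curve <- gen_chem_unfold(sim_spec("chem_three_state",
                                    truth = list(params = p), seed = 1))
  fit <- fit_three_state(curve)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), curve$signal - fitted(fit))
  expect_named(coef(fit), c("dG_NI", "m_NI", "dG_IU", "m_IU",
                            "Y_N", "Y_I", "Y_U"))
  s <- summary(fit)
  expect_true(all(c("Cm_NI", "Cm_IU") %in% rownames(s$coefficients)))
})
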