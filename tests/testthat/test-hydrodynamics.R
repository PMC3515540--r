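test_that("correct_s_to_s20w is the identity at water-20C and linear in viscosity", {
  w20 <- buffer_props(0.99823, 1.002)
  expect_equal(correct_s_to_s20w(2.0, 0.7263, w20), 2.0)
  expect_equal(correct_s_to_s20w(3.5, 0.73, w20), 3.5)
  doubled <- buffer_props(0.99823, 2 * 1.002)
  expect_equal(correct_s_to_s20w(2.0, 0.7263, doubled), 4.0)
  # hand-evaluated formula
  b <- buffer_props(1.10, 1.50)
  expected <- 2.0 * (1.50 / 1.002) * (1 - 0.7263 * 0.99823) / (1 - 0.7263 * 1.10)
  expect_equal(correct_s_to_s20w(2.0, 0.7263, b), expected)
  # protein lighter than solvent: buoyancy violated
  expect_error(correct_s_to_s20w(2.0, 0.95, buffer_props(1.10, 1.5)),
               "buoyancy")
})

test_that("extrapolate_s0 reproduces closed-form lines", {
  conc <- c(0.25, 0.5, 0.75)
  expect_equal(extrapolate_s0(conc, rep(3.5, 3))$s0_20w, 3.5)
  fit <- extrapolate_s0(conc, 3.6 - 0.2 * conc)
  expect_equal(fit$s0_20w, 3.6, tolerance = 1e-10)
  expect_equal(fit$slope, -0.2, tolerance = 1e-10)
  # two points: exact line through them
  f2 <- extrapolate_s0(c(0.25, 0.75), c(3.55, 3.45))
  expect_equal(f2$s0_20w, 3.6, tolerance = 1e-10)
  # noisy points stay within 2 SE of the generating intercept
  set.seed(31)
  fn <- extrapolate_s0(conc, 3.6 - 0.2 * conc + rnorm(3, 0, 0.02))
  expect_lt(abs(fn$s0_20w - 3.6), 2 * max(fn$se_s0, 0.02))
  expect_warning(f1 <- extrapolate_s0(0.5, 3.5), "single concentration")
  expect_identical(f1$se_s0, Inf)
  expect_true(f1$single_point)
})

test_that("urea_buffer_props hits the water limit and increases with urea", {
  w <- urea_buffer_props(0, 20)
  expect_equal(w$density_g_mL, 0.9982, tolerance = 1e-3)
  expect_equal(w$viscosity_cP, 1.002, tolerance = 1e-2)
  grid <- seq(0, 8, by = 0.5)
  dens <- vapply(grid, function(c) urea_buffer_props(c)$density_g_mL, 1)
  visc <- vapply(grid, function(c) urea_buffer_props(c)$viscosity_cP, 1)
  expect_true(all(diff(dens) > 0))
  expect_true(all(diff(visc) > 0))
  expect_gt(urea_buffer_props(5)$density_g_mL,
            urea_buffer_props(1)$density_g_mL)
  expect_error(urea_buffer_props(9.5), "within")
  expect_error(urea_buffer_props(-1), "within")
})

test_that("vbar_from_sequence is a mass-weighted residue mean", {
  # homopolymers return the tabulated residue value exactly
  expect_equal(vbar_from_sequence("GGGG"), 0.64)
  expect_equal(vbar_from_sequence("AAA"), 0.74)
  # two-residue weighted mean by hand (Gly 57.05 Da/0.64, Ala 71.08 Da/0.74)
  byhand <- (57.05 * 0.64 + 71.08 * 0.74) / (57.05 + 71.08)
  expect_equal(vbar_from_sequence("GA"), byhand)
  expect_equal(vbar_from_sequence("ga"), byhand)  # case-insensitive
  expect_error(vbar_from_sequence(""), "non-empty")
  expect_error(vbar_from_sequence("GAX"), "position 3")
  # physically plausible range on random standard sequences
  set.seed(5)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:20) {
    s <- paste(sample(aas, 150, replace = TRUE), collapse = "")
    v <- vbar_from_sequence(s)
    expect_gt(v, 0.58); expect_lt(v, 0.80)
  }
})

test_that("read_fasta_seq round-trips a single record", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">toy synthetic", "GAVL", "IKRH"), f)
  expect_identical(read_fasta_seq(f), "GAVLIKRH")
  writeLines(c(">a", "GAV", ">b", "LIK"), f)
  expect_error(read_fasta_seq(f), "single")
})

test_that("fit_transition_midpoint recovers exact and noisy logistic midpoints", {
  x <- seq(0, 6, by = 0.25)
  # decreasing transition, midpoint 3.4, plateaus 3.5 -> 2.0
  y <- logistic_curve(x, 3.5, 2.0, 3.4, 0.3)
  fit <- fit_transition_midpoint(x, y)
  expect_lt(abs(fit$midpoint - 3.4), 1e-6)
  # reversed (increasing) transition: same midpoint, amplitudes swapped
  fit_up <- fit_transition_midpoint(x, logistic_curve(x, 2.0, 3.5, 3.4, 0.3))
  expect_lt(abs(fit_up$midpoint - 3.4), 1e-6)
  expect_equal(fit_up$lower, fit$upper, tolerance = 1e-6)
  expect_equal(fit_up$upper, fit$lower, tolerance = 1e-6)
  # noisy recovery within 0.15 M
  noisy <- gen_logistic_series(sim_spec("logistic_series",
    truth = list(lower = 3.5, upper = 2.0, midpoint = 3.4, width = 0.3),
    grid = x, noise_sd = 0.03, seed = 13))
  nf <- fit_transition_midpoint(noisy$x, noisy$y)
  expect_lt(abs(nf$midpoint - 3.4), 0.15)
  # flat data: no transition
  expect_error(fit_transition_midpoint(x, rep(2, length(x))), "flat")
  expect_error(fit_transition_midpoint(x[1:4], y[1:4]), "at least 5")
})

test_that("random noiseless logistics are recovered to < 1e-6", {
  set.seed(77)
  for (i in 1:50) {
    lo <- runif(1, -5, 5); up <- lo + sample(c(-1, 1), 1) * runif(1, 0.5, 5)
    mid <- runif(1, 1.5, 4.5); w <- runif(1, 0.15, 0.8)
    x <- seq(0, 6, by = 0.2)
    fit <- fit_transition_midpoint(x, logistic_curve(x, lo, up, mid, w))
    expect_lt(abs(fit$midpoint - mid), 1e-6)
  }
})

test_that("classify_oligomer separates dimer, monomer and other", {
  expect_identical(classify_oligomer(78, 39), "dimer")
  expect_identical(classify_oligomer(39, 39), "monomer")
  expect_identical(classify_oligomer(60, 39), "other")
  expect_identical(classify_oligomer(c(78, 39, 60), 39),
                   c("dimer", "monomer", "other"))
  expect_error(classify_oligomer(-1, 39), "positive")
})
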