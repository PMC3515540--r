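# Shared simulation truths (wild-type Sis1 style) and independent oracles.

sis1_chem_params <- function(Y = c(0, 0.5, 1))
  three_state_params(dG_NI = 7.2, m_NI = 2.1, dG_IU = 8.0, m_IU = 1.7,
                     Y_N = Y[1], Y_I = Y[2], Y_U = Y[3])

sis1_dsc_transitions <- function()
  list(transition_fit(59.0, 154.0), transition_fit(67.7, 29.5))

# Independent oracle: direct Boltzmann-weight evaluation of the three-state
# partition function (free energies of I and U relative to N, no K1/K2
# factorization).
oracle_three_state <- function(d, p, temperature_K = 293.15) {
  RT <- 1.987e-3 * temperature_K
  gI <- p$dG_NI - p$m_NI * d
  gU <- gI + p$dG_IU - p$m_IU * d
  sapply(seq_along(d), function(i) {
    w <- c(1, exp(-gI[i] / RT), exp(-gU[i] / RT))
    sum(c(p$Y_N, p$Y_I, p$Y_U) * w) / sum(w)
  })
}

random_three_state_params <- function() {
  m1 <- runif(1, 0.5, 4); m2 <- runif(1, 0.5, 4)
  Cm1 <- runif(1, 1, 3); Cm2 <- Cm1 + runif(1, 0.5, 3)
  three_state_params(dG_NI = m1 * Cm1, m_NI = m1,
                     dG_IU = m2 * Cm2, m_IU = m2,
                     Y_N = runif(1, -10, 10), Y_I = runif(1, -10, 10),
                     Y_U = runif(1, -10, 10))
}

logistic_curve <- function(x, lower, upper, midpoint, width)
  lower + (upper - lower) / (1 + exp((midpoint - x) / width))
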