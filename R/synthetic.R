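#' Simulation specification
#'
#' Describes one synthetic dataset: the forward model, its true parameters,
#' the sampling grid, the noise scale in observable units and a seed. Equal
#' specs produce bit-identical data; independent noise arrays inside one
#' generator use sub-streams derived deterministically from the seed, so
#' adding an output never shifts existing draws.
#'
#' @param model_kind one of `"chem_three_state"`, `"dsc_two_transition"`,
#'   `"kirchhoff_line"`, `"logistic_series"`, `"stern_volmer"`,
#'   `"emission_spectrum"`.
#' @param truth named list of true parameters for the chosen model (see the
#'   individual `gen_*` functions).
#' @param grid sampling points (non-empty numeric). Defaults per model
#'   mirror the instrument protocols: urea 0-6 M step 0.1 for chemical
#'   unfolding, 15-90 C step 0.25 for DSC, 0-100 mM step 10 for quenching.
#' @param noise_sd Gaussian noise scale in observable units (fractional for
#'   multiplicative models); must be non-negative.
#' @param seed integer seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(model_kind = c("chem_three_state", "dsc_two_transition",
                                    "kirchhoff_line", "logistic_series",
                                    "stern_volmer", "emission_spectrum"),
                     truth, grid = NULL, noise_sd = 0, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (is.null(grid)) {
    grid <- switch(model_kind,
                   chem_three_state = seq(0, 6, by = 0.1),
                   dsc_two_transition = seq(15, 90, by = 0.25),
                   stern_volmer = seq(0, 0.1, by = 0.01),
                   emission_spectrum = seq(300, 420, by = 1),
                   NULL)
  }
  if (model_kind %in% c("chem_three_state", "dsc_two_transition",
                        "stern_volmer", "emission_spectrum",
                        "logistic_series") &&
      (is.null(grid) || length(grid) == 0))
    .stopf("grid must be non-empty")
  if (!is.numeric(noise_sd) || noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(model_kind = model_kind, truth = truth, grid = grid,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic sub-stream seed for the k-th output array of a spec
.substream <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * k) %% .Machine$integer.max)
}

#' Simulate a chemical unfolding curve
#'
#' Forward three-state linear-extrapolation model plus additive Gaussian
#' noise on the signal.
#'
#' @param spec a [sim_spec] with `model_kind = "chem_three_state"`; `truth`
#'   must hold a [three_state_params] (field `params`) and optionally
#'   `temperature_K` (default 293.15) and `signal_kind` (default
#'   `"fraction"`).
#' @return A [chem_unfold_curve].
#' @export
gen_chem_unfold <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "chem_three_state")
  p <- spec$truth$params
  if (!inherits(p, "three_state_params"))
    p <- do.call(three_state_params, spec$truth$params)
  Tk <- spec$truth$temperature_K %||% 293.15
  y <- three_state_fraction(spec$grid, p, Tk)
  noise <- .with_seed(.substream(spec$seed, 1L),
                      stats::rnorm(length(y), 0, spec$noise_sd))
  chem_unfold_curve(spec$grid, y + noise, temperature_K = Tk,
                    signal_kind = spec$truth$signal_kind %||% "fraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate DSC scans
#'
#' First scan = linear baseline + sum of independent two-state transitions
#' + Gaussian noise; optional rescan with the transition heat scaled by a
#' reversibility fraction r (same baseline, independent noise sub-stream).
#'
#' @param spec a [sim_spec] with `model_kind = "dsc_two_transition"`;
#'   `truth` fields: `transitions` (list of [transition_fit]), `baseline`
#'   (`c(intercept, slope)` in kcal/mol/K vs C, default c(0, 0)),
#'   `reversibility` (r in \[0, 1\], or NULL for a single scan).
#' @return List of [thermogram]s: `scan1` and, when `reversibility` is not
#'   NULL, `scan2`.
#' @export
gen_dsc <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "dsc_two_transition")
  trs <- spec$truth$transitions
  tc <- spec$grid
  tms <- vapply(trs, `[[`, numeric(1), "Tm_C")
  if (any(tms < min(tc) | tms > max(tc)))
    .stopf("transition Tm outside the temperature grid")
  bl <- spec$truth$baseline %||% c(0, 0)
  r <- spec$truth$reversibility
  if (!is.null(r) && (r < 0 || r > 1))
    .stopf("reversibility must lie in [0, 1]")
  base <- bl[1] + bl[2] * tc
  peak <- .sum_transitions(tc, trs)
  n1 <- .with_seed(.substream(spec$seed, 1L),
                   stats::rnorm(length(tc), 0, spec$noise_sd))
  out <- list(scan1 = thermogram(tc, base + peak + n1, scan_index = 1L))
  if (!is.null(r)) {
    n2 <- .with_seed(.substream(spec$seed, 2L),
                     stats::rnorm(length(tc), 0, spec$noise_sd))
    out$scan2 <- thermogram(tc, base + r * peak + n2, scan_index = 2L)
  }
  out
}

#' Simulate a Kirchhoff (Tm, dH_cal) series
#'
#' Enthalpies on the line dH = dH_ref + dCp (Tm - Tm_ref) at perturbed
#' midpoints (emulating sub-denaturing urea 0.25-2 M), plus Gaussian noise
#' on dH.
#'
#' @param spec a [sim_spec] with `model_kind = "kirchhoff_line"`; `truth`
#'   fields: `dCp` (kcal/mol/K), `dH_ref` (kcal/mol), `Tm_ref_C`,
#'   `Tm_shifts` (numeric vector of Tm offsets from `Tm_ref_C`, one per
#'   condition, at least 3), optional `urea_M` metadata of the same length.
#' @return Data frame `urea_M` (if given), `Tm_C`, `dHcal_kcal_mol`.
#' @export
gen_kirchhoff_series <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "kirchhoff_line")
  tr <- spec$truth
  if (length(tr$Tm_shifts) < 3) .stopf("need at least 3 conditions")
  Tm <- tr$Tm_ref_C + tr$Tm_shifts
  dH <- tr$dH_ref + tr$dCp * (Tm - tr$Tm_ref_C)
  noise <- .with_seed(.substream(spec$seed, 1L),
                      stats::rnorm(length(Tm), 0, spec$noise_sd))
  out <- data.frame(Tm_C = Tm, dHcal_kcal_mol = dH + noise)
  if (!is.null(tr$urea_M)) out <- cbind(urea_M = tr$urea_M, out)
  out
}

#' Simulate a logistic transition series
#'
#' Four-parameter logistic plus Gaussian noise on the requested grid; the
#' common shape behind s20,w-vs-urea, molar-mass-vs-urea and thermal CD
#' series.
#'
#' @param spec a [sim_spec] with `model_kind = "logistic_series"`; `truth`
#'   fields: `lower`, `upper`, `midpoint`, `width` (> 0); `grid` is the x
#'   axis (urea in M or temperature in C).
#' @param kind output flavor: `"sed"` (columns `urea_M`, `s0_20w_S`),
#'   `"mm"` (`urea_M`, `mm_kDa`), `"thermal_cd"` (`temp_C`, `signal`) or
#'   `"xy"` (`x`, `y`).
#' @return Data frame in the requested column layout.
#' @export
gen_logistic_series <- function(spec, kind = c("xy", "sed", "mm", "thermal_cd")) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "logistic_series")
  kind <- match.arg(kind)
  tr <- spec$truth
  if (is.null(tr$width) || tr$width <= 0) .stopf("truth width must be positive")
  x <- spec$grid
  y <- tr$lower + (tr$upper - tr$lower) / (1 + exp((tr$midpoint - x) / tr$width))
  noise <- .with_seed(.substream(spec$seed, 1L),
                      stats::rnorm(length(x), 0, spec$noise_sd))
  y <- y + noise
  switch(kind,
         xy = data.frame(x = x, y = y),
         sed = data.frame(urea_M = x, s0_20w_S = y),
         mm = data.frame(urea_M = x, mm_kDa = y),
         thermal_cd = data.frame(temp_C = x, signal = y))
}

#' Simulate an acrylamide quenching series
#'
#' Intensities F = F0 / (1 + Ksv \[Q\]) with multiplicative Gaussian noise
#' (`noise_sd` is the fractional scale).
#'
#' @param spec a [sim_spec] with `model_kind = "stern_volmer"`; `truth`
#'   fields `F0` (> 0) and `Ksv` (>= 0, 1/M); `grid` are quencher
#'   concentrations in M starting at 0 (default 0-0.1 step 0.01).
#' @return A [quench_series].
#' @export
gen_quench_series <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "stern_volmer")
  tr <- spec$truth
  if (tr$Ksv < 0) .stopf("Ksv must be non-negative")
  Q <- spec$grid
  f <- tr$F0 / (1 + tr$Ksv * Q)
  fac <- .with_seed(.substream(spec$seed, 1L),
                    stats::rnorm(length(Q), 0, spec$noise_sd))
  quench_series(Q, f * (1 + fac))
}

#' Simulate a tryptophan emission spectrum
#'
#' Gaussian emission band centered at the true center of spectral mass,
#' plus additive noise truncated at zero.
#'
#' @param spec a [sim_spec] with `model_kind = "emission_spectrum"`;
#'   `truth` fields `center_nm`, `width_nm`, `amplitude`.
#' @return An [emission_spectrum].
#' @export
gen_emission_spectrum <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"), spec$model_kind == "emission_spectrum")
  tr <- spec$truth
  lam <- spec$grid
  f <- tr$amplitude * exp(-0.5 * ((lam - tr$center_nm) / tr$width_nm)^2)
  noise <- .with_seed(.substream(spec$seed, 1L),
                      stats::rnorm(length(lam), 0, spec$noise_sd))
  emission_spectrum(lam, pmax(f + noise, 0))
}
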