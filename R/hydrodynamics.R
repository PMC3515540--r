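#' Buffer solvent properties
#'
#' @param density_g_mL solvent density, g/mL, positive.
#' @param viscosity_cP solvent viscosity, cP, positive.
#' @return A `buffer_props` list.
#' @export
buffer_props <- function(density_g_mL, viscosity_cP) {
  if (density_g_mL <= 0 || viscosity_cP <= 0)
    .stopf("buffer density and viscosity must be positive")
  structure(list(density_g_mL = density_g_mL, viscosity_cP = viscosity_cP),
            class = "buffer_props")
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' Corrects an apparent sedimentation coefficient for solvent viscosity and
#' buoyancy to the standard condition (water, 20 C):
#' s20,w = s_obs (eta_b / eta_w20) (1 - vbar rho_w20) / (1 - vbar rho_b),
#' with water-at-20 C constants eta = 1.002 cP, rho = 0.99823 g/mL.
#'
#' @param s_obs apparent sedimentation coefficient, Svedberg.
#' @param vbar partial specific volume of the protein, mL/g.
#' @param buffer a [buffer_props] (density and viscosity of the experiment
#'   solvent at the experiment temperature).
#' @return s20,w in Svedberg (vectorized over `s_obs`).
#' @export
correct_s_to_s20w <- function(s_obs, vbar, buffer) {
  b_w <- 1 - vbar * .water20$density_g_mL
  b_b <- 1 - vbar * buffer$density_g_mL
  if (b_w <= 0 || b_b <= 0)
    .stopf("buoyancy term 1 - vbar*rho is not positive (vbar = %.4f)", vbar)
  s_obs * (buffer$viscosity_cP / .water20$viscosity_cP) * b_w / b_b
}

#' Extrapolate s20,w to zero protein concentration
#'
#' Ordinary least-squares line through s20,w versus loading concentration;
#' the intercept is the standard sedimentation coefficient at 0 mg/mL.
#'
#' @param conc_mg_mL protein concentrations, mg/mL.
#' @param s20w_S standardized sedimentation coefficients, S.
#' @return List with `s0_20w`, `se_s0`, `slope`, `se_slope`, `n`, and
#'   `single_point` (TRUE when only one concentration was available, in
#'   which case the value is returned with infinite standard error).
#' @export
extrapolate_s0 <- function(conc_mg_mL, s20w_S) {
  if (length(conc_mg_mL) != length(s20w_S)) .stopf("input lengths differ")
  if (length(unique(conc_mg_mL)) < 2) {
    warning("single concentration: returning its s20,w with infinite standard error")
    return(list(s0_20w = mean(s20w_S), se_s0 = Inf, slope = NA_real_,
                se_slope = Inf, n = length(s20w_S), single_point = TRUE))
  }
  fit <- stats::lm(s20w_S ~ conc_mg_mL)
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(s0_20w = cf["(Intercept)", "Estimate"],
       se_s0 = cf["(Intercept)", "Std. Error"],
       slope = cf["conc_mg_mL", "Estimate"],
       se_slope = cf["conc_mg_mL", "Std. Error"],
       n = length(s20w_S), single_point = FALSE)
}

# Kell equation: density of air-free water, g/mL, t in C
.water_density <- function(t) {
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.87985e-3 * t) / 1000
}

# Vogel equation: viscosity of water, cP, t in C
.water_viscosity <- function(t) exp(-3.7188 + 578.919 / (-137.546 + t + 273.15))

#' Density and viscosity of aqueous urea
#'
#' Empirical solvent properties of urea solutions for sedimentation
#' standardization. Water density follows the Kell equation and water
#' viscosity the Vogel equation; the urea contribution uses empirical
#' relations in urea molarity calibrated against tabulated urea-solution
#' data: density from the weight-fraction expansion
#' rho = rho_w + 0.2658 W + 0.0330 W^2 (W = urea weight fraction, solved by
#' fixed point), relative viscosity 1 + 0.0329 c + 0.00375 c^2.
#'
#' @param urea_M urea molarity, 0 to 9 M.
#' @param temp_C solution temperature, C (default 20).
#' @return A [buffer_props].
#' @export
urea_buffer_props <- function(urea_M, temp_C = 20) {
  if (!is.finite(urea_M) || urea_M < 0 || urea_M > 9)
    .stopf("urea_M must be within [0, 9] M (got %s)", format(urea_M))
  rho_w <- .water_density(temp_C)
  rho <- rho_w
  for (i in 1:30) {
    W <- 60.056 * urea_M / (1000 * rho)
    rho_new <- rho_w + 0.2658 * W + 0.0330 * W^2
    if (abs(rho_new - rho) < 1e-12) { rho <- rho_new; break }
    rho <- rho_new
  }
  eta <- .water_viscosity(temp_C) * (1 + 0.0329 * urea_M + 0.00375 * urea_M^2)
  buffer_props(rho, eta)
}

# Cohn-Edsall consensus partial specific volumes (mL/g) and residue masses
# (Da, monomer minus water) for the 20 standard amino acids.
.residue_table <- data.frame(
  aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  vbar = c(0.74, 0.70, 0.62, 0.60, 0.63, 0.67, 0.66, 0.64, 0.67, 0.90,
           0.90, 0.82, 0.75, 0.77, 0.76, 0.63, 0.70, 0.74, 0.71, 0.86),
  mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
           137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
           101.10, 186.21, 163.18, 99.13),
  stringsAsFactors = FALSE
)

#' Partial specific volume from an amino-acid sequence
#'
#' Mass-weighted mean of tabulated residue partial specific volumes
#' (Cohn-Edsall consensus values), the standard composition-based estimate
#' used to standardize sedimentation coefficients.
#'
#' @param sequence one-letter amino-acid string (standard 20 letters; case
#'   insensitive).
#' @return Partial specific volume, mL/g.
#' @export
vbar_from_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    .stopf("sequence must be a single non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(aa, .residue_table$aa)
  if (anyNA(idx))
    .stopf("unknown amino-acid letter '%s' at position %d",
           aa[which(is.na(idx))[1]], which(is.na(idx))[1])
  m <- .residue_table$mass[idx]
  sum(m * .residue_table$vbar[idx]) / sum(m)
}

#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with exactly one record.
#' @return The sequence as an upper-case string.
#' @export
read_fasta_seq <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) != 1)
    .stopf("expected a single FASTA record, found %d", length(recs))
  toupper(as.character(recs[[1]]))
}

#' Classify oligomeric state from a weight-average molar mass
#'
#' Compares an observed weight-average molar mass with the sequence
#' monomer mass: dimer when the ratio is within `2 tol` of 2, monomer when
#' within `tol` of 1, otherwise "other".
#'
#' @param mm_obs observed molar mass, kDa.
#' @param mm_monomer monomer (sequence) molar mass, kDa.
#' @param tol relative tolerance (default 0.15).
#' @return `"monomer"`, `"dimer"` or `"other"` (vectorized over `mm_obs`).
#' @export
classify_oligomer <- function(mm_obs, mm_monomer, tol = 0.15) {
  if (any(mm_obs <= 0) || mm_monomer <= 0) .stopf("masses must be positive")
  r <- mm_obs / mm_monomer
  ifelse(abs(r - 2) <= 2 * tol, "dimer",
         ifelse(abs(r - 1) <= tol, "monomer", "other"))
}
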