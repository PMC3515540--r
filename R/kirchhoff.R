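#' Kirchhoff regression of calorimetric enthalpy on Tm
#'
#' Estimates the heat-capacity change of an unfolding transition from the
#' linear dependence of the calorimetric enthalpy on the transition
#' midpoint, dH_cal(Tm) = dH_ref + dCp (Tm - Tm_ref), with dCp assumed
#' temperature-independent. The (Tm, dH_cal) pairs typically come from
#' scans perturbed by sub-denaturing urea; the perturbant concentration is
#' metadata only and never enters the regression.
#'
#' @param series a data frame with columns `Tm_C` and `dHcal_kcal_mol`
#'   (extra columns such as `urea_M` are carried along as metadata), or a
#'   numeric vector of Tm values when `dHcal` is given separately.
#' @param dHcal optional numeric vector of enthalpies when `series` is a
#'   Tm vector.
#' @param Tm_ref_C reference temperature; default the highest Tm in the
#'   series (the unperturbed, zero-urea scan).
#' @param weights optional regression weights; unweighted by default.
#' @return A `kirchhoff_fit` object: `dCp` (kcal/mol/K), `se_dCp`,
#'   `dH_ref` (kcal/mol at `Tm_ref_C`), `se_dH_ref`, `Tm_ref_C`, and the
#'   underlying `lm` fit.
#' @export
fit_kirchhoff <- function(series, dHcal = NULL, Tm_ref_C = NULL,
                          weights = NULL) {
  if (is.data.frame(series)) {
    if (!all(c("Tm_C", "dHcal_kcal_mol") %in% names(series)))
      .stopf("series needs columns Tm_C and dHcal_kcal_mol")
    Tm <- series$Tm_C
    dH <- series$dHcal_kcal_mol
  } else {
    Tm <- as.numeric(series)
    dH <- as.numeric(dHcal)
  }
  if (length(Tm) != length(dH)) .stopf("Tm and dHcal lengths differ")
  if (length(Tm) < 3) .stopf("Kirchhoff regression needs at least 3 pairs")
  if (length(unique(Tm)) < 2)
    .stopf("all Tm values identical: regression is rank-deficient")
  if (is.null(Tm_ref_C)) Tm_ref_C <- max(Tm)
  df <- data.frame(dH = dH, dT = Tm - Tm_ref_C)
  lmfit <- stats::lm(dH ~ dT, data = df, weights = weights)
  # exact collinear input is a designed use; silence the perfect-fit note
  cf <- suppressWarnings(summary(lmfit)$coefficients)
  structure(list(dCp = cf["dT", "Estimate"],
                 se_dCp = cf["dT", "Std. Error"],
                 dH_ref = cf["(Intercept)", "Estimate"],
                 se_dH_ref = cf["(Intercept)", "Std. Error"],
                 Tm_ref_C = Tm_ref_C, n = length(Tm),
                 Tm_C = Tm, dHcal_kcal_mol = dH, lm = lmfit),
            class = "kirchhoff_fit")
}

#' @export
print.kirchhoff_fit <- function(x, ...) {
  cat("Kirchhoff regression dH_cal ~ Tm\n")
  cat(sprintf("  dCp = %.3f (SE %.3f) kcal/mol/K\n", x$dCp, x$se_dCp))
  cat(sprintf("  dH_ref = %.1f (SE %.1f) kcal/mol at Tm_ref = %.2f C (n = %d)\n",
              x$dH_ref, x$se_dH_ref, x$Tm_ref_C, x$n))
  invisible(x)
}

#' @export
coef.kirchhoff_fit <- function(object, ...)
  c(dCp = object$dCp, dH_ref = object$dH_ref)

#' @export
predict.kirchhoff_fit <- function(object, newdata = NULL, ...) {
  Tm <- if (is.null(newdata)) object$Tm_C
        else if (is.numeric(newdata)) newdata else newdata$Tm_C
  object$dH_ref + object$dCp * (Tm - object$Tm_ref_C)
}

#' @export
residuals.kirchhoff_fit <- function(object, ...)
  object$dHcal_kcal_mol - predict(object)

#' @export
plot.kirchhoff_fit <- function(x, ...) {
  graphics::plot(x$Tm_C, x$dHcal_kcal_mol, xlab = "Tm (C)",
                 ylab = "dH_cal (kcal/mol)", main = "Kirchhoff plot", ...)
  graphics::abline(x$dH_ref - x$dCp * x$Tm_ref_C, x$dCp)
  invisible(x)
}

#' Per-residue heat-capacity change
#'
#' Normalizes a transition heat-capacity change by the number of residues
#' of the domain assigned to that transition, 1000 dCp / n_residues in
#' cal/mol/K per residue. With the default `digits = 1` the value is
#' reported to one decimal, the conventional precision for this quantity;
#' pass `digits = NULL` for the exact ratio (which satisfies
#' `per_residue_dcp(dCp, n, digits = NULL) * n / 1000 == dCp`).
#'
#' @param dCp heat-capacity change, kcal/mol/K.
#' @param n_residues number of amino-acid residues in the unfolding domain.
#' @param digits decimals for reporting (default 1), or `NULL` for the
#'   unrounded ratio.
#' @return Per-residue dCp in cal/mol/K.
#' @export
per_residue_dcp <- function(dCp, n_residues, digits = 1) {
  if (any(!is.finite(n_residues)) || any(n_residues <= 0))
    .stopf("n_residues must be positive")
  out <- 1000 * dCp / n_residues
  if (is.null(digits)) out else round(out, digits)
}
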