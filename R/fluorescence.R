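#' Tryptophan emission spectrum
#'
#' @param lambda_nm ascending emission wavelengths, nm.
#' @param intensity non-negative fluorescence intensities; at least one must
#'   be strictly positive.
#' @return An `emission_spectrum` data frame.
#' @export
emission_spectrum <- function(lambda_nm, intensity) {
  if (length(lambda_nm) != length(intensity)) .stopf("input lengths differ")
  if (any(diff(lambda_nm) <= 0)) .stopf("lambda_nm must be strictly increasing")
  if (any(intensity < 0)) .stopf("intensities must be non-negative")
  if (!any(intensity > 0)) .stopf("all intensities are zero")
  structure(data.frame(lambda_nm = lambda_nm, intensity = intensity),
            class = c("emission_spectrum", "data.frame"))
}

#' Center of spectral mass
#'
#' Intensity-weighted mean emission wavelength,
#' \eqn{\langle\lambda\rangle = \sum \lambda_i F_i / \sum F_i}. Red shifts
#' of the center report increased solvent exposure of the fluorophore.
#'
#' @param sp an [emission_spectrum], or a data frame with `lambda_nm` and
#'   `intensity` columns.
#' @return Center of spectral mass, nm.
#' @export
center_of_spectral_mass <- function(sp) {
  if (!inherits(sp, "emission_spectrum"))
    sp <- emission_spectrum(sp$lambda_nm, sp$intensity)
  sum(sp$lambda_nm * sp$intensity) / sum(sp$intensity)
}

#' Acrylamide quenching series
#'
#' @param quencher_M ascending quencher (acrylamide) concentrations, M,
#'   starting at 0 (which defines F0).
#' @param intensity positive fluorescence intensities at the emission
#'   maximum for each concentration.
#' @return A `quench_series` data frame.
#' @export
quench_series <- function(quencher_M, intensity) {
  if (length(quencher_M) != length(intensity)) .stopf("input lengths differ")
  if (quencher_M[1] != 0) .stopf("first entry must be quencher_M = 0 (defines F0)")
  if (any(diff(quencher_M) <= 0)) .stopf("quencher_M must be strictly increasing")
  if (any(intensity <= 0)) .stopf("intensities must be positive")
  structure(data.frame(quencher_M = quencher_M, intensity = intensity),
            class = c("quench_series", "data.frame"))
}

#' Stern-Volmer quenching fit
#'
#' Linear regression of F0/F on quencher concentration for collisional
#' quenching: F0/F = 1 + Ksv [Q]. By default the intercept is fitted freely
#' and reported as a linearity diagnostic (it should be close to 1);
#' `force_intercept = TRUE` constrains the regression through 1, matching
#' the Stern-Volmer equation exactly.
#'
#' @param q a [quench_series] (or data frame with `quencher_M` and
#'   `intensity`), at least 4 concentrations.
#' @param force_intercept constrain the intercept to 1 (default FALSE).
#' @return A `stern_volmer_fit` object: `Ksv` (1/M), `se_Ksv`, `intercept`,
#'   `se_intercept`, `F0`, underlying `lm`.
#' @export
fit_stern_volmer <- function(q, force_intercept = FALSE) {
  if (!inherits(q, "quench_series")) q <- quench_series(q$quencher_M, q$intensity)
  if (nrow(q) < 4) .stopf("Stern-Volmer fit needs at least 4 concentrations")
  F0 <- q$intensity[1]
  df <- data.frame(Q = q$quencher_M, ratio = F0 / q$intensity)
  if (force_intercept) {
    lmfit <- stats::lm(I(ratio - 1) ~ 0 + Q, data = df)
    cf <- suppressWarnings(summary(lmfit)$coefficients)
    Ksv <- cf["Q", "Estimate"]; se <- cf["Q", "Std. Error"]
    intercept <- 1; se_int <- 0
  } else {
    lmfit <- stats::lm(ratio ~ Q, data = df)
    cf <- suppressWarnings(summary(lmfit)$coefficients)
    Ksv <- cf["Q", "Estimate"]; se <- cf["Q", "Std. Error"]
    intercept <- cf["(Intercept)", "Estimate"]
    se_int <- cf["(Intercept)", "Std. Error"]
  }
  structure(list(Ksv = Ksv, se_Ksv = se, intercept = intercept,
                 se_intercept = se_int, F0 = F0,
                 force_intercept = force_intercept, data = df, lm = lmfit),
            class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat("Stern-Volmer quenching fit\n")
  cat(sprintf("  Ksv = %.2f (SE %.2g) 1/M\n", x$Ksv, x$se_Ksv))
  cat(sprintf("  intercept = %.3f%s (expected ~1 for collisional quenching)\n",
              x$intercept, if (x$force_intercept) " [forced]" else ""))
  invisible(x)
}

#' @export
coef.stern_volmer_fit <- function(object, ...)
  c(Ksv = object$Ksv, intercept = object$intercept)

#' @export
predict.stern_volmer_fit <- function(object, newdata = NULL, ...) {
  Q <- if (is.null(newdata)) object$data$Q
       else if (is.numeric(newdata)) newdata else newdata$quencher_M
  object$intercept + object$Ksv * Q
}

#' @export
residuals.stern_volmer_fit <- function(object, ...)
  object$data$ratio - predict(object)

#' @export
plot.stern_volmer_fit <- function(x, ...) {
  graphics::plot(x$data$Q, x$data$ratio, xlab = "[Q] (M)", ylab = "F0/F",
                 main = "Stern-Volmer plot", ...)
  graphics::abline(x$intercept, x$Ksv)
  invisible(x)
}
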