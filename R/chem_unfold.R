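#' Chemical unfolding curve
#'
#' Container for an equilibrium denaturant-titration curve: molar urea
#' concentrations against an observed optical signal, measured at a fixed
#' temperature. The signal may be a raw spectroscopic quantity (e.g.
#' ellipticity at 222 nm in deg cm^2/dmol) or an apparent fraction of
#' unfolded protein.
#'
#' @param denaturant_M numeric, strictly increasing molar denaturant
#'   concentrations.
#' @param signal numeric observed signal, same length as `denaturant_M`.
#' @param temperature_K absolute temperature of the measurement (default
#'   293.15 K, i.e. 20 C).
#' @param signal_kind `"raw"` or `"fraction"`.
#' @return An object of class `chem_unfold_curve`: a data frame with columns
#'   `denaturant_M` and `signal` plus `temperature_K` and `signal_kind`
#'   attributes.
#' @export
chem_unfold_curve <- function(denaturant_M, signal,
                              temperature_K = 293.15,
                              signal_kind = c("raw", "fraction")) {
  signal_kind <- match.arg(signal_kind)
  if (length(denaturant_M) != length(signal))
    .stopf("denaturant_M and signal must have the same length")
  if (anyNA(denaturant_M) || anyNA(signal))
    .stopf("missing values are not allowed in an unfolding curve")
  if (any(diff(denaturant_M) <= 0))
    .stopf("denaturant_M must be strictly increasing")
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 ||
      !is.finite(temperature_K) || temperature_K <= 0)
    .stopf("temperature_K must be a single positive number")
  out <- data.frame(denaturant_M = as.numeric(denaturant_M),
                    signal = as.numeric(signal))
  attr(out, "temperature_K") <- temperature_K
  attr(out, "signal_kind") <- signal_kind
  class(out) <- c("chem_unfold_curve", "data.frame")
  out
}

#' Three-state unfolding parameters
#'
#' Parameter set of the three-state linear-extrapolation model
#' N <-> I <-> U: zero-denaturant free-energy changes (kcal/mol) and
#' m-values (kcal/mol/M) of the two transitions, and the plateau signals of
#' the three species.
#'
#' @param dG_NI,dG_IU free-energy change of the N-I and I-U transitions at
#'   zero denaturant, kcal/mol; must be positive for a protein folded in
#'   water.
#' @param m_NI,m_IU m-values (slope of delta-G versus denaturant), positive,
#'   kcal/mol/M.
#' @param Y_N,Y_I,Y_U plateau signals of native, intermediate and unfolded
#'   species, in the unit of the observed signal.
#' @return A named list of class `three_state_params`.
#' @export
three_state_params <- function(dG_NI, m_NI, dG_IU, m_IU, Y_N, Y_I, Y_U) {
  p <- list(dG_NI = dG_NI, m_NI = m_NI, dG_IU = dG_IU, m_IU = m_IU,
            Y_N = Y_N, Y_I = Y_I, Y_U = Y_U)
  vals <- unlist(p)
  if (!all(is.finite(vals))) .stopf("all three-state parameters must be finite")
  if (m_NI <= 0 || m_IU <= 0) .stopf("m-values must be positive")
  if (dG_NI <= 0 || dG_IU <= 0)
    .stopf("dG values must be positive (protein folded at zero denaturant)")
  structure(p, class = "three_state_params")
}

#' Three-state linear-extrapolation signal
#'
#' Forward model of a three-state equilibrium unfolding transition under the
#' linear extrapolation method. Each transition free energy is linear in
#' denaturant, dG(d) = dG0 - m d; equilibrium constants
#' K1 = exp(-(dG_NI - m_NI d)/RT) and K2 = exp(-(dG_IU - m_IU d)/RT) give
#' species populations fN = 1/Z, fI = K1/Z, fU = K1 K2/Z with
#' Z = 1 + K1 + K1 K2, and the observable is the population-weighted plateau
#' signal.
#'
#' @param d denaturant concentration(s), M.
#' @param params a [three_state_params] object (or list with those fields).
#' @param temperature_K absolute temperature, K.
#' @param what `"signal"` (default) returns the observable; `"fractions"`
#'   returns a matrix with columns `fN`, `fI`, `fU`.
#' @return Numeric vector of model signal values, or the fraction matrix.
#' @export
three_state_fraction <- function(d, params, temperature_K = 293.15,
                                 what = c("signal", "fractions")) {
  what <- match.arg(what)
  if (!all(is.finite(unlist(params[c("dG_NI", "m_NI", "dG_IU", "m_IU")]))))
    .stopf("non-finite three-state parameters")
  if (params$m_NI <= 0 || params$m_IU <= 0) .stopf("m-values must be positive")
  if (temperature_K <= 0) .stopf("temperature_K must be positive")
  RT <- Rgas_kcal * temperature_K
  K1 <- exp(-(params$dG_NI - params$m_NI * d) / RT)
  K2 <- exp(-(params$dG_IU - params$m_IU * d) / RT)
  Z <- 1 + K1 + K1 * K2
  fN <- 1 / Z
  fI <- K1 / Z
  fU <- K1 * K2 / Z
  if (what == "fractions")
    return(cbind(fN = fN, fI = fI, fU = fU))
  params$Y_N * fN + params$Y_I * fI + params$Y_U * fU
}

#' Convert a raw-signal curve to fraction unfolded
#'
#' Projects a raw optical signal onto the apparent fraction of unfolded
#' protein using linear native and unfolded baselines:
#' f(d) = (y(d) - yN(d)) / (yU(d) - yN(d)).
#'
#' @param curve a [chem_unfold_curve] with `signal_kind = "raw"`.
#' @param native_baseline,unfolded_baseline numeric length-2 vectors
#'   `c(intercept, slope)` of the pre- and post-transition baselines in
#'   signal units versus M.
#' @param tol minimum allowed baseline separation at any point, in signal
#'   units.
#' @return A [chem_unfold_curve] with `signal_kind = "fraction"`.
#' @export
raw_to_fraction <- function(curve, native_baseline, unfolded_baseline,
                            tol = 1e-8) {
  d <- curve$denaturant_M
  yN <- native_baseline[1] + native_baseline[2] * d
  yU <- unfolded_baseline[1] + unfolded_baseline[2] * d
  if (any(abs(yU - yN) < tol))
    .stopf("degenerate baselines: native and unfolded coincide within %g", tol)
  f <- (curve$signal - yN) / (yU - yN)
  chem_unfold_curve(d, f, temperature_K = attr(curve, "temperature_K"),
                    signal_kind = "fraction")
}

#' Transition midpoint from dG and m
#'
#' Midpoint denaturant concentration of a linear-extrapolation transition,
#' Cm = dG / m: the concentration at which the transition free energy
#' vanishes.
#'
#' @param dG free-energy change at zero denaturant, kcal/mol.
#' @param m m-value, kcal/mol/M; must be positive.
#' @return Cm in M (vectorized).
#' @export
compute_cm <- function(dG, m) {
  if (any(!is.finite(m)) || any(m <= 0)) .stopf("m must be positive and finite")
  dG / m
}

# Self-initialization for sigmoid-like unfolding data (see fit_three_state).
.init_three_state <- function(d, y) {
  n <- length(d)
  k <- max(2L, ceiling(0.1 * n))
  Y_N <- mean(y[seq_len(k)])
  Y_U <- mean(y[seq.int(n - k + 1L, n)])
  # light smoothing for crossing detection
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  rng <- Y_U - Y_N
  cross <- function(q) {
    target <- Y_N + q * rng
    idx <- if (rng >= 0) which(ys >= target) else which(ys <= target)
    if (length(idx) == 0) return(stats::median(d))
    d[idx[1]]
  }
  Cm1 <- cross(0.25)
  Cm2 <- cross(0.75)
  if (Cm2 <= Cm1) Cm2 <- Cm1 + max(diff(range(d)) / 10, 0.1)
  m0 <- 2
  list(dG_NI = m0 * max(Cm1, 0.1), m_NI = m0,
       dG_IU = m0 * Cm2, m_IU = m0,
       Y_N = Y_N, Y_I = (Y_N + Y_U) / 2, Y_U = Y_U)
}

#' Fit the three-state unfolding model
#'
#' Nonlinear least-squares fit of [three_state_fraction] to a chemical
#' unfolding curve. The two transitions are kept ordered by construction:
#' the optimizer works on (dG_NI, m_NI, m_IU, log(Cm_IU - Cm_NI), Y...), so
#' Cm_NI < Cm_IU holds for every candidate. Midpoints are reported as the
#' exact ratios Cm = dG/m of the fitted parameters. Standard errors come
#' from the local curvature of the least-squares objective (Gauss-Newton
#' approximation) evaluated in the natural parameterization.
#'
#' @param curve a [chem_unfold_curve] (raw or fraction signal; the plateau
#'   parameters absorb the units).
#' @param init optional [three_state_params] starting values; when absent the
#'   fit self-initializes from the data (plateaus from the outer 10% of
#'   points, midpoint guesses at the 25%/75% crossings, m-values 2
#'   kcal/mol/M).
#' @param fix_yi optional numeric: constrain the intermediate plateau Y_I to
#'   this value instead of fitting it.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return An object of class `three_state_fit` with components `params`
#'   (fitted [three_state_params]), `se` (named standard errors), `Cm_NI`,
#'   `Cm_IU`, `se_Cm` (delta-method errors on the midpoints),
#'   `residual_rms`, `converged`, `curve`, `fitted`.
#' @export
fit_three_state <- function(curve, init = NULL, fix_yi = NULL, maxiter = 200) {
  stopifnot(inherits(curve, "chem_unfold_curve"))
  d <- curve$denaturant_M
  y <- curve$signal
  Tk <- attr(curve, "temperature_K")
  free_yi <- is.null(fix_yi)
  n_par <- if (free_yi) 7L else 6L
  if (length(d) < 8)
    .stopf("a three-state fit needs at least 8 points spanning both transitions (got %d)",
           length(d))
  if (length(d) <= n_par)
    .stopf("fewer points (%d) than free parameters (%d)", length(d), n_par)

  if (is.null(init)) init <- .init_three_state(d, y)
  Cm1_0 <- init$dG_NI / init$m_NI
  Cm2_0 <- init$dG_IU / init$m_IU
  if (Cm2_0 <= Cm1_0) Cm2_0 <- Cm1_0 + 0.5

  # working parameterization enforces Cm_NI < Cm_IU
  to_natural <- function(w) {
    Cm1 <- w[["dG_NI"]] / w[["m_NI"]]
    Cm2 <- Cm1 + exp(w[["ldCm"]])
    p <- list(dG_NI = w[["dG_NI"]], m_NI = w[["m_NI"]],
              dG_IU = w[["m_IU"]] * Cm2, m_IU = w[["m_IU"]],
              Y_N = w[["Y_N"]],
              Y_I = if (free_yi) w[["Y_I"]] else fix_yi,
              Y_U = w[["Y_U"]])
    p
  }
  w0 <- c(dG_NI = init$dG_NI, m_NI = init$m_NI,
          ldCm = log(Cm2_0 - Cm1_0), m_IU = init$m_IU,
          Y_N = init$Y_N, Y_U = init$Y_U)
  if (free_yi) w0 <- c(w0, Y_I = init$Y_I)
  lower <- c(dG_NI = 1e-3, m_NI = 1e-3, ldCm = log(1e-6), m_IU = 1e-3,
             Y_N = -Inf, Y_U = -Inf)
  upper <- c(dG_NI = 50, m_NI = 10, ldCm = log(50), m_IU = 10,
             Y_N = Inf, Y_U = Inf)
  if (free_yi) {
    lower <- c(lower, Y_I = -Inf)
    upper <- c(upper, Y_I = Inf)
  }
  resid_fn <- function(w) {
    names(w) <- names(w0)
    y - three_state_fraction(d, to_natural(w), Tk)
  }
  fit <- minpack.lm::nls.lm(par = w0, lower = lower[names(w0)],
                            upper = upper[names(w0)], fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = maxiter))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning(sprintf("three-state fit did not converge (nls.lm info %d: %s)",
                    fit$info, fit$message))
  w <- fit$par
  pn <- to_natural(w)
  params <- three_state_params(pn$dG_NI, pn$m_NI, pn$dG_IU, pn$m_IU,
                               pn$Y_N, pn$Y_I, pn$Y_U)
  fitted <- three_state_fraction(d, params, Tk)
  rss <- sum((y - fitted)^2)
  dof <- length(d) - n_par
  sigma2 <- rss / max(dof, 1)

  # curvature-based SEs in the natural parameterization (delta-free)
  nat_names <- c("dG_NI", "m_NI", "dG_IU", "m_IU", "Y_N", "Y_I", "Y_U")
  free_names <- if (free_yi) nat_names else setdiff(nat_names, "Y_I")
  theta <- unlist(params[free_names])
  J <- .num_jacobian(function(th) {
    p <- as.list(params)
    p[free_names] <- as.list(th)
    three_state_fraction(d, p, Tk)
  }, theta)
  covm <- .safe_cov(J, sigma2)
  se <- rep(NA_real_, length(nat_names))
  names(se) <- nat_names
  if (!is.null(covm)) se[free_names] <- sqrt(pmax(diag(covm), 0))
  if (!free_yi) se["Y_I"] <- 0

  Cm_NI <- compute_cm(params$dG_NI, params$m_NI)
  Cm_IU <- compute_cm(params$dG_IU, params$m_IU)
  se_Cm <- c(Cm_NI = NA_real_, Cm_IU = NA_real_)
  if (!is.null(covm)) {
    se_Cm["Cm_NI"] <- .ratio_se(params$dG_NI, params$m_NI,
                                covm[c("dG_NI", "m_NI"), c("dG_NI", "m_NI")])
    se_Cm["Cm_IU"] <- .ratio_se(params$dG_IU, params$m_IU,
                                covm[c("dG_IU", "m_IU"), c("dG_IU", "m_IU")])
  }

  structure(list(params = params, se = se,
                 Cm_NI = Cm_NI, Cm_IU = Cm_IU, se_Cm = se_Cm,
                 residual_rms = sqrt(rss / length(d)),
                 sigma = sqrt(sigma2), converged = converged,
                 n = length(d), temperature_K = Tk, free_yi = free_yi,
                 curve = curve, fitted = fitted, nls_info = fit$info),
            class = "three_state_fit")
}

# central-difference Jacobian of a vector-valued model
.num_jacobian <- function(f, theta) {
  f0 <- f(theta)
  J <- matrix(NA_real_, length(f0), length(theta),
              dimnames = list(NULL, names(theta)))
  for (j in seq_along(theta)) {
    h <- max(1e-6 * abs(theta[j]), 1e-8)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  J
}

.safe_cov <- function(J, sigma2) {
  XtX <- crossprod(J)
  covm <- tryCatch(solve(XtX) * sigma2, error = function(e) NULL)
  if (is.null(covm)) return(NULL)
  dimnames(covm) <- list(colnames(J), colnames(J))
  covm
}

# delta-method SE of a/b given the 2x2 covariance of (a, b)
.ratio_se <- function(a, b, V) {
  g <- c(1 / b, -a / b^2)
  as.numeric(sqrt(pmax(t(g) %*% V %*% g, 0)))
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat("Three-state unfolding fit (linear extrapolation method)\n")
  cat(sprintf("  n = %d points, T = %.2f K, Y_I %s\n", x$n, x$temperature_K,
              if (x$free_yi) "free" else "fixed"))
  p <- x$params
  cat(sprintf("  dG_NI = %.2f (SE %.2f) kcal/mol, m_NI = %.2f kcal/mol/M\n",
              p$dG_NI, x$se["dG_NI"], p$m_NI))
  cat(sprintf("  dG_IU = %.2f (SE %.2f) kcal/mol, m_IU = %.2f kcal/mol/M\n",
              p$dG_IU, x$se["dG_IU"], p$m_IU))
  cat(sprintf("  Cm_NI = %.2f M, Cm_IU = %.2f M\n", x$Cm_NI, x$Cm_IU))
  cat(sprintf("  residual RMS = %.4g; converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
coef.three_state_fit <- function(object, ...) unlist(object$params)

#' @export
summary.three_state_fit <- function(object, ...) {
  tab <- data.frame(estimate = unlist(object$params),
                    std_error = object$se[names(object$params)])
  extra <- data.frame(estimate = c(object$Cm_NI, object$Cm_IU),
                      std_error = object$se_Cm,
                      row.names = c("Cm_NI", "Cm_IU"))
  out <- list(coefficients = rbind(tab, extra),
              residual_rms = object$residual_rms,
              converged = object$converged, n = object$n)
  class(out) <- "summary.three_state_fit"
  out
}

#' @export
print.summary.three_state_fit <- function(x, ...) {
  cat("Three-state unfolding fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("residual RMS %.4g on %d points; converged: %s\n",
              x$residual_rms, x$n, x$converged))
  invisible(x)
}

#' @export
predict.three_state_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$curve$denaturant_M
       else if (is.numeric(newdata)) newdata
       else newdata$denaturant_M
  three_state_fraction(d, object$params, object$temperature_K)
}

#' @export
residuals.three_state_fit <- function(object, ...)
  object$curve$signal - object$fitted

#' @export
fitted.three_state_fit <- function(object, ...) object$fitted

#' @export
plot.three_state_fit <- function(x, ...) {
  d <- x$curve$denaturant_M
  graphics::plot(d, x$curve$signal, xlab = "urea (M)", ylab = "signal",
                 main = "Three-state unfolding fit", ...)
  dd <- seq(min(d), max(d), length.out = 200)
  graphics::lines(dd, three_state_fraction(dd, x$params, x$temperature_K))
  graphics::abline(v = c(x$Cm_NI, x$Cm_IU), lty = 3)
  invisible(x)
}
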