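#' Four-parameter logistic transition fit
#'
#' Generic sigmoid used for every single-transition midpoint in the
#' pipeline: thermal CD melting curves (Tm_CD), sedimentation-coefficient
#' versus urea series (Cm_AUC) and molar-mass versus urea series
#' (Cm_SEC-MALLS). The model is
#' y(x) = lower + (upper - lower) / (1 + exp((midpoint - x)/width)),
#' so y -> lower far below and y -> upper far above the midpoint;
#' decreasing transitions simply have upper < lower.
#'
#' @param x ordinate (denaturant in M or temperature in C), at least 5
#'   points spanning both plateaus.
#' @param y observable (signal, s20w in S, molar mass in kDa, ...).
#' @param init optional named list/vector with `lower`, `upper`,
#'   `midpoint`, `width` starting values.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return A `sigmoid_fit` object with `lower`, `upper`, `midpoint`,
#'   `width`, per-parameter `se`, `se_midpoint`, `residual_rms`,
#'   `converged`.
#' @export
fit_transition_midpoint <- function(x, y, init = NULL, maxiter = 200) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  if (length(x) < 5) .stopf("sigmoid fit needs at least 5 points")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not allowed")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  amp <- diff(range(y))
  if (amp <= .Machine$double.eps * max(1, max(abs(y))) * 10)
    .stopf("no transition detectable: y is flat")

  starts <- list()
  if (is.null(init)) {
    k <- max(1L, ceiling(0.1 * length(x)))
    lower0 <- mean(y[seq_len(k)])
    upper0 <- mean(y[seq.int(length(y) - k + 1L, length(y))])
    cross <- function(q) {
      target <- lower0 + q * (upper0 - lower0)
      idx <- if (upper0 >= lower0) which(y >= target) else which(y <= target)
      if (length(idx)) x[idx[1]] else stats::median(x)
    }
    mid0 <- cross(0.5)
    # 25-75% crossing distance sets the width scale (logistic: 2 ln 3 widths)
    w_cross <- max(abs(cross(0.75) - cross(0.25)) / (2 * log(3)),
                   1e-3 * diff(range(x)))
    for (w in unique(c(w_cross, diff(range(x)) / 10, diff(range(x)) / 50)))
      starts[[length(starts) + 1L]] <-
        list(lower = lower0, upper = upper0, midpoint = mid0, width = w)
  } else {
    starts[[1L]] <- init
  }
  # transitions narrower than the sampling cannot be resolved; keep the
  # width bounded away from the degenerate step fit
  lo <- c(-Inf, -Inf, min(x), 0.25 * stats::median(diff(x)))
  hi <- c(Inf, Inf, max(x), 10 * diff(range(x)))
  model <- function(p, xx)
    p[1] + (p[2] - p[1]) / (1 + exp((p[3] - xx) / p[4]))
  fit <- NULL
  for (s in starts) {
    p0 <- c(lower = s$lower, upper = s$upper,
            midpoint = s$midpoint, width = max(s$width, lo[4]))
    cand <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                               fn = function(p) y - model(p, x),
                               control = minpack.lm::nls.lm.control(maxiter = maxiter))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  converged <- fit$info %in% 1:4
  if (!converged) warning("sigmoid fit did not converge")
  p <- fit$par
  fitted <- model(p, x)
  rss <- sum((y - fitted)^2)
  sigma2 <- rss / max(length(x) - 4, 1)
  J <- .num_jacobian(function(th) model(th, x), p)
  covm <- .safe_cov(J, sigma2)
  se <- rep(NA_real_, 4)
  names(se) <- names(p0)
  if (!is.null(covm)) se[] <- sqrt(pmax(diag(covm), 0))

  # flag non-monotone data beyond what the residual noise explains
  dir <- sign(p[["upper"]] - p[["lower"]])
  steps <- diff(y)
  noise <- stats::mad(steps - stats::median(steps)) + 1e-12
  reversals <- sum(dir * steps < -4 * noise)
  if (reversals > length(y) / 5)
    warning("y is strongly non-monotone for a single logistic transition")

  structure(list(lower = p[["lower"]], upper = p[["upper"]],
                 midpoint = p[["midpoint"]], width = p[["width"]],
                 se = se, se_midpoint = se[["midpoint"]],
                 residual_rms = sqrt(rss / length(x)),
                 converged = converged, x = x, y = y, fitted = fitted),
            class = "sigmoid_fit")
}

#' Midpoint temperature from a thermal CD trace
#'
#' Fits the shared four-parameter logistic ([fit_transition_midpoint]) to a
#' thermal-unfolding CD curve and reports the midpoint as Tm_CD.
#'
#' @param curve data frame with columns `temp_C` and `signal` (mean residue
#'   ellipticity or delta-signal), or separate `temp_C`/`signal` vectors.
#' @param signal optional signal vector when `curve` is a temperature
#'   vector.
#' @return A `sigmoid_fit`; the midpoint is Tm_CD in C.
#' @export
fit_tm_sigmoid <- function(curve, signal = NULL) {
  if (is.data.frame(curve)) {
    if (!all(c("temp_C", "signal") %in% names(curve)))
      .stopf("curve needs columns temp_C and signal")
    fit_transition_midpoint(curve$temp_C, curve$signal)
  } else {
    fit_transition_midpoint(curve, signal)
  }
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Logistic transition fit\n")
  cat(sprintf("  midpoint = %.3f (SE %.3g), width = %.3f\n",
              x$midpoint, x$se_midpoint, x$width))
  cat(sprintf("  plateaus %.3f -> %.3f; residual RMS %.4g; converged: %s\n",
              x$lower, x$upper, x$residual_rms, x$converged))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...)
  c(lower = object$lower, upper = object$upper,
    midpoint = object$midpoint, width = object$width)

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x
        else if (is.numeric(newdata)) newdata else newdata[[1]]
  object$lower + (object$upper - object$lower) /
    (1 + exp((object$midpoint - xx) / object$width))
}

#' @export
residuals.sigmoid_fit <- function(object, ...) object$y - object$fitted

#' @export
fitted.sigmoid_fit <- function(object, ...) object$fitted

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y",
                 main = "Logistic transition", ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(v = x$midpoint, lty = 3)
  invisible(x)
}
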