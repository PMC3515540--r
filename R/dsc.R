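#' DSC thermogram
#'
#' A single differential scanning calorimetry scan: molar heat capacity
#' versus temperature at a constant scan rate.
#'
#' @param temp_C strictly increasing temperatures, C.
#' @param cp molar heat capacity, kcal/mol/K.
#' @param scan_rate_C_per_min positive scan rate (default 1.0 C/min).
#' @param scan_index ordinal of consecutive up/down scans (first scan = 1).
#' @return A `thermogram` object (data frame `temp_C`, `cp` with scan
#'   metadata attributes).
#' @export
thermogram <- function(temp_C, cp, scan_rate_C_per_min = 1, scan_index = 1L) {
  if (length(temp_C) != length(cp))
    .stopf("temp_C and cp must have the same length")
  if (length(temp_C) < 50)
    .stopf("a thermogram needs at least 50 points (got %d)", length(temp_C))
  if (any(diff(temp_C) <= 0)) .stopf("temp_C must be strictly increasing")
  if (scan_rate_C_per_min <= 0) .stopf("scan_rate_C_per_min must be positive")
  out <- data.frame(temp_C = as.numeric(temp_C), cp = as.numeric(cp))
  attr(out, "scan_rate_C_per_min") <- scan_rate_C_per_min
  attr(out, "scan_index") <- as.integer(scan_index)
  class(out) <- c("thermogram", "data.frame")
  out
}

.line_fit <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Subtract a chemical baseline from a DSC scan
#'
#' Fits straight lines through the pre- and post-transition temperature
#' ranges and subtracts a connection of the two: by default the lines are
#' blended with a progress weight equal to the cumulative normalized excess
#' heat (the standard sigmoidal baseline of calorimetry), refined by
#' fixed-point iteration; a linear chord between the range edges is
#' available as an option.
#'
#' @param t a [thermogram].
#' @param pre_range,post_range length-2 numeric, C: temperature intervals of
#'   the pre- and post-transition baselines. Each must contain at least 5
#'   scan points and the intervals must not overlap.
#' @param method `"progress"` (default) or `"chord"`.
#' @param iterations fixed-point refinements of the progress weight.
#' @return A [thermogram] of excess heat capacity (same grid); the fitted
#'   baseline is attached as attribute `"baseline"`.
#' @export
subtract_baseline <- function(t, pre_range, post_range,
                              method = c("progress", "chord"),
                              iterations = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(t, "thermogram"))
  pre_range <- sort(pre_range); post_range <- sort(post_range)
  if (pre_range[2] >= post_range[1])
    .stopf("pre_range and post_range must not overlap")
  tc <- t$temp_C
  if (pre_range[1] < min(tc) - 1e-9 || post_range[2] > max(tc) + 1e-9)
    .stopf("baseline ranges fall outside the scan (%.2f-%.2f C)",
           min(tc), max(tc))
  in_pre <- tc >= pre_range[1] & tc <= pre_range[2]
  in_post <- tc >= post_range[1] & tc <= post_range[2]
  if (sum(in_pre) < 5 || sum(in_post) < 5)
    .stopf("each baseline range must contain at least 5 points")
  pre <- .line_fit(tc[in_pre], t$cp[in_pre])
  post <- .line_fit(tc[in_post], t$cp[in_post])
  pre_y <- pre["intercept"] + pre["slope"] * tc
  post_y <- post["intercept"] + post["slope"] * tc

  # initial progress: linear ramp across the transition window
  alpha <- pmin(pmax((tc - pre_range[2]) / (post_range[1] - pre_range[2]), 0), 1)
  if (method == "progress") {
    for (i in seq_len(iterations)) {
      base <- (1 - alpha) * pre_y + alpha * post_y
      ex <- pmax(t$cp - base, 0)
      cum <- cumsum(c(0, diff(tc) * (ex[-1] + ex[-length(ex)]) / 2))
      total <- cum[length(cum)]
      if (total <= 0) break  # no excess heat: keep ramp connection
      alpha <- cum / total
    }
  }
  base <- (1 - alpha) * pre_y + alpha * post_y
  out <- thermogram(tc, t$cp - base,
                    scan_rate_C_per_min = attr(t, "scan_rate_C_per_min"),
                    scan_index = attr(t, "scan_index"))
  attr(out, "baseline") <- data.frame(temp_C = tc, baseline = base)
  attr(out, "baseline_lines") <- list(pre = pre, post = post, method = method)
  out
}

#' Calorimetric enthalpy by peak integration
#'
#' Trapezoidal integral of the excess heat capacity over a temperature
#' window, i.e. the apparent calorimetric enthalpy of the transition under
#' the peak.
#'
#' @param excess an excess-heat-capacity [thermogram] (baseline already
#'   subtracted).
#' @param t_lo,t_hi integration window, C; must lie inside the scan range.
#' @return Enthalpy in kcal/mol.
#' @export
integrate_dHcal <- function(excess, t_lo, t_hi) {
  stopifnot(inherits(excess, "thermogram"))
  if (t_hi <= t_lo) .stopf("empty integration window")
  tc <- excess$temp_C
  if (t_lo < min(tc) - 1e-9 || t_hi > max(tc) + 1e-9)
    .stopf("integration window [%.2f, %.2f] outside scan range [%.2f, %.2f]",
           t_lo, t_hi, min(tc), max(tc))
  keep <- tc >= t_lo & tc <= t_hi
  if (sum(keep) < 2) .stopf("integration window contains fewer than 2 points")
  x <- tc[keep]; y <- excess$cp[keep]
  # close the window exactly by interpolating the edges
  if (x[1] > t_lo) {
    y <- c(stats::approx(tc, excess$cp, t_lo)$y, y); x <- c(t_lo, x)
  }
  if (x[length(x)] < t_hi) {
    y <- c(y, stats::approx(tc, excess$cp, t_hi)$y); x <- c(x, t_hi)
  }
  .trapz(x, y)
}

#' Single-transition parameters
#'
#' One unfolding transition of a non-two-state DSC deconvolution: midpoint
#' temperature, calorimetric (area) enthalpy and van't Hoff (shape)
#' enthalpy.
#'
#' @param Tm_C midpoint temperature, C.
#' @param dH_cal calorimetric enthalpy, kcal/mol, positive.
#' @param dH_vH van't Hoff enthalpy, kcal/mol, positive; defaults to
#'   `dH_cal` (two-state shape).
#' @return A `transition_fit` list.
#' @export
transition_fit <- function(Tm_C, dH_cal, dH_vH = dH_cal) {
  if (dH_cal <= 0 || dH_vH <= 0) .stopf("transition enthalpies must be positive")
  structure(list(Tm_C = Tm_C, dH_cal = dH_cal, dH_vH = dH_vH),
            class = "transition_fit")
}

#' Excess heat capacity of one two-state transition
#'
#' The independent-transition excess heat capacity used for non-two-state
#' deconvolution: with K(T) = exp(-(dH_vH/R) (1/T - 1/Tm)), the
#' contribution is Cp(T) = dH_cal dH_vH / (R T^2) * K/(1+K)^2. Its integral
#' over temperature is dH_cal; its shape (peak width) is set by dH_vH.
#'
#' @param temp_C temperature(s), C.
#' @param tr a [transition_fit].
#' @return Excess heat capacity, kcal/mol/K (vectorized over `temp_C`).
#' @export
two_state_excess_cp <- function(temp_C, tr) {
  Tk <- .C_to_K(temp_C)
  if (any(Tk <= 0)) .stopf("temperature must be above 0 K")
  Tm <- .C_to_K(tr$Tm_C)
  lK <- -(tr$dH_vH / Rgas_kcal) * (1 / Tk - 1 / Tm)
  # K/(1+K)^2 computed stably as exp(lK)/(1+exp(lK))^2
  w <- ifelse(abs(lK) > 700, 0, exp(lK) / (1 + exp(lK))^2)
  tr$dH_cal * tr$dH_vH / (Rgas_kcal * Tk^2) * w
}

.sum_transitions <- function(temp_C, transitions) {
  out <- numeric(length(temp_C))
  for (tr in transitions) out <- out + two_state_excess_cp(temp_C, tr)
  out
}

.smooth_cp <- function(cp, n_pts) {
  k <- max(3L, round(n_pts / 50))
  sm <- stats::filter(cp, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- cp[is.na(sm)]
  as.numeric(sm)
}

# one transition guessed from a trace: peak position/height plus area
.guess_transition <- function(tc, cp) {
  sm <- .smooth_cp(cp, length(tc))
  i <- which.max(sm)
  h <- max(sm[i], 1e-6)
  area <- max(.trapz(tc, pmax(cp, 0)), 1e-3)
  Tm <- tc[i]
  dH_vH <- min(max(4 * Rgas_kcal * .C_to_K(Tm)^2 * h / area, 10), 1000)
  transition_fit(Tm, area, dH_vH)
}

.lm_fit_sum <- function(tc, cp, trs, constrain_vh, maxiter = 100) {
  per <- if (constrain_vh) 2L else 3L
  n <- length(trs)
  p0 <- unlist(lapply(trs, function(tr)
    if (constrain_vh) c(tr$Tm_C, tr$dH_cal) else c(tr$Tm_C, tr$dH_cal, tr$dH_vH)))
  unpack <- function(par) lapply(seq_len(n), function(i) {
    b <- (i - 1L) * per
    if (constrain_vh) transition_fit(par[b + 1], max(par[b + 2], 1e-6))
    else transition_fit(par[b + 1], max(par[b + 2], 1e-6), max(par[b + 3], 1e-6))
  })
  lo <- rep(if (constrain_vh) c(min(tc), 0.5) else c(min(tc), 0.5, 5), n)
  hi <- rep(if (constrain_vh) c(max(tc), 5000) else c(max(tc), 5000, 2000), n)
  fit <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                            fn = function(p) cp - .sum_transitions(tc, unpack(p)),
                            control = minpack.lm::nls.lm.control(maxiter = maxiter))
  list(fit = fit, transitions = unpack(fit$par))
}

# sequential-peeling initialization: fit k transitions, seed transition
# k+1 from the largest positive residual peak, refit jointly
.init_dsc <- function(tc, cp, n, constrain_vh) {
  trs <- list(.guess_transition(tc, cp))
  trs <- .lm_fit_sum(tc, cp, trs, constrain_vh)$transitions
  while (length(trs) < n) {
    res <- cp - .sum_transitions(tc, trs)
    trs <- c(trs, list(.guess_transition(tc, pmax(res, 0))))
    trs <- .lm_fit_sum(tc, cp, trs, constrain_vh)$transitions
  }
  trs
}

#' Deconvolve a DSC excess heat-capacity scan
#'
#' Least-squares fit of a sum of independent two-state transitions
#' ([two_state_excess_cp]) to an excess heat-capacity thermogram (the
#' "non-two-state" model: per-transition calorimetric and van't Hoff
#' enthalpies). Transitions are returned sorted by ascending Tm.
#'
#' @param excess excess-heat-capacity [thermogram] (baseline already
#'   removed, e.g. by [subtract_baseline]).
#' @param n_transitions number of transitions, 1 to 3.
#' @param init optional list of [transition_fit] starting values.
#' @param constrain_vh if `TRUE`, fix dH_vH = dH_cal per transition
#'   (two-state shape constraint); default `FALSE` (free van't Hoff
#'   enthalpy).
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return A `dsc_fit` object: `transitions` (list of [transition_fit],
#'   Tm-ascending), `se` (matrix of standard errors), `residual_rms`,
#'   `converged`.
#' @export
fit_dsc <- function(excess, n_transitions = 2L, init = NULL,
                    constrain_vh = FALSE, maxiter = 300) {
  stopifnot(inherits(excess, "thermogram"))
  if (!n_transitions %in% 1:3)
    .stopf("n_transitions must be 1, 2 or 3 (got %s)", n_transitions)
  n <- as.integer(n_transitions)
  tc <- excess$temp_C; cp <- excess$cp
  if (is.null(init)) init <- .init_dsc(tc, cp, n, constrain_vh)
  if (length(init) != n) .stopf("init must supply %d transitions", n)

  per <- if (constrain_vh) 2L else 3L
  res <- .lm_fit_sum(tc, cp, init, constrain_vh, maxiter = maxiter)
  fit <- res$fit
  converged <- fit$info %in% 1:4
  if (!converged)
    warning(sprintf("DSC fit did not converge (nls.lm info %d); residual RMS %.4g",
                    fit$info, sqrt(fit$deviance / length(tc))))
  trs <- res$transitions
  ord <- order(vapply(trs, `[[`, numeric(1), "Tm_C"))
  trs <- trs[ord]
  fitted <- .sum_transitions(tc, trs)
  rss <- sum((cp - fitted)^2)
  n_par <- n * per
  sigma2 <- rss / max(length(tc) - n_par, 1)
  pack <- function(x) unlist(lapply(x, function(tr)
    if (constrain_vh) c(tr$Tm_C, tr$dH_cal) else c(tr$Tm_C, tr$dH_cal, tr$dH_vH)))
  unpack <- function(par) lapply(seq_len(n), function(i) {
    b <- (i - 1L) * per
    if (constrain_vh) transition_fit(par[b + 1], par[b + 2])
    else transition_fit(par[b + 1], par[b + 2], par[b + 3])
  })
  J <- .num_jacobian(function(p) .sum_transitions(tc, unpack(p)), pack(trs))
  covm <- .safe_cov(J, sigma2)
  se <- matrix(NA_real_, n, 3,
               dimnames = list(NULL, c("Tm_C", "dH_cal", "dH_vH")))
  if (!is.null(covm)) {
    s <- sqrt(pmax(diag(covm), 0))
    for (i in seq_len(n)) {
      b <- (i - 1L) * per
      se[i, "Tm_C"] <- s[b + 1]
      se[i, "dH_cal"] <- s[b + 2]
      se[i, "dH_vH"] <- if (constrain_vh) s[b + 2] else s[b + 3]
    }
  }
  tms <- vapply(trs, `[[`, numeric(1), "Tm_C")
  if (n > 1 && any(diff(tms) < 1))
    warning("fitted transitions are separated by less than 1 C; deconvolution may be unreliable")
  structure(list(transitions = trs, se = se,
                 residual_rms = sqrt(rss / length(tc)),
                 converged = converged, constrain_vh = constrain_vh,
                 excess = excess, fitted = fitted, n = length(tc)),
            class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, ...) {
  cat(sprintf("DSC deconvolution: %d transition(s), dH_vH %s\n",
              length(x$transitions),
              if (x$constrain_vh) "constrained to dH_cal" else "free"))
  for (i in seq_along(x$transitions)) {
    tr <- x$transitions[[i]]
    cat(sprintf("  %d: Tm = %.2f C (SE %.2g), dH_cal = %.1f kcal/mol (SE %.2g), dH_vH = %.1f\n",
                i, tr$Tm_C, x$se[i, "Tm_C"], tr$dH_cal, x$se[i, "dH_cal"],
                tr$dH_vH))
  }
  cat(sprintf("  residual RMS = %.4g kcal/mol/K; converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
coef.dsc_fit <- function(object, ...) {
  m <- t(vapply(object$transitions,
                function(tr) c(Tm_C = tr$Tm_C, dH_cal = tr$dH_cal,
                               dH_vH = tr$dH_vH),
                numeric(3)))
  rownames(m) <- paste0("transition", seq_len(nrow(m)))
  m
}

#' @export
summary.dsc_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), se = object$se,
              residual_rms = object$residual_rms,
              converged = object$converged)
  class(out) <- "summary.dsc_fit"
  out
}

#' @export
print.summary.dsc_fit <- function(x, ...) {
  cat("DSC deconvolution\n")
  print(round(x$coefficients, 3))
  cat("standard errors:\n")
  print(signif(x$se, 3))
  cat(sprintf("residual RMS %.4g kcal/mol/K; converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
predict.dsc_fit <- function(object, newdata = NULL, ...) {
  tc <- if (is.null(newdata)) object$excess$temp_C
        else if (is.numeric(newdata)) newdata else newdata$temp_C
  .sum_transitions(tc, object$transitions)
}

#' @export
fitted.dsc_fit <- function(object, ...) object$fitted

#' @export
residuals.dsc_fit <- function(object, ...) object$excess$cp - object$fitted

#' @export
plot.dsc_fit <- function(x, ...) {
  tc <- x$excess$temp_C
  graphics::plot(tc, x$excess$cp, type = "l", xlab = "temperature (C)",
                 ylab = "excess Cp (kcal/mol/K)", main = "DSC deconvolution",
                 ...)
  graphics::lines(tc, x$fitted, col = 2)
  for (tr in x$transitions)
    graphics::lines(tc, two_state_excess_cp(tc, tr), lty = 2, col = 4)
  invisible(x)
}

#' Reversibility of consecutive DSC scans
#'
#' Ratio of the excess-heat areas of a rescan to a first scan over their
#' shared temperature window. A transition is classified reversible when
#' the rescan retains at least `threshold` (default 95%) of the first-scan
#' area.
#'
#' @param scan1,scan2 excess-heat-capacity [thermogram]s of consecutive
#'   scans.
#' @param threshold reversibility acceptance threshold (fraction).
#' @return List with `fraction` (area ratio, >= 0), `reversible` (logical)
#'   and `threshold`.
#' @export
reversibility_fraction <- function(scan1, scan2, threshold = 0.95) {
  stopifnot(inherits(scan1, "thermogram"), inherits(scan2, "thermogram"))
  lo <- max(min(scan1$temp_C), min(scan2$temp_C))
  hi <- min(max(scan1$temp_C), max(scan2$temp_C))
  if (hi <= lo) .stopf("scans have no overlapping temperature range")
  a1 <- integrate_dHcal(scan1, lo, hi)
  a2 <- integrate_dHcal(scan2, lo, hi)
  if (a1 <= 0) .stopf("first-scan excess heat area is not positive")
  frac <- a2 / a1
  list(fraction = frac, reversible = frac >= threshold, threshold = threshold)
}
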