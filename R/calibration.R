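# Fluorescence calibration: pseudo-sigmoidal signal model, nonlinear fit to
# serial dilutions, and safeguarded inversion back to normalized
# concentration C' (C' = 1 at the frozen 0 h stock).

#' Construct a calibration fit object
#'
#' Pseudo-sigmoidal signal model with the floor fixed at the measured
#' background:
#'
#'   signal(C') = alpha + (beta - alpha) * C'^gamma / (delta^gamma + C'^gamma)
#'
#' alpha is the background fluorescence (held fixed, never fitted); beta is
#' the saturation plateau; delta the half-saturation concentration; gamma the
#' slope of the transition in log-dilution space. The functional form sits
#' behind the forward/invert interface, so callers never depend on it.
#'
#' @param alpha Background signal (instrument units).
#' @param beta,gamma,delta Shape parameters (beta > alpha, gamma > 0,
#'   delta > 0).
#' @param r_squared Quality of fit (set by [fit_calibration()]).
#' @param valid_range Concentration range over which inversion is defined.
#' @param r2_threshold Usability gate on r_squared.
#' @param wavelength_pair Optional metadata label, e.g. "501/521".
#' @return Object of class `calibration_fit`.
#' @export
calibration_fit <- function(alpha, beta, gamma, delta, r_squared = NA_real_,
                            valid_range = c(0, Inf), r2_threshold = 0.999,
                            wavelength_pair = NA_character_) {
  if (beta <= alpha) stop("plateau beta must exceed background alpha")
  if (gamma <= 0 || delta <= 0) stop("gamma and delta must be > 0")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
         r_squared = r_squared, valid_range = valid_range,
         r2_threshold = r2_threshold,
         usable = is.na(r_squared) || r_squared >= r2_threshold,
         wavelength_pair = wavelength_pair),
    class = "calibration_fit"
  )
}

#' Forward calibration model
#'
#' @param c_norm Normalized concentration C' >= 0 (vectorised).
#' @param fit A [calibration_fit()].
#' @return Predicted signal; equals `fit$alpha` at C' = 0, monotone
#'   non-decreasing, saturating at `fit$beta`.
#' @export
forward_signal <- function(c_norm, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(c_norm < 0)) stop("c_norm must be >= 0")
  with(fit, alpha + (beta - alpha) * c_norm^gamma / (delta^gamma + c_norm^gamma))
}

#' Fit the calibration model to a serial dilution series
#'
#' Least-squares fit of beta, gamma, delta with alpha held fixed at the
#' measured background, via Levenberg-Marquardt. The dilution series must
#' bracket the usable range: at least 5 points including a blank (C' = 0)
#' and the undiluted stock (C' = 1). The fit is flagged unusable when
#' r_squared falls below `r2_threshold` (default 0.999, the quality-of-fit
#' level the model form was selected for).
#'
#' @param c_norm,signal Dilution series: normalized concentrations and
#'   measured signals (same length).
#' @param alpha Background signal (fixed).
#' @param r2_threshold Usability gate (default 0.999).
#' @param wavelength_pair Optional metadata label.
#' @return A [calibration_fit()] with `r_squared` and `valid_range` set.
#' @export
fit_calibration <- function(c_norm, signal, alpha, r2_threshold = 0.999,
                            wavelength_pair = NA_character_) {
  if (length(c_norm) != length(signal)) stop("c_norm and signal lengths differ")
  if (length(c_norm) < 5) stop("need at least 5 dilution points")
  if (!any(c_norm == 0)) stop("dilution series must include a blank (C' = 0)")
  if (!any(c_norm == 1)) stop("dilution series must include the stock (C' = 1)")
  if (stats::sd(signal) == 0) {
    stop("constant signals: calibration cannot converge (flat curve)")
  }

  df <- data.frame(c_norm = c_norm, signal = signal)
  start <- list(beta = max(signal) * 1.05,
                gamma = 1,
                delta = stats::median(c_norm[c_norm > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ alpha + (beta - alpha) * c_norm^gamma /
        (delta^gamma + c_norm^gamma),
      data = df, start = start,
      lower = c(beta = alpha + .Machine$double.eps, gamma = 1e-6,
                delta = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("calibration fit did not converge: ", conditionMessage(e))
    }
  )
  est <- stats::coef(fit)
  resid <- df$signal - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$signal - mean(df$signal))^2)
  calibration_fit(alpha = alpha, beta = est[["beta"]], gamma = est[["gamma"]],
                  delta = est[["delta"]], r_squared = r2,
                  valid_range = c(0, max(c_norm)),
                  r2_threshold = r2_threshold,
                  wavelength_pair = wavelength_pair)
}

#' Invert a signal to normalized concentration
#'
#' Safeguarded bracketed root finding on the forward model (never algebraic,
#' so the model form can change without touching callers). Signals at or
#' below the background map to 0 and carry a `censored` attribute; signals at
#' or above the saturation plateau are an error.
#'
#' @param signal Measured signal (scalar).
#' @param fit A [calibration_fit()].
#' @param tol Relative convergence tolerance (default 1e-12).
#' @return Normalized concentration C'; attribute `censored` is TRUE when the
#'   signal fell below background.
#' @export
invert_to_concentration <- function(signal, fit, tol = 1e-12) {
  stopifnot(inherits(fit, "calibration_fit"), length(signal) == 1)
  if (signal <= fit$alpha) {
    out <- 0
    attr(out, "censored") <- signal < fit$alpha
    return(out)
  }
  if (signal >= fit$beta) {
    stop("signal at or above the saturation plateau: outside invertible range")
  }
  upper <- if (is.finite(fit$valid_range[2])) max(fit$valid_range[2], 1) else 1
  # expand the bracket if the signal lies beyond the calibrated range
  while (forward_signal(upper, fit) < signal && upper < 1e12) upper <- upper * 2
  if (forward_signal(upper, fit) < signal) {
    stop("signal not reachable within the invertible range")
  }
  root <- stats::uniroot(function(c) forward_signal(c, fit) - signal,
                         interval = c(0, upper), tol = tol * max(upper, 1))
  out <- root$root
  attr(out, "censored") <- FALSE
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> alpha=%.4g beta=%.4g gamma=%.4g delta=%.4g R2=%s%s\n",
    x$alpha, x$beta, x$gamma, x$delta,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.5f", x$r_squared)),
    if (!x$usable) " [UNUSABLE: below quality gate]" else ""))
  invisible(x)
}
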