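#' Ultrasound pulse parameters
#'
#' Stimulus pulse description: negative peak pressure (MPa), center frequency
#' (MHz), pulse duration (ms) and repetition period (s). The duty cycle is
#' derived as duration/period and must lie in (0, 1]. The default matches the
#' standard stimulation sequence: a 10-ms pulse every 6 s.
#'
#' @param npp Negative peak pressure (MPa).
#' @param f Center frequency (MHz).
#' @param duration_ms Pulse duration (ms).
#' @param period_s Repetition period (s).
#' @return An object of class `pulse_params`.
#' @export
pulse_params <- function(npp, f, duration_ms = 10, period_s = 6) {
  stopifnot(npp > 0, f > 0, duration_ms > 0, period_s > 0)
  duty <- (duration_ms / 1000) / period_s
  if (duty > 1) stop("duty cycle > 1: duration exceeds the repetition period")
  structure(list(npp = npp, f = f, duration_ms = duration_ms,
                 period_s = period_s, duty = duty), class = "pulse_params")
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf("<pulse_params> NPP = %g MPa, f = %g MHz, %g ms / %g s (duty %.4g)\n",
              x$npp, x$f, x$duration_ms, x$period_s, x$duty))
  invisible(x)
}

#' Mechanical index
#'
#' MI = NPP(MPa) / sqrt(f(MHz)), the standard cavitation-risk proxy.
#'
#' @param pulse A [pulse_params()].
#' @return MI (dimensionless).
#' @export
mechanical_index <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_params"))
  pulse$npp / sqrt(pulse$f)
}

#' Spatial-peak intensities
#'
#' I_SPPA = NPP^2 / (2 rho c) reported in W/cm^2, and
#' I_SPTA = I_SPPA x duty cycle, reported in mW/cm^2.
#'
#' @param pulse A [pulse_params()].
#' @param medium A [medium_props()].
#' @return Named list with `isppa_W_cm2` and `ispta_mW_cm2`.
#' @export
intensities <- function(pulse, medium = water_medium()) {
  stopifnot(inherits(pulse, "pulse_params"), inherits(medium, "medium_props"))
  isppa_W_m2 <- (pulse$npp * 1e6)^2 / (2 * medium$rho * medium$c)
  isppa <- isppa_W_m2 / 1e4
  list(isppa_W_cm2 = isppa, ispta_mW_cm2 = isppa * pulse$duty * 1000)
}

#' Thermal index at the retina
#'
#' Soft-tissue small-aperture form: TI = min(W, I_SPTA x 1 cm^2) * f / 210,
#' with W the derated acoustic power in mW, I_SPTA in mW/cm^2 and f in MHz
#' (the 210 mW MHz denominator implies the frequency factor). The selected
#' min-branch is reported alongside the value.
#'
#' @param W_mW Derated acoustic power (mW).
#' @param ispta_mW_cm2 Spatial-peak temporal-average intensity (mW/cm^2).
#' @param f Center frequency (MHz).
#' @return List with `ti` and `branch` ("power" or "intensity").
#' @export
thermal_index <- function(W_mW, ispta_mW_cm2, f) {
  stopifnot(W_mW >= 0, ispta_mW_cm2 >= 0, f > 0)
  m <- min(W_mW, ispta_mW_cm2 * 1)
  list(ti = m * f / 210,
       branch = if (W_mW <= ispta_mW_cm2) "power" else "intensity")
}

#' Acoustic radiation force per unit volume
#'
#' F = p^2 alpha f / (rho c^2) in N/m^3: the body force produced by momentum
#' transfer of the attenuated wave, the inferred mechanism of retinal
#' activation. Linear in alpha and f, quadratic in p.
#'
#' @param p Acoustic pressure (Pa).
#' @param alpha Attenuation coefficient at 1 MHz (Np m^-1 MHz^-1).
#' @param f Center frequency (MHz).
#' @param medium A [medium_props()].
#' @return Force per unit volume (N/m^3).
#' @export
arf_force <- function(p, alpha, f, medium = water_medium()) {
  stopifnot(all(p >= 0), alpha >= 0, f > 0)
  p^2 * (alpha * f) / (medium$rho * medium$c^2)
}

#' Fit the frequency-threshold activation curve
#'
#' Least-squares fit of the power law p = a f^b to activation-threshold
#' pressures. `model = "inverse"` fixes b = -1 (pressure threshold inversely
#' proportional to frequency); `model = "free"` estimates b as well (>= 3
#' points required). A constant radiation-force threshold under F =
#' p^2 alpha f / (rho c^2) predicts b = -1/2, which `model = "arf"` fixes.
#' RMSE is reported in pressure units over the data.
#'
#' @param freqs Frequencies (MHz), distinct, positive.
#' @param thresholds Threshold pressures (MPa).
#' @param model "inverse" (b = -1), "arf" (b = -1/2) or "free".
#' @return Object of class `threshold_fit` with `a`, `b`, `rmse`, `fitted`,
#'   `model` and the data.
#' @export
fit_threshold_curve <- function(freqs, thresholds, model = c("inverse", "arf", "free")) {
  model <- match.arg(model)
  stopifnot(length(freqs) == length(thresholds), length(freqs) >= 2,
            all(freqs > 0), all(thresholds > 0),
            length(unique(freqs)) == length(freqs))
  if (model == "free") {
    if (length(freqs) < 3) stop("free-exponent model needs >= 3 points")
    lg <- stats::lm(log(thresholds) ~ log(freqs))
    st <- list(a = exp(stats::coef(lg)[[1]]), b = stats::coef(lg)[[2]])
    # Levenberg-Marquardt: robust to the zero-residual case where nls's
    # relative-offset criterion fails
    fit <- minpack.lm::nlsLM(thresholds ~ a * freqs^b, start = st)
    a <- stats::coef(fit)[["a"]]; b <- stats::coef(fit)[["b"]]
  } else {
    b <- if (model == "inverse") -1 else -0.5
    x <- freqs^b
    a <- sum(thresholds * x) / sum(x^2)   # no-intercept LS
  }
  fitted <- a * freqs^b
  structure(list(a = a, b = b, rmse = sqrt(mean((thresholds - fitted)^2)),
                 fitted = fitted, freqs = freqs, thresholds = thresholds,
                 model = model),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> p = %.4g * f^%.4g (%s model), RMSE = %.4g MPa on %d points\n",
              x$a, x$b, x$model, x$rmse, length(x$freqs)))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.threshold_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$freqs else
    if (is.list(newdata)) newdata$freqs else as.numeric(newdata)
  object$a * f^object$b
}

#' All exposure metrics for a pulse
#'
#' Convenience wrapper returning MI, I_SPPA, I_SPTA, TI and the ARF body
#' force at the focal pressure in one list.
#'
#' @param pulse A [pulse_params()].
#' @param medium A [medium_props()].
#' @param W_mW Derated acoustic power for the TI (mW).
#' @param alpha_tissue Tissue attenuation for the ARF (Np/m/MHz); default the
#'   retina-like 5 Np/m/MHz.
#' @return Named list of class `exposure_metrics`.
#' @export
exposure_metrics <- function(pulse, medium = water_medium(), W_mW = 5,
                             alpha_tissue = 5) {
  ii <- intensities(pulse, medium)
  ti <- thermal_index(W_mW, ii$ispta_mW_cm2, pulse$f)
  structure(list(mi = mechanical_index(pulse),
                 isppa_W_cm2 = ii$isppa_W_cm2,
                 ispta_mW_cm2 = ii$ispta_mW_cm2,
                 ti = ti$ti, ti_branch = ti$branch,
                 arf_N_m3 = arf_force(pulse$npp * 1e6, alpha_tissue, pulse$f, medium),
                 W_mW = W_mW),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf(paste0("<exposure_metrics> MI = %.3f, ISPPA = %.2f W/cm^2, ",
                     "ISPTA = %.2f mW/cm^2, TI = %.4f (%s branch), ARF = %.3g N/m^3\n"),
              x$mi, x$isppa_W_cm2, x$ispta_mW_cm2, x$ti, x$ti_branch, x$arf_N_m3))
  invisible(x)
}
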