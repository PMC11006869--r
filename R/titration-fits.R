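#' Sub-grid absorption maximum of a spectrum
#'
#' Locates the peak wavelength by parabolic interpolation through the
#' maximum sample and its two neighbours, giving sub-grid-step resolution
#' (e.g. a 535.5 nm maximum on a 1 nm grid).
#'
#' @param spectrum Tibble with columns `wavelength` (increasing, nm) and
#'   `absorbance`.
#' @param window Length-2 wavelength window, default the full range.
#' @return Peak wavelength (nm). If the maximum sample sits on the window
#'   edge a warning is raised and attribute `"edge"` is set.
#' @export
lambda_max <- function(spectrum, window = range(spectrum$wavelength)) {
  stopifnot(all(c("wavelength", "absorbance") %in% names(spectrum)))
  s <- spectrum[spectrum$wavelength >= window[1] &
                  spectrum$wavelength <= window[2], ]
  if (nrow(s) < 3) abort("window must contain at least 3 samples")
  i <- which.max(s$absorbance)
  if (i == 1 || i == nrow(s)) {
    warn("spectral maximum at window edge; no interpolation possible")
    return(structure(s$wavelength[i], edge = TRUE))
  }
  x <- s$wavelength[(i - 1):(i + 1)]; y <- s$absorbance[(i - 1):(i + 1)]
  # vertex of the parabola through three samples
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  structure(-b / (2 * a), edge = FALSE)
}

#' Normalize a spectrum to the absorbance at 280 nm
#'
#' @param spectrum Tibble with `wavelength`, `absorbance`; 280 nm must be
#'   within range (value linearly interpolated).
#' @return The spectrum scaled so A(280 nm) = 1; attribute `"factor"`
#'   holds the applied scale factor.
#' @export
normalize_at_280 <- function(spectrum) {
  a280 <- approx(spectrum$wavelength, spectrum$absorbance, xout = 280)$y
  if (is.na(a280)) abort("280 nm outside the spectral range")
  if (a280 == 0) abort("A(280 nm) is zero; scale undefined")
  out <- dplyr::mutate(spectrum, absorbance = .data$absorbance / a280)
  attr(out, "factor") <- 1 / a280
  out
}

multi_pka_model <- function(pH, pka, amp, baseline) {
  y <- rep(baseline, length(pH))
  for (k in seq_along(pka)) y <- y + amp[k] / (1 + 10^(pH - pka[k]))
  y
}

#' Fit a multi-pKa (Henderson-Hasselbalch) titration curve
#'
#' Least-squares fit of
#' `y(pH) = baseline + sum_k A_k / (1 + 10^(pH - pKa_k))`,
#' with starting pKa values from a scan of the numerical derivative
#' (inflection scan). Transitions contribute toward low pH (protonation-
#' increasing), amplitude signs free. Parameter uncertainties come from the
#' local curvature of the objective (covariance of the nls fit).
#'
#' @param curve Tibble with columns `pH` and `observable` (e.g. lambda-max
#'   in nm, or normalized absorbance); needs at least
#'   `2 * n_transitions + 2` points.
#' @param n_transitions Number of protonation transitions to fit.
#' @return Object of class `pka_fit` with sorted pKa values, amplitudes,
#'   baseline, standard errors, residual RMS and a `converged` flag.
#' @export
fit_multi_pka <- function(curve, n_transitions = 2) {
  stopifnot(all(c("pH", "observable") %in% names(curve)))
  curve <- dplyr::arrange(curve, .data$pH)
  if (nrow(curve) < 2 * n_transitions + 2) abort("too few points for the requested transitions")
  pH <- curve$pH; y <- curve$observable
  # inflection scan: steepest |dy/dpH| midpoints, kept mutually >= 0.8 pH apart
  mid <- (pH[-1] + pH[-length(pH)]) / 2
  dy <- abs(diff(y) / diff(pH))
  ord <- order(-dy)
  guesses <- numeric(0)
  for (i in ord) {
    if (all(abs(mid[i] - guesses) >= 0.8)) guesses <- c(guesses, mid[i])
    if (length(guesses) == n_transitions) break
  }
  if (length(guesses) < n_transitions) {
    guesses <- quantile(pH, probs = seq(0.2, 0.8, length.out = n_transitions))
  }
  guesses <- sort(unname(guesses))
  base0 <- y[length(y)]
  amp_tot <- y[1] - base0
  # keep the start strictly off the endpoint-interpolating values: an
  # exactly endpoint-matching start can degenerate the nls model matrix
  start <- c(setNames(guesses, paste0("pka", seq_len(n_transitions))),
             setNames(rep(amp_tot * 1.001 / n_transitions, n_transitions),
                      paste0("A", seq_len(n_transitions))),
             baseline = base0 + 1e-3 * amp_tot)
  form <- paste0("observable ~ ",
                 paste(sprintf("A%d / (1 + 10^(pH - pka%d))",
                               seq_len(n_transitions), seq_len(n_transitions)),
                       collapse = " + "),
                 " + baseline")
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form), data = curve, start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE,
                          diagnostics = conditionMessage(fit),
                          n_transitions = n_transitions, data = curve),
                     class = "pka_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  ord_k <- order(est[paste0("pka", seq_len(n_transitions))])
  co <- tibble(
    term = c(paste0("pKa", seq_len(n_transitions)),
             paste0("A", seq_len(n_transitions)), "baseline"),
    estimate = c(est[paste0("pka", seq_len(n_transitions))][ord_k],
                 est[paste0("A", seq_len(n_transitions))][ord_k],
                 est["baseline"]),
    std_error = c(se[paste0("pka", seq_len(n_transitions))][ord_k],
                  se[paste0("A", seq_len(n_transitions))][ord_k],
                  se["baseline"]))
  structure(list(converged = TRUE, coefficients = co,
                 pka = unname(co$estimate[seq_len(n_transitions)]),
                 amplitudes = unname(co$estimate[n_transitions + seq_len(n_transitions)]),
                 baseline = unname(est["baseline"]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit, n_transitions = n_transitions, data = curve),
            class = "pka_fit")
}

#' Fit the Hill equation
#'
#' Least-squares fit of `y = y_max c^n / (K^n + c^n)` with the Hill
#' coefficient free (initialized at 1); yields the half-saturation
#' constant, e.g. the sodium dependence of the O-intermediate amplitude.
#'
#' @param data Tibble with columns `conc` (>= 4 values spanning the
#'   half-saturation) and `amplitude`.
#' @return Object of class `hill_fit`: `K_half`, `n_hill`, `y_max`,
#'   standard errors, residual RMS.
#' @export
fit_hill <- function(data) {
  stopifnot(all(c("conc", "amplitude") %in% names(data)))
  if (nrow(data) < 4) abort("need at least 4 concentrations")
  if (length(unique(data$amplitude)) == 1) abort("all amplitudes equal; Hill fit undefined")
  ymax0 <- max(data$amplitude)
  K0 <- data$conc[which.min(abs(data$amplitude - ymax0 / 2))]
  if (K0 <= 0) K0 <- median(data$conc[data$conc > 0])
  fit <- minpack.lm::nlsLM(
    amplitude ~ y_max * conc^n / (K^n + conc^n), data = data,
    start = list(K = K0, n = 1, y_max = ymax0),
    lower = c(K = 1e-12, n = 1e-3, y_max = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(K_half = unname(est["K"]), n_hill = unname(est["n"]),
                 y_max = unname(est["y_max"]),
                 coefficients = tibble(term = c("K_half", "n_hill", "y_max"),
                                       estimate = unname(est[c("K", "n", "y_max")]),
                                       std_error = unname(se)),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit, data = data, converged = TRUE),
            class = "hill_fit")
}

#' Monoexponential decay fit
#'
#' Fits `I(t) = A exp(-t / t_off) + C` to a decaying segment (e.g.
#' photocurrent decay after light-off); initialization by log-linear
#' regression on the offset-corrected signal. Non-decaying or offset-only
#' data yield `converged = FALSE` with a diagnostic instead of an error.
#'
#' @param times,current Numeric vectors; the decaying segment starts at
#'   `start_index`.
#' @param start_index First index of the decay (default 1).
#' @return Object of class `expdecay_fit`: `t_off`, `amplitude`,
#'   `offset`, standard errors.
#' @export
fit_monoexp <- function(times, current, start_index = 1) {
  stopifnot(length(times) == length(current))
  t0 <- times[start_index:length(times)] - times[start_index]
  yy <- current[start_index:length(current)]
  C0 <- mean(tail(yy, max(3, length(yy) %/% 10)))
  A0 <- yy[1] - C0
  pos <- (yy - C0) * sign(A0) > 0
  flagged <- function(msg) structure(
    list(converged = FALSE, diagnostics = msg,
         data = tibble(time = t0, current = yy)),
    class = "expdecay_fit")
  if (abs(A0) < 1e-12 * max(abs(yy), 1) || sum(pos) < 3) {
    return(flagged("non-decaying or offset-only data"))
  }
  lfit <- lm(log(abs(yy[pos] - C0)) ~ t0[pos])
  slope <- unname(coef(lfit)[2])
  if (!is.finite(slope) || slope >= 0) return(flagged("signal does not decay"))
  tau0 <- -1 / slope
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-t0 / tau) + C,
                      data = data.frame(t0 = t0, yy = yy),
                      start = list(A = A0, tau = tau0, C = C0),
                      lower = c(A = -Inf, tau = 1e-15, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) return(flagged(conditionMessage(fit)))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(converged = TRUE, t_off = unname(est["tau"]),
                 amplitude = unname(est["A"]), offset = unname(est["C"]),
                 coefficients = tibble(term = c("amplitude", "t_off", "offset"),
                                       estimate = unname(est[c("A", "tau", "C")]),
                                       std_error = unname(se)),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit, data = tibble(time = t0, current = yy)),
            class = "expdecay_fit")
}

#' Photocurrent at a target voltage from the linear I-V branch
#'
#' Ordinary least-squares line through the positive-voltage points,
#' evaluated at `v_target` (default +60 mV).
#'
#' @param voltage,current Paired I-V readings.
#' @param v_target Evaluation voltage (mV).
#' @return Interpolated current (same units as `current`).
#' @export
extract_current_at <- function(voltage, current, v_target = 60) {
  pos <- voltage > 0
  if (sum(pos) < 2) abort("need at least 2 positive-voltage points")
  fit <- lm(current[pos] ~ voltage[pos])
  unname(coef(fit)[1] + coef(fit)[2] * v_target)
}

#' 95%-power radius of a Gaussian beam
#'
#' For an isotropic 2-D Gaussian intensity profile the radius enclosing
#' 95% of the total power is `sigma * sqrt(2 ln 20)` (about 2.448 sigma),
#' used as a spot-size measure.
#'
#' @param sigma Gaussian sigma, > 0.
#' @return Radius in the units of `sigma`.
#' @export
beam_r95 <- function(sigma) {
  stopifnot(all(sigma > 0))
  sigma * sqrt(2 * log(20))
}
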