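#' Simulate a multi-pKa titration curve
#'
#' Generates `y(pH) = baseline + sum_k A_k / (1 + 10^(pH - pKa_k))` with
#' optional additive Gaussian noise. Each transition contributes its full
#' amplitude at low pH (fully protonated) and nothing at high pH, matching
#' acid-induced spectral shifts. Defaults reproduce a two-pKa dark-state
#' titration of the absorption maximum (pKa 3.34 and 5.71, amplitudes
#' 6.5 and 3.0 nm on a 535.5 nm baseline).
#'
#' @param pka_values Finite pKa values.
#' @param amplitudes Per-transition amplitudes `A_k` (same units as the
#'   observable).
#' @param baseline Observable at high pH.
#' @param pH Evaluation grid; should cover each pKa +/- 2.
#' @param noise_sigma Gaussian noise sd (0 for noise-free).
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @param observable_kind Label for the observable column.
#' @return Tibble with columns `pH`, `observable`; attribute
#'   `"truth"` stores the generating parameters.
#' @export
simulate_titration_curve <- function(pka_values = c(3.34, 5.71),
                                     amplitudes = c(6.5, 3.0),
                                     baseline = 535.5,
                                     pH = seq(1.3, 7.8, by = 0.25),
                                     noise_sigma = 0, seed = 1L,
                                     observable_kind = "lambda_max_nm") {
  if (length(pH) == 0) abort("empty pH grid")
  stopifnot(all(is.finite(pka_values)), length(amplitudes) == length(pka_values),
            noise_sigma >= 0)
  y <- rep(baseline, length(pH))
  for (k in seq_along(pka_values)) {
    y <- y + amplitudes[k] / (1 + 10^(pH - pka_values[k]))
  }
  if (noise_sigma > 0) {
    withr::local_seed(seed)
    y <- y + rnorm(length(y), 0, noise_sigma)
  }
  out <- tibble(pH = as.numeric(pH), observable = y)
  attr(out, "truth") <- list(pka = pka_values, amplitudes = amplitudes,
                             baseline = baseline, kind = observable_kind)
  out
}

#' Simulate a Hill saturation curve
#'
#' `y(c) = y_max * c^n / (K^n + c^n)` plus optional Gaussian noise; the
#' noise-free curve passes through `y_max / 2` at `c = K_half`. Defaults
#' emulate the sodium dependence of the O-intermediate amplitude
#' (half-saturation 190 mM).
#'
#' @param K_half Half-saturation concentration (mM), > 0.
#' @param n_hill Hill coefficient, > 0.
#' @param y_max Saturating amplitude.
#' @param conc Concentration grid (mM), non-negative.
#' @param noise_sigma Gaussian noise sd.
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @return Tibble with columns `conc`, `amplitude`; attribute `"truth"`.
#' @export
simulate_hill_curve <- function(K_half = 190, n_hill = 1, y_max = 1,
                                conc = c(0, 10, 30, 100, 190, 300, 600, 1000),
                                noise_sigma = 0, seed = 1L) {
  stopifnot(K_half > 0, n_hill > 0)
  if (any(conc < 0)) abort("negative concentrations")
  y <- y_max * conc^n_hill / (K_half^n_hill + conc^n_hill)
  y[conc == 0] <- 0
  if (noise_sigma > 0) {
    withr::local_seed(seed)
    y <- y + rnorm(length(y), 0, noise_sigma)
  }
  out <- tibble(conc = as.numeric(conc), amplitude = y)
  attr(out, "truth") <- list(K_half = K_half, n_hill = n_hill, y_max = y_max)
  out
}
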