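#' Define a sequential photocycle scheme
#'
#' A photocycle scheme describes a unidirectional first-order chain of
#' spectroscopic intermediates (e.g. K1 -> K2 -> M -> O1 -> O2 -> ground),
#' each with a lifetime and a Gaussian absorption band, plus the band of the
#' parent (ground) state. The chain is strictly sequential: branching and
#' back-reactions are not modelled.
#'
#' @param intermediates Character vector of ordered intermediate labels.
#' @param lifetimes Strictly positive, strictly increasing time constants
#'   (seconds), one per step of the chain.
#' @param band_centers Absorption maxima (nm), one per intermediate.
#' @param band_widths Gaussian sigma (nm), all positive.
#' @param band_amplitudes Unitless band amplitudes (default 1).
#' @param ground_center,ground_width,ground_amplitude Parameters of the
#'   parent-state band.
#'
#' @return An object of class `photocycle_scheme`.
#' @examples
#' sch <- photocycle_scheme(c("K", "M"), lifetimes = c(1e-5, 1e-2),
#'                          band_centers = c(590, 400), band_widths = c(30, 25))
#' @export
photocycle_scheme <- function(intermediates, lifetimes, band_centers, band_widths,
                              band_amplitudes = rep(1, length(intermediates)),
                              ground_center = 525, ground_width = 40,
                              ground_amplitude = 1) {
  n <- length(intermediates)
  stopifnot(n >= 1)
  if (length(lifetimes) != n || length(band_centers) != n ||
      length(band_widths) != n || length(band_amplitudes) != n) {
    abort("intermediates, lifetimes, band_centers, band_widths, band_amplitudes must have equal length")
  }
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    abort("lifetimes must be finite and strictly positive")
  }
  if (n > 1 && any(diff(lifetimes) <= 0)) {
    abort("lifetimes must be strictly increasing along the chain")
  }
  if (any(band_widths <= 0) || ground_width <= 0) {
    abort("band widths must be positive")
  }
  structure(
    list(intermediates = as.character(intermediates),
         lifetimes = as.numeric(lifetimes),
         band_centers = as.numeric(band_centers),
         band_widths = as.numeric(band_widths),
         band_amplitudes = as.numeric(band_amplitudes),
         ground_center = ground_center, ground_width = ground_width,
         ground_amplitude = ground_amplitude),
    class = "photocycle_scheme")
}

#' Default five-intermediate photocycle
#'
#' A sodium-pumping-rhodopsin-like chain K1 -> K2 -> M -> O1 -> O2 with
#' lifetimes spanning picoseconds to seconds (2 ps, 7 us, 1 ms, 5 ms, 6 s),
#' red-shifted K and O bands (590 / 620 nm), a blue-shifted M band (400 nm)
#' and a 525 nm parent band.
#'
#' @return A `photocycle_scheme`.
#' @export
default_photocycle <- function() {
  photocycle_scheme(
    intermediates = c("K1", "K2", "M", "O1", "O2"),
    lifetimes = c(2e-12, 7e-6, 1e-3, 5e-3, 6),
    band_centers = c(590, 590, 400, 620, 620),
    band_widths = c(32, 32, 28, 35, 35),
    band_amplitudes = c(0.9, 0.9, 0.8, 1.0, 1.0),
    ground_center = 525, ground_width = 38, ground_amplitude = 1)
}

#' Mixed linear/logarithmic time grid
#'
#' Linear spacing from `start` up to `linear_end`, then log-spaced points at
#' `points_per_decade` per decade up to `end` — the combined time base used
#' for flash-photolysis data reduction. The linear segment carries
#' `points_per_decade` evenly spaced points.
#'
#' @param start,end Grid limits in seconds, `start < end`.
#' @param linear_end End of the linear segment (seconds).
#' @param points_per_decade Log-segment density (and linear point count).
#' @return Strictly increasing numeric vector of times (s).
#' @export
mixed_time_grid <- function(start, end, linear_end = start * 10,
                            points_per_decade = 20) {
  stopifnot(start < end, points_per_decade >= 2)
  linear_end <- min(linear_end, end)
  lin <- seq(start, linear_end, length.out = points_per_decade)
  if (linear_end >= end) return(lin)
  nlog <- max(2, ceiling(log10(end / linear_end) * points_per_decade) + 1)
  lg <- 10^seq(log10(linear_end), log10(end), length.out = nlog)
  sort(unique(c(lin, lg[-1])))
}

#' Simulation configuration for transient datasets
#'
#' @param seed Integer seed; identical seed implies bit-identical output.
#' @param noise_sigma Additive i.i.d. Gaussian noise level (delta-A units).
#' @param time_start,time_end,linear_end,points_per_decade Mixed time base
#'   parameters (seconds), see [mixed_time_grid()].
#' @param wl_start,wl_end,wl_step Wavelength grid (nm).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, noise_sigma = 0,
                              time_start = 1e-7, time_end = 10,
                              linear_end = 1e-6, points_per_decade = 15,
                              wl_start = 340, wl_end = 700, wl_step = 5) {
  stopifnot(time_start < time_end, wl_start < wl_end, noise_sigma >= 0)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 time_start = time_start, time_end = time_end,
                 linear_end = linear_end,
                 points_per_decade = points_per_decade,
                 wl_start = wl_start, wl_end = wl_end, wl_step = wl_step),
            class = "simulation_config")
}

gaussian_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-((wl - center)^2) / (2 * width^2))
}

#' Concentration profiles of a sequential first-order chain
#'
#' Solves A1 -> A2 -> ... -> An -> ground with c1(0) = 1 using the Bateman
#' closed form (distinct lifetimes) or a matrix exponential. Mass is
#' conserved: the ground-state recovery equals one minus the sum of the
#' intermediate concentrations.
#'
#' @param times Numeric times (s), non-negative.
#' @param lifetimes Per-step time constants (s).
#' @param method `"bateman"` (closed form; rejects near-duplicate lifetimes)
#'   or `"expm"` (matrix exponential; tolerates duplicates).
#' @return Matrix `[length(times) x length(lifetimes)]` of concentrations.
#' @export
chain_concentrations <- function(times, lifetimes,
                                 method = c("bateman", "expm")) {
  method <- match.arg(method)
  stopifnot(all(times >= 0), all(lifetimes > 0))
  n <- length(lifetimes)
  k <- 1 / lifetimes
  if (method == "bateman") {
    # degenerate Bateman denominators blow up for (near-)equal rates
    if (n > 1) {
      rel <- abs(outer(lifetimes, lifetimes, "-")) /
        outer(lifetimes, lifetimes, pmax)
      diag(rel) <- Inf
      if (any(rel < 1e-9)) {
        abort("duplicate lifetimes (relative tolerance 1e-9); use method = \"expm\"")
      }
    }
    conc <- matrix(0, length(times), n)
    for (i in seq_len(n)) {
      pref <- if (i > 1) prod(k[seq_len(i - 1)]) else 1
      ci <- 0
      for (j in seq_len(i)) {
        denom <- prod(k[setdiff(seq_len(i), j)] - k[j])
        ci <- ci + exp(-k[j] * times) / if (i == 1) 1 else denom
      }
      conc[, i] <- pref * ci
    }
    conc
  } else {
    M <- diag(-k, n)
    if (n > 1) for (i in 2:n) M[i, i - 1] <- k[i - 1]
    t(vapply(times, function(t0) {
      as.numeric(Matrix::expm(M * t0) %*% c(1, rep(0, n - 1)))
    }, numeric(n)))
  }
}

#' Simulate a transient absorption dataset
#'
#' Generates a delta-A(t, lambda) surface for a sequential photocycle:
#' intermediate concentrations follow the first-order chain, each state
#' contributes a Gaussian band, and the signal is the population-weighted
#' difference to the parent-state band plus optional additive Gaussian
#' noise. In the noise-free limit the surface decays to zero as the
#' photocycle completes.
#'
#' @param scheme A [photocycle_scheme()].
#' @param config A [simulation_config()].
#' @param method Chain solver passed to [chain_concentrations()].
#' @return A [transient_dataset()].
#' @export
simulate_transient_dataset <- function(scheme, config = simulation_config(),
                                       method = c("bateman", "expm")) {
  stopifnot(inherits(scheme, "photocycle_scheme"),
            inherits(config, "simulation_config"))
  method <- match.arg(method)
  times <- mixed_time_grid(config$time_start, config$time_end,
                           config$linear_end, config$points_per_decade)
  wl <- seq(config$wl_start, config$wl_end, by = config$wl_step)
  conc <- chain_concentrations(times, scheme$lifetimes, method = method)
  n <- length(scheme$intermediates)
  s_ground <- gaussian_band(wl, scheme$ground_center, scheme$ground_width,
                            scheme$ground_amplitude)
  dA <- matrix(0, length(times), length(wl))
  for (i in seq_len(n)) {
    s_i <- gaussian_band(wl, scheme$band_centers[i], scheme$band_widths[i],
                         scheme$band_amplitudes[i])
    dA <- dA + outer(conc[, i], s_i - s_ground)
  }
  if (config$noise_sigma > 0) {
    withr::local_seed(config$seed)
    dA <- dA + matrix(rnorm(length(dA), 0, config$noise_sigma),
                      nrow(dA), ncol(dA))
  }
  transient_dataset(times, wl, dA,
                    metadata = list(seed = config$seed,
                                    noise_sigma = config$noise_sigma,
                                    scheme = scheme$intermediates,
                                    lifetimes = scheme$lifetimes))
}
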