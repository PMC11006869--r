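#' Transient absorption dataset
#'
#' Container for a delta-A(t, lambda) surface on a (typically mixed
#' linear/logarithmic) time base, with measurement metadata (pH, salt,
#' excitation wavelength, ...).
#'
#' @param times Strictly increasing times (s).
#' @param wavelengths Wavelengths (nm).
#' @param delta_A Matrix `[time x wavelength]` of delta-absorbance (dOD).
#' @param metadata Named list of condition metadata.
#' @return Object of class `transient_dataset`.
#' @export
transient_dataset <- function(times, wavelengths, delta_A, metadata = list()) {
  times <- as.numeric(times); wavelengths <- as.numeric(wavelengths)
  delta_A <- as.matrix(delta_A)
  if (nrow(delta_A) != length(times) || ncol(delta_A) != length(wavelengths)) {
    abort("delta_A dimensions must match times x wavelengths")
  }
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (any(!is.finite(delta_A))) abort("delta_A must be finite")
  structure(list(times = times, wavelengths = wavelengths,
                 delta_A = delta_A, metadata = metadata),
            class = "transient_dataset")
}

#' @export
print.transient_dataset <- function(x, ...) {
  cat(sprintf("<transient_dataset> %d times (%.3g..%.3g s) x %d wavelengths (%g..%g nm)\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as_tibble.transient_dataset <- function(x, ...) {
  tidyr::expand_grid(time = x$times, wavelength = x$wavelengths) |>
    dplyr::mutate(delta_A = as.vector(t(x$delta_A)))
}

#' @rdname transient_dataset
#' @param x A `transient_dataset`.
#' @param ... Unused.
#' @export
tidy.transient_dataset <- function(x, ...) as_tibble(x)

#' Write / read a transient dataset as CSV plus JSON sidecar
#'
#' The CSV holds the time axis in its first column (`time_s`) and one column
#' per wavelength (header = wavelength in nm); the sidecar
#' (`<path>.json`) carries the metadata.
#'
#' @param dataset A [transient_dataset()].
#' @param path CSV file path.
#' @return `write_transient_csv()` the path, invisibly;
#'   `read_transient_csv()` a `transient_dataset`.
#' @export
write_transient_csv <- function(dataset, path) {
  df <- data.frame(time_s = dataset$times, dataset$delta_A, check.names = FALSE)
  names(df) <- c("time_s", format(dataset$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(dataset$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transient_csv
#' @export
read_transient_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  transient_dataset(df[[1]], as.numeric(names(df)[-1]),
                    as.matrix(df[, -1, drop = FALSE]), metadata = meta)
}

#' Reduce a raw transient to a combined linear/logarithmic time base
#'
#' Points up to `linear_end` pass through unchanged; beyond it, consecutive
#' raw points falling into each logarithmic bin (`points_per_decade` bins
#' per decade) are block-averaged (mean time, mean value), so the signal
#' mean within each bin is preserved exactly. Empty bins are skipped, never
#' interpolated.
#'
#' @param times,values Raw transient; `times` strictly increasing.
#' @param linear_end End of the pass-through segment (s).
#' @param points_per_decade Logarithmic bin density.
#' @return Tibble with columns `time`, `value`.
#' @export
reduce_transient <- function(times, values, linear_end, points_per_decade = 20) {
  stopifnot(length(times) == length(values), points_per_decade >= 1)
  if (any(diff(times) <= 0)) abort("raw times must be strictly increasing")
  keep <- times <= linear_end
  out_lin <- tibble(time = times[keep], value = values[keep])
  t_log <- times[!keep]; v_log <- values[!keep]
  if (length(t_log) == 0) return(out_lin)
  edges_lo <- log10(max(linear_end, min(t_log) / 1.000001))
  bin <- floor((log10(t_log) - edges_lo) * points_per_decade)
  out_log <- tibble(time = t_log, value = v_log, bin = bin) |>
    dplyr::summarise(time = mean(.data$time), value = mean(.data$value),
                     .by = "bin") |>
    dplyr::arrange(.data$time) |>
    dplyr::select("time", "value")
  dplyr::bind_rows(out_lin, out_log)
}

#' Normalize transients to a common amplitude at a reference time
#'
#' Scales each transient so that its (linearly interpolated) value at
#' `t_ref` equals that of the first transient, e.g. to compare sodium
#' dependences after normalizing at 0.1 ms.
#'
#' @param transients Tibble with columns `id`, `time`, `value`; every
#'   transient must cover `t_ref`.
#' @param t_ref Reference time (s), default 1e-4 (0.1 ms).
#' @return The input tibble with `value` rescaled; attribute `"factors"`
#'   holds a tibble of per-id scale factors.
#' @export
normalize_at_time <- function(transients, t_ref = 1e-4) {
  stopifnot(all(c("id", "time", "value") %in% names(transients)))
  ids <- unique(transients$id)
  at_ref <- vapply(ids, function(i) {
    tr <- transients[transients$id == i, ]
    if (t_ref < min(tr$time) || t_ref > max(tr$time)) {
      abort(sprintf("transient '%s' does not cover t_ref = %g s", i, t_ref))
    }
    approx(tr$time, tr$value, xout = t_ref)$y
  }, numeric(1))
  if (any(at_ref == 0)) abort("zero value at t_ref: scale undefined")
  factors <- unname(at_ref[1] / at_ref)
  out <- transients |>
    dplyr::mutate(value = .data$value * factors[match(.data$id, ids)])
  attr(out, "factors") <- tibble(id = ids, factor = unname(factors))
  out
}

#' @export
autoplot.transient_dataset <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$wavelength,
                                 fill = .data$delta_A)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (s)", y = "wavelength (nm)",
                  fill = expression(Delta * A))
}
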