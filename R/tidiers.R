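#' @export
print.pka_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pka_fit> NOT converged:", x$diagnostics, "\n")
  } else {
    cat(sprintf("<pka_fit> %d transition(s): pKa = %s; residual RMS %.3g\n",
                x$n_transitions,
                paste(sprintf("%.3f", x$pka), collapse = ", "),
                x$residual_rms))
  }
  invisible(x)
}

#' @export
tidy.pka_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(0), estimate = numeric(0),
                                  std_error = numeric(0)))
  x$coefficients
}

#' @export
glance.pka_fit <- function(x, ...) {
  tibble(converged = x$converged,
         n_transitions = x$n_transitions %||% NA_integer_,
         residual_rms = if (x$converged) x$residual_rms else NA_real_,
         nobs = nrow(x$data))
}

#' @export
predict.pka_fit <- function(object, pH = object$data$pH, ...) {
  stopifnot(object$converged)
  multi_pka_model(pH, object$pka, object$amplitudes, object$baseline)
}

#' @export
autoplot.pka_fit <- function(object, ...) {
  stopifnot(object$converged)
  grid <- tibble(pH = seq(min(object$data$pH), max(object$data$pH),
                          length.out = 200))
  grid$observable <- predict(object, grid$pH)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$pH, .data$observable)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "pH", y = "observable")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_half = %.4g, n = %.3g, y_max = %.4g; residual RMS %.3g\n",
              x$K_half, x$n_hill, x$y_max, x$residual_rms))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) x$coefficients

#' @export
glance.hill_fit <- function(x, ...) {
  tibble(K_half = x$K_half, n_hill = x$n_hill, y_max = x$y_max,
         residual_rms = x$residual_rms, nobs = nrow(x$data))
}

#' @export
predict.hill_fit <- function(object, conc = object$data$conc, ...) {
  object$y_max * conc^object$n_hill /
    (object$K_half^object$n_hill + conc^object$n_hill)
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(conc = seq(min(object$data$conc), max(object$data$conc),
                            length.out = 200))
  grid$amplitude <- predict(object, grid$conc)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[Na+] (mM)", y = "amplitude")
}

#' @export
print.expdecay_fit <- function(x, ...) {
  if (!x$converged) cat("<expdecay_fit> NOT converged:", x$diagnostics, "\n")
  else cat(sprintf("<expdecay_fit> t_off = %.4g, amplitude = %.4g, offset = %.4g\n",
                   x$t_off, x$amplitude, x$offset))
  invisible(x)
}

#' @export
tidy.expdecay_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(0), estimate = numeric(0),
                                  std_error = numeric(0)))
  x$coefficients
}

#' @export
glance.expdecay_fit <- function(x, ...) {
  tibble(converged = x$converged,
         t_off = if (x$converged) x$t_off else NA_real_,
         residual_rms = if (x$converged) x$residual_rms else NA_real_,
         nobs = nrow(x$data))
}
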