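#' Log-even lifetime grid
#'
#' `tau_j = start * (end/start)^((j-1)/(n-1))`: n lifetimes with a constant
#' log step. The conventional defaults are 0.03-5400 ps for the ultrafast
#' timescale and, for the ns-to-s timescale, an end lifetime of three times
#' the last experimental time point (see [default_lifetime_grid()]).
#'
#' @param start,end Grid limits (s), `0 < start < end`.
#' @param n Number of lifetimes (>= 2), default 200.
#' @return Numeric vector of class `lifetime_grid`.
#' @export
build_lifetime_grid <- function(start, end, n = 200) {
  if (!is.finite(start) || !is.finite(end) || start <= 0 || end <= start) {
    abort("need 0 < start < end")
  }
  if (n < 2) abort("n must be >= 2")
  tau <- start * (end / start)^((seq_len(n) - 1) / (n - 1))
  structure(tau, class = "lifetime_grid", start = start, end = end, n = n)
}

#' Default lifetime grid for a dataset
#'
#' `"ultrafast"`: 0.03 ps to 5400 ps. `"ns_s"`: 0.4 us to three times the
#' last experimental time point. 200 lifetimes in both cases.
#'
#' @param dataset A [transient_dataset()] (needed for `"ns_s"`).
#' @param timescale `"ns_s"` or `"ultrafast"`.
#' @param n Number of lifetimes.
#' @return A [build_lifetime_grid()] result.
#' @export
default_lifetime_grid <- function(dataset = NULL,
                                  timescale = c("ns_s", "ultrafast"), n = 200) {
  timescale <- match.arg(timescale)
  if (timescale == "ultrafast") {
    build_lifetime_grid(0.03e-12, 5400e-12, n = n)
  } else {
    if (is.null(dataset)) abort("ns_s grid needs the dataset (end = 3 x last time)")
    build_lifetime_grid(4e-7, 3 * max(dataset$times), n = n)
  }
}

#' Multiexponential design matrix
#'
#' `A[i, j] = exp(-t_i / tau_j)`: the discretized Laplace kernel whose
#' regularized inversion yields the lifetime distribution. Entries lie in
#' (0, 1]; the row at t = 0 is all ones and every column decreases in t.
#'
#' @param times Non-negative times (s).
#' @param grid Positive lifetimes (s).
#' @return Matrix `[length(times) x length(grid)]`.
#' @export
build_design_matrix <- function(times, grid) {
  if (any(times < 0)) abort("negative times")
  if (any(grid <= 0)) abort("lifetimes must be positive")
  exp(-outer(as.numeric(times), 1 / as.numeric(grid)))
}

#' Tikhonov-regularized least squares
#'
#' Solves `argmin ||A x - y||^2 + alpha^2 ||x||^2`, i.e. the normal
#' equations `(A'A + alpha^2 I) x = A'y`, via the SVD of A. Amplitudes are
#' signed: positive and negative lobes are both meaningful (photoproduct
#' absorption versus ground-state bleach). At `alpha = 0` with a
#' rank-deficient A the minimum-norm solution is returned and flagged via
#' attribute `"rank_deficient"`. The penalty is written `alpha^2 ||x||^2`
#' so quoted regularization factors act on the amplitude-norm scale;
#' `penalty = "alpha"` switches to `alpha ||x||^2`.
#'
#' @param A Design matrix.
#' @param y Data vector.
#' @param alpha Regularization factor, >= 0.
#' @param penalty `"alpha2"` (default) or `"alpha"`.
#' @return Amplitude vector x.
#' @export
tikhonov_solve <- function(A, y, alpha, penalty = c("alpha2", "alpha")) {
  penalty <- match.arg(penalty)
  if (alpha < 0) abort("alpha must be >= 0")
  sv <- svd(A)
  a2 <- if (penalty == "alpha2") alpha^2 else alpha
  b <- crossprod(sv$u, y)
  rank_def <- FALSE
  if (a2 == 0) {
    tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    rank_def <- any(!pos)
    f <- ifelse(pos, 1 / sv$d, 0)
  } else {
    f <- sv$d / (sv$d^2 + a2)
  }
  x <- as.numeric(sv$v %*% (f * b))
  attr(x, "rank_deficient") <- rank_def
  x
}

# filter-factor path built on one SVD; returns norms and solutions
.ridge_path <- function(sv, y, alphas, penalty = "alpha2") {
  b <- as.numeric(crossprod(sv$u, y))
  y2 <- sum(y^2)
  out_of_range2 <- max(y2 - sum(b^2), 0)
  a2 <- if (penalty == "alpha2") alphas^2 else alphas
  res <- sol <- numeric(length(alphas))
  X <- matrix(0, ncol(sv$v), length(alphas))
  for (i in seq_along(alphas)) {
    f <- sv$d / (sv$d^2 + a2[i])
    xi <- f * b
    res[i] <- sqrt(sum(((a2[i] / (sv$d^2 + a2[i])) * b)^2) + out_of_range2)
    sol[i] <- sqrt(sum(xi^2))
    X[, i] <- xi
  }
  list(residual_norm = res, solution_norm = sol, coef = X, v = sv$v)
}

#' Regularization path
#'
#' Computes residual norm `||A x - y||` and solution norm `||x||` along a
#' log-spaced grid of regularization factors (default 200 factors from
#' 0.01 to 5). The residual norm is non-decreasing and the solution norm
#' non-increasing in alpha.
#'
#' @param A Design matrix.
#' @param y Data vector.
#' @param alpha_min,alpha_max Grid limits, `alpha_min > 0`.
#' @param m Number of factors (>= 3).
#' @param penalty See [tikhonov_solve()].
#' @return Tibble of class `regularization_path` with columns `alpha`,
#'   `residual_norm`, `solution_norm`.
#' @export
regularization_path <- function(A, y, alpha_min = 0.01, alpha_max = 5,
                                m = 200, penalty = "alpha2") {
  if (alpha_min <= 0) abort("alpha_min must be > 0")
  if (m < 3) abort("need m >= 3")
  alphas <- 10^seq(log10(alpha_min), log10(alpha_max), length.out = m)
  sv <- svd(A)
  p <- .ridge_path(sv, y, alphas, penalty)
  out <- tibble(alpha = alphas, residual_norm = p$residual_norm,
                solution_norm = p$solution_norm)
  class(out) <- c("regularization_path", class(out))
  out
}

#' L-curve corner selection
#'
#' Chooses the regularization factor at the point of maximum curvature of
#' the (log residual-norm, log solution-norm) trade-off curve, estimated by
#' central finite differences over the path index; endpoints are excluded
#' and ties resolved toward the smaller factor. A degenerate flat curve
#' falls back to the median factor with a warning.
#'
#' @param path A [regularization_path()].
#' @return The chosen alpha; attributes `"index"` and `"curvature"`.
#' @export
l_curve_corner <- function(path) {
  if (nrow(path) < 5) abort("need at least 5 path points")
  lx <- log(pmax(path$residual_norm, .Machine$double.xmin))
  ly <- log(pmax(path$solution_norm, .Machine$double.xmin))
  n <- length(lx)
  i <- 2:(n - 1)
  dx <- (lx[i + 1] - lx[i - 1]) / 2
  dy <- (ly[i + 1] - ly[i - 1]) / 2
  ddx <- lx[i + 1] - 2 * lx[i] + lx[i - 1]
  ddy <- ly[i + 1] - 2 * ly[i] + ly[i - 1]
  denom <- (dx^2 + dy^2)^1.5
  kappa <- ifelse(denom > 0, (dx * ddy - dy * ddx) / denom, 0)
  if (diff(range(ly)) < 1e-10 || all(!is.finite(kappa)) ||
      max(kappa, na.rm = TRUE) <= 0) {
    warn("degenerate L-curve; falling back to median alpha")
    idx <- ceiling(n / 2)
  } else {
    idx <- i[which.max(kappa)]  # which.max takes the first tie -> smaller alpha
  }
  structure(path$alpha[idx], index = idx,
            curvature = c(NA, kappa, NA))
}

#' Lifetime distribution map
#'
#' Inverts a transient dataset into signed lifetime distributions by
#' Tikhonov-regularized inverse Laplace transformation, per wavelength
#' (independent inversion and L-curve factor per transient; the default) or
#' globally (one factor chosen from the stacked system). Times at or below
#' `drop_before` are discarded prior to inversion (pump-probe artifact
#' region).
#'
#' @param dataset A [transient_dataset()].
#' @param grid A [build_lifetime_grid()]; default
#'   [default_lifetime_grid()] on the ns-to-s timescale.
#' @param alpha_min,alpha_max,n_alpha Regularization-factor grid (defaults
#'   0.01-5, 200 factors).
#' @param mode `"per-wavelength"` or `"global"`.
#' @param drop_before Drop times `<= drop_before` (s), default 0.
#' @param penalty See [tikhonov_solve()].
#' @return Object of class `ldm`: `grid`, `wavelengths`, `amplitudes`
#'   `[n_tau x n_wavelength]`, `alpha` (per wavelength or scalar),
#'   `residual` (relative reconstruction residual per wavelength), `mode`.
#' @export
compute_ldm <- function(dataset, grid = NULL, alpha_min = 0.01, alpha_max = 5,
                        n_alpha = 200, mode = c("per-wavelength", "global"),
                        drop_before = 0, penalty = "alpha2") {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "transient_dataset"))
  if (is.null(grid)) grid <- default_lifetime_grid(dataset, "ns_s")
  keep <- dataset$times > drop_before
  times <- dataset$times[keep]
  Y <- dataset$delta_A[keep, , drop = FALSE]
  if (any(apply(Y, 2, function(col) all(is.na(col))))) abort("all-NaN wavelength column")
  A <- build_design_matrix(times, grid)
  sv <- svd(A)
  alphas <- 10^seq(log10(alpha_min), log10(alpha_max), length.out = n_alpha)
  nw <- ncol(Y)
  X <- matrix(0, length(grid), nw)
  resid_rel <- numeric(nw)
  if (mode == "per-wavelength") {
    alpha_sel <- numeric(nw)
    for (j in seq_len(nw)) {
      p <- .ridge_path(sv, Y[, j], alphas, penalty)
      pt <- tibble(alpha = alphas, residual_norm = p$residual_norm,
                   solution_norm = p$solution_norm)
      class(pt) <- c("regularization_path", class(pt))
      a_j <- suppressWarnings(l_curve_corner(pt))
      idx <- attr(a_j, "index")
      alpha_sel[j] <- as.numeric(a_j)
      X[, j] <- p$v %*% p$coef[, idx]
      ynorm <- sqrt(sum(Y[, j]^2))
      resid_rel[j] <- if (ynorm > 0) p$residual_norm[idx] / ynorm else 0
    }
  } else {
    res2 <- sol2 <- numeric(length(alphas))
    paths <- vector("list", nw)
    for (j in seq_len(nw)) {
      p <- .ridge_path(sv, Y[, j], alphas, penalty)
      paths[[j]] <- p
      res2 <- res2 + p$residual_norm^2
      sol2 <- sol2 + p$solution_norm^2
    }
    pt <- tibble(alpha = alphas, residual_norm = sqrt(res2),
                 solution_norm = sqrt(sol2))
    class(pt) <- c("regularization_path", class(pt))
    a_g <- suppressWarnings(l_curve_corner(pt))
    idx <- attr(a_g, "index")
    alpha_sel <- as.numeric(a_g)
    for (j in seq_len(nw)) {
      X[, j] <- paths[[j]]$v %*% paths[[j]]$coef[, idx]
      ynorm <- sqrt(sum(Y[, j]^2))
      resid_rel[j] <- if (ynorm > 0) paths[[j]]$residual_norm[idx] / ynorm else 0
    }
  }
  structure(list(grid = grid, wavelengths = dataset$wavelengths,
                 amplitudes = X, alpha = alpha_sel, residual = resid_rel,
                 mode = mode, metadata = dataset$metadata),
            class = "ldm")
}

#' @export
print.ldm <- function(x, ...) {
  cat(sprintf("<ldm> %d lifetimes (%.3g..%.3g s) x %d wavelengths, mode %s\n",
              length(x$grid), min(x$grid), max(x$grid),
              length(x$wavelengths), x$mode))
  invisible(x)
}

#' @rdname compute_ldm
#' @param x An `ldm`.
#' @param ... Unused.
#' @export
tidy.ldm <- function(x, ...) {
  tidyr::expand_grid(lifetime = as.numeric(x$grid),
                     wavelength = x$wavelengths) |>
    dplyr::mutate(amplitude = as.vector(t(x$amplitudes)))
}

#' @export
autoplot.ldm <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$lifetime, .data$wavelength,
                                 fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "lifetime (s)", y = "wavelength (nm)", fill = "amplitude")
}

#' Peak lifetimes of a distribution
#'
#' Local maxima of the absolute amplitude along the lifetime axis at one
#' wavelength, above a relative amplitude floor, reported with their signed
#' amplitude and sorted by lifetime. Intermediate transition lifetimes are
#' read off at these maxima, so they are approximate by construction.
#'
#' @param ldm An [compute_ldm()] result.
#' @param wavelength Wavelength (nm); nearest grid wavelength is used.
#' @param amplitude_floor Fraction of the maximum absolute amplitude below
#'   which peaks are ignored (default 0.05).
#' @return Tibble: `lifetime`, `amplitude` (signed); empty when the
#'   distribution is all zero.
#' @export
peak_lifetimes <- function(ldm, wavelength, amplitude_floor = 0.05) {
  j <- which.min(abs(ldm$wavelengths - wavelength))
  x <- ldm$amplitudes[, j]
  ax <- abs(x)
  if (max(ax) == 0) return(tibble(lifetime = numeric(0), amplitude = numeric(0)))
  floor_abs <- amplitude_floor * max(ax)
  n <- length(ax)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) ax[i - 1] else -Inf
    right <- if (i < n) ax[i + 1] else -Inf
    ax[i] >= left && ax[i] > right && ax[i] > floor_abs
  }, logical(1))
  tibble(lifetime = as.numeric(ldm$grid[is_peak]), amplitude = x[is_peak]) |>
    dplyr::arrange(.data$lifetime)
}

#' @export
autoplot.regularization_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$residual_norm,
                                       .data$solution_norm)) +
    ggplot2::geom_path() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "||Ax - y||", y = "||x||", title = "L-curve")
}

#' Write an LDM as CSV plus JSON sidecar
#'
#' CSV matrix with lifetimes as rows (`lifetime_s` column) and wavelengths
#' as columns; the sidecar holds chosen factors and residuals.
#'
#' @param ldm An `ldm`.
#' @param path CSV path.
#' @export
write_ldm_csv <- function(ldm, path) {
  df <- data.frame(lifetime_s = as.numeric(ldm$grid), ldm$amplitudes,
                   check.names = FALSE)
  names(df) <- c("lifetime_s", format(ldm$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(mode = ldm$mode, alpha = ldm$alpha,
                            residual = ldm$residual,
                            wavelengths = ldm$wavelengths),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
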