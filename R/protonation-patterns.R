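#' Enumerate protonation patterns of a titratable residue set
#'
#' Each residue of the counterion complex (default E64, D105, D242) is
#' either deprotonated (`-`) or protonated with one of `n_orientations`
#' geometric proton placements (`H1` ... `H4`). All combinations with at
#' most `max_protonated` protonated residues are enumerated in a canonical
#' order (by proton count, then lexicographically over the per-residue
#' states). With the defaults this yields 61 patterns: 1 zero-, 12 single-
#' and 48 double-protonation.
#'
#' @param residues Ordered residue labels (default `c("E64","D105","D242")`).
#' @param n_orientations Proton orientations per protonated residue
#'   (default 4).
#' @param max_protonated Maximum number of simultaneously protonated
#'   residues (default 2; may not exceed the residue count).
#' @return Tibble: `pattern_id`, `n_protons`, one state column per
#'   residue.
#' @export
enumerate_patterns <- function(residues = c("E64", "D105", "D242"),
                               n_orientations = 4, max_protonated = 2) {
  n <- length(residues)
  stopifnot(n >= 0, n_orientations >= 0, max_protonated >= 0)
  if (max_protonated > n) abort("max_protonated exceeds the number of residues")
  states <- list()
  for (k in 0:max_protonated) {
    combos <- if (k == 0) matrix(integer(0), nrow = 1, ncol = 0)
              else t(utils::combn(n, k))
    for (r in seq_len(nrow(combos))) {
      prot <- combos[r, ]
      ori <- if (k == 0) matrix(integer(0), nrow = 1, ncol = 0)
             else as.matrix(expand.grid(rep(list(seq_len(n_orientations)), k)))
      if (k > 0 && n_orientations == 0) next
      for (s in seq_len(nrow(ori))) {
        st <- rep("-", n)
        if (k > 0) st[prot] <- paste0("H", ori[s, ])
        states[[length(states) + 1]] <- st
      }
    }
  }
  if (length(states) == 0) {
    return(tibble(pattern_id = character(0), n_protons = integer(0)))
  }
  M <- do.call(rbind, states)
  n_protons <- rowSums(M != "-")
  key <- apply(M, 1, paste, collapse = "|")
  ord <- order(n_protons, key, method = "radix")
  M <- M[ord, , drop = FALSE]
  n_protons <- n_protons[ord]
  out <- tibble(pattern_id = sprintf("P%03d", seq_len(nrow(M))),
                n_protons = as.integer(n_protons))
  for (j in seq_len(n)) out[[residues[j]]] <- M[, j]
  out
}

#' Pattern counts per protonation level
#'
#' @param patterns An [enumerate_patterns()] tibble.
#' @return Tibble with `n_protons` and `count` (counts sum to the total).
#' @export
count_by_level <- function(patterns) {
  if (nrow(patterns) == 0) return(tibble(n_protons = integer(0), count = integer(0)))
  dplyr::count(patterns, .data$n_protons, name = "count")
}

#' Photon energy / wavelength conversion
#'
#' `E[eV] = 1239.842 / lambda[nm]` and its inverse.
#'
#' @param lambda_nm,energy_ev Numeric vectors.
#' @return Converted values.
#' @export
ev_from_nm <- function(lambda_nm) 1239.842 / lambda_nm

#' @rdname ev_from_nm
#' @export
nm_from_ev <- function(energy_ev) 1239.842 / energy_ev

#' Select the protonation model consistent with experiment
#'
#' Shortlists the patterns whose computed vertical excitation energy lies
#' within `tolerance_ev` of the experimental value (the excitation-energy
#' method's estimated error is 0.1-0.3 eV), optionally restricted to a
#' given proton count, and picks the shortlist member with the lowest
#' ground-state energy; exact ties are all reported. An empty shortlist
#' yields an explicit no-consistent-model result rather than an error.
#'
#' @param table Tibble with columns `pattern_id`, `ground_energy`,
#'   `excitation_ev`, a `unit` column (or attribute) tagging the
#'   ground-state energy unit, and optionally `n_protons`.
#' @param experimental_ev Experimental excitation energy (eV); convert
#'   from an absorption maximum with [ev_from_nm()].
#' @param tolerance_ev Energy window half-width (default 0.3 eV).
#' @param required_proton_count Optional restriction on `n_protons`.
#' @return Object of class `model_selection`: `consistent` flag, `chosen`
#'   (ids of the minimum-energy pattern(s)), `shortlist` (tibble ranked by
#'   ground-state energy).
#' @export
select_consistent_model <- function(table, experimental_ev, tolerance_ev = 0.3,
                                    required_proton_count = NULL) {
  stopifnot(all(c("pattern_id", "ground_energy", "excitation_ev") %in% names(table)))
  if (nrow(table) == 0) abort("empty energy table")
  if (anyDuplicated(table$pattern_id)) abort("pattern ids must be unique")
  if (any(!is.finite(table$ground_energy)) || any(!is.finite(table$excitation_ev))) {
    abort("energies must be finite")
  }
  unit <- if ("unit" %in% names(table)) unique(table$unit) else attr(table, "unit")
  if (is.null(unit)) abort("ground-state energies must carry a unit tag ('unit' column or attribute)")
  if (length(unit) > 1) abort(paste("mixed energy units:", paste(unit, collapse = ", ")))
  short <- table[abs(table$excitation_ev - experimental_ev) <= tolerance_ev, ]
  if (!is.null(required_proton_count)) {
    if (!"n_protons" %in% names(short)) abort("required_proton_count needs an n_protons column")
    short <- short[short$n_protons == required_proton_count, ]
  }
  if (nrow(short) == 0) {
    return(structure(list(consistent = FALSE, chosen = character(0),
                          shortlist = short, unit = unit,
                          experimental_ev = experimental_ev,
                          tolerance_ev = tolerance_ev),
                     class = "model_selection"))
  }
  short <- dplyr::arrange(short, .data$ground_energy, .data$pattern_id)
  e_min <- min(short$ground_energy)
  chosen <- short$pattern_id[short$ground_energy == e_min]
  structure(list(consistent = TRUE, chosen = chosen, shortlist = short,
                 unit = unit, experimental_ev = experimental_ev,
                 tolerance_ev = tolerance_ev),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  if (!x$consistent) {
    cat(sprintf("<model_selection> no consistent model within %.2f eV of %.3f eV\n",
                x$tolerance_ev, x$experimental_ev))
  } else {
    cat(sprintf("<model_selection> chosen: %s (of %d within %.2f eV of %.3f eV)\n",
                paste(x$chosen, collapse = ", "), nrow(x$shortlist),
                x$tolerance_ev, x$experimental_ev))
  }
  invisible(x)
}

#' @rdname select_consistent_model
#' @param x A `model_selection`.
#' @param ... Unused.
#' @export
tidy.model_selection <- function(x, ...) x$shortlist

#' @rdname select_consistent_model
#' @export
glance.model_selection <- function(x, ...) {
  tibble(consistent = x$consistent, n_shortlist = nrow(x$shortlist),
         chosen = paste(x$chosen, collapse = ","),
         experimental_ev = x$experimental_ev, tolerance_ev = x$tolerance_ev)
}
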