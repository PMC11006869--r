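#' Structure model (atom table)
#'
#' A tidy atom table: one row per atom with chain, residue number/name,
#' atom name, element, coordinates (Angstrom), occupancy and alt-loc.
#'
#' @param atoms Tibble/data frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `elesy` (element), `x`, `y`, `z`, `o`
#'   (occupancy), `alt`.
#' @param format Source format tag.
#' @return Tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, format = "memory") {
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z", "o", "alt")
  atoms <- as_tibble(atoms)
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste("missing atom columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) abort("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$alt)
  if (anyDuplicated(key)) abort("duplicate (chain, resno, atom, alt-loc) atoms")
  out <- atoms[, need]
  class(out) <- c("structure_model", class(out))
  attr(out, "format") <- format
  out
}

#' Read a structure from PDB or mmCIF
#'
#' Loads all ATOM/HETATM records. Alternate locations are resolved by
#' keeping, per (chain, residue, atom), the highest-occupancy conformer,
#' ties broken in favour of alt-loc 'A'.
#'
#' @param path File path (`.pdb`, `.cif`) or a character string containing
#'   PDB-format text (detected by an embedded newline).
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (grepl("\n", path)) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(path, tf)
    path <- tf
    if (format == "auto") format <- "pdb"
  }
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    withCallingHandlers(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
      warning = function(w) {
        # informational bio3d notices (beta read.cif, missing helix/sheet)
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) abort(paste0("malformed ", format, " file '", path, "': ",
                                     conditionMessage(e))))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0) abort("no atom records found")
  atoms <- tibble(chain = as.character(a$chain), resno = as.integer(a$resno),
                  resid = as.character(a$resid), elety = as.character(a$elety),
                  elesy = as.character(a$elesy %||% ""),
                  x = a$x, y = a$y, z = a$z,
                  o = as.numeric(a$o %||% 1),
                  alt = ifelse(is.na(a$alt) | a$alt == "", "", as.character(a$alt)))
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  # alt-loc policy: highest occupancy, tie -> 'A' (then alphabetical)
  atoms <- atoms |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt) |>
    dplyr::distinct(.data$chain, .data$resno, .data$elety, .keep_all = TRUE) |>
    dplyr::arrange(.data$chain, .data$resno)
  structure_model(atoms, format = format)
}

#' Write a structure in a minimal PDB dialect
#'
#' Fixed-width ATOM records only; the dialect round-trips byte-stably
#' through [read_structure()] / `write_structure_pdb()`.
#'
#' @param model A [structure_model()].
#' @param path Output path, or `NULL` to return the text.
#' @export
write_structure_pdb <- function(model, path = NULL) {
  pad_atom <- function(a) {
    # short atom names start in column 14 by PDB convention
    if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a)
  }
  lines <- vapply(seq_len(nrow(model)), function(i) {
    sprintf("ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, pad_atom(model$elety[i]), substr(model$alt[i], 1, 1),
            model$resid[i], model$chain[i], model$resno[i],
            model$x[i], model$y[i], model$z[i], model$o[i], 0,
            model$elesy[i])
  }, "")
  txt <- c(lines, "END")
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}

parse_selection <- function(sel) {
  if (is.list(sel)) return(sel)
  # "A/64/OE1,OE2" or "64/OE1,OE2" or "OE1,OE2"
  parts <- strsplit(sel, "/", fixed = TRUE)[[1]]
  out <- list()
  if (length(parts) == 3) {
    out$chain <- parts[1]; out$resno <- as.integer(parts[2])
    out$elety <- strsplit(parts[3], ",")[[1]]
  } else if (length(parts) == 2) {
    out$resno <- as.integer(parts[1]); out$elety <- strsplit(parts[2], ",")[[1]]
  } else {
    out$elety <- strsplit(parts[1], ",")[[1]]
  }
  out
}

select_atoms <- function(model, sel) {
  sel <- parse_selection(sel)
  keep <- rep(TRUE, nrow(model))
  if (!is.null(sel$chain)) keep <- keep & model$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & model$resno %in% sel$resno
  if (!is.null(sel$resid)) keep <- keep & model$resid %in% sel$resid
  if (!is.null(sel$elety)) keep <- keep & model$elety %in% sel$elety
  model[keep, ]
}

#' Minimum distance between two atom selections
#'
#' Minimum Euclidean distance over the cross-product of two selections,
#' e.g. the nearest carboxyl oxygens of E64 and D105. Selections are
#' compact strings `"chain/resno/atom1,atom2"` or named lists with any of
#' `chain`, `resno`, `resid`, `elety`.
#'
#' @param model A [structure_model()].
#' @param sel_a,sel_b Atom selections.
#' @return One-row tibble: `distance` (Angstrom) plus the identifying
#'   fields of the closest atom pair.
#' @export
min_distance <- function(model, sel_a, sel_b) {
  A <- select_atoms(model, sel_a); B <- select_atoms(model, sel_b)
  if (nrow(A) == 0) abort(paste("empty selection:", format_sel(sel_a)))
  if (nrow(B) == 0) abort(paste("empty selection:", format_sel(sel_b)))
  pa <- as.matrix(A[, c("x", "y", "z")]); pb <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  ij <- arrayInd(which.min(d2), dim(d2))
  tibble(distance = sqrt(max(d2[ij], 0)),
         chain_a = A$chain[ij[1]], resno_a = A$resno[ij[1]],
         atom_a = A$elety[ij[1]],
         chain_b = B$chain[ij[2]], resno_b = B$resno[ij[2]],
         atom_b = B$elety[ij[2]])
}

format_sel <- function(sel) {
  if (is.character(sel)) sel else paste(unlist(sel), collapse = "/")
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Pairs atoms between two models by (chain, residue number, atom name),
#' restricted to a selection (default C-alpha, waters excluded), and
#' computes the least-squares rigid superposition with a proper rotation
#' (determinant correction via SVD). Plain n x 3 coordinate matrices are
#' also accepted and paired row-by-row.
#'
#' @param model_a,model_b [structure_model()]s or n x 3 matrices.
#' @param selection Atom selection applied to both models (ignored for
#'   matrices). Default C-alpha atoms.
#' @param exclude_water Drop HOH/WAT residues before pairing.
#' @return Object of class `superposition_result`: rotation (3 x 3, det
#'   +1), translation, `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch_rmsd <- function(model_a, model_b, selection = list(elety = "CA"),
                        exclude_water = TRUE) {
  if (is.matrix(model_a) && is.matrix(model_b)) {
    P <- model_a; Q <- model_b
    sel_desc <- "matrix rows"
  } else {
    A <- select_atoms(model_a, selection); B <- select_atoms(model_b, selection)
    if (exclude_water) {
      A <- A[!A$resid %in% c("HOH", "WAT"), ]
      B <- B[!B$resid %in% c("HOH", "WAT"), ]
    }
    key_a <- paste(A$chain, A$resno, A$elety)
    key_b <- paste(B$chain, B$resno, B$elety)
    common <- intersect(key_a, key_b)
    if (length(common) == 0) abort("no common atoms under the selection")
    P <- as.matrix(A[match(common, key_a), c("x", "y", "z")])
    Q <- as.matrix(B[match(common, key_b), c("x", "y", "z")])
    sel_desc <- format_sel(selection)
  }
  if (nrow(P) < 3 || nrow(P) != nrow(Q)) abort("need >= 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # R maps centered A onto centered B
  P_rot <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P_rot - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd, n_atoms = nrow(P), selection = sel_desc),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %d atoms (%s)\n",
              x$rmsd, x$n_atoms, x$selection))
  invisible(x)
}

#' @rdname kabsch_rmsd
#' @param x A `superposition_result`.
#' @param ... Unused.
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble(term = c("rmsd", "n_atoms", paste0("t", 1:3)),
         value = c(x$rmsd, x$n_atoms, x$translation))
}

#' @rdname kabsch_rmsd
#' @export
glance.superposition_result <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         det_rotation = det(x$rotation), selection = x$selection)
}

#' Modeled residue range of a chain
#'
#' First and last residue numbers with at least one atom, and the count of
#' distinct modeled residues (waters excluded by default).
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @param exclude_water Drop HOH/WAT residues.
#' @return One-row tibble: `first`, `last`, `count`.
#' @export
modeled_residue_range <- function(model, chain, exclude_water = TRUE) {
  m <- model[model$chain == chain, ]
  if (exclude_water) m <- m[!m$resid %in% c("HOH", "WAT"), ]
  if (nrow(m) == 0) abort(paste("unknown chain:", chain))
  resno <- unique(m$resno)
  tibble(first = min(resno), last = max(resno), count = length(resno))
}

#' Generate a rigid-transformed toy structure pair
#'
#' Random C-alpha-only model plus a copy subjected to a proper rotation,
#' translation and optional per-atom Gaussian jitter; the expected Kabsch
#' RMSD tends to zero as the jitter vanishes.
#'
#' @param n_atoms Number of atoms (>= 3).
#' @param rotation 3 x 3 proper rotation (det +1) or `NULL` for a random one.
#' @param translation Length-3 numeric.
#' @param jitter_sigma Per-coordinate Gaussian sd (Angstrom).
#' @param seed Integer seed.
#' @return List `a`, `b` ([structure_model()]s), `rotation`, `translation`.
#' @export
generate_toy_structure_pair <- function(n_atoms = 50, rotation = NULL,
                                        translation = c(0, 0, 0),
                                        jitter_sigma = 0, seed = 1L) {
  if (n_atoms < 3) abort("n_atoms must be >= 3")
  withr::local_seed(seed)
  if (is.null(rotation)) rotation <- random_rotation_matrix()
  if (abs(det(rotation) - 1) > 1e-8) abort("rotation must be proper (det = +1)")
  P <- matrix(runif(3 * n_atoms, -10, 10), ncol = 3)
  Q <- P %*% t(rotation) + matrix(translation, n_atoms, 3, byrow = TRUE)
  if (jitter_sigma > 0) Q <- Q + matrix(rnorm(3 * n_atoms, 0, jitter_sigma), ncol = 3)
  mk <- function(X) structure_model(tibble(
    chain = "A", resno = seq_len(n_atoms), resid = "GLY", elety = "CA",
    elesy = "C", x = X[, 1], y = X[, 2], z = X[, 3], o = 1, alt = ""))
  list(a = mk(P), b = mk(Q), rotation = rotation, translation = translation)
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) random rotation via QR decomposition with sign fix.
#' @return 3 x 3 matrix with determinant +1.
#' @export
random_rotation_matrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
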