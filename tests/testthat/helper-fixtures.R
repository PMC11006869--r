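# Shared helpers: independent oracles and small fixture builders.

# Horn quaternion-method superposition oracle, independent of the SVD path.
quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- t(P0) %*% Q0
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# A planted lifetime counts as recovered when a peak lies within one
# lifetime-grid step (ratio tolerance) of it.
recovered_within_step <- function(peaks, tau, grid) {
  step <- (max(grid) / min(grid))^(1 / (length(grid) - 1))
  any(abs(log(peaks$lifetime / tau)) <= log(step) * (1 + 1e-9))
}

# Small handmade reference-anchored alignment.
toy_alignment <- function() {
  ref_alignment(tibble::tibble(
    id = c("KR2", "s1", "s2"),
    seq = c("MRND-QDK", "MKND-QDK", "M-NDAQDK")), reference_id = "KR2")
}

# Minimal three-atom PDB text.
toy_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}
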