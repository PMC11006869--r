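#' Reference-anchored alignment
#'
#' An aligned set of sequence records (equal lengths, gaps as `-`) together
#' with the id of a reference record whose residue numbering anchors all
#' position-based operations (motif columns, subgroup column).
#'
#' @param records Tibble with columns `id` (unique, non-empty) and `seq`
#'   (upper-case amino acids, `X` and `-` allowed).
#' @param reference_id Id of the reference record; must be present.
#' @param offset Residue number of the reference's first residue (default 1).
#' @return Tibble of class `ref_alignment`.
#' @export
ref_alignment <- function(records, reference_id, offset = 1L) {
  records <- as_tibble(records)
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) abort("record ids must be unique")
  if (any(records$id == "")) abort("record ids must be non-empty")
  widths <- nchar(records$seq)
  if (length(unique(widths)) != 1) abort("aligned records must have equal length")
  if (!reference_id %in% records$id) abort(paste("reference id not found:", reference_id))
  bad <- grepl(sprintf("[^%sX-]", paste(AA20, collapse = "")), toupper(records$seq))
  if (any(bad)) abort(paste("invalid residue letters in:",
                            paste(records$id[bad], collapse = ", ")))
  records$seq <- toupper(records$seq)
  out <- records
  class(out) <- c("ref_alignment", class(out))
  attr(out, "reference_id") <- reference_id
  attr(out, "offset") <- as.integer(offset)
  out
}

ungapped_length <- function(seq) nchar(gsub("-", "", seq, fixed = TRUE))

#' Map reference residue numbers to alignment columns
#'
#' Column `c` maps to reference position `p` iff the reference row has its
#' p-th non-gap character (in reference numbering, honouring the offset) in
#' column `c`. Columns are 1-based in all user-facing output.
#'
#' @param aln A [ref_alignment()].
#' @param positions 1-based reference residue numbers.
#' @return Named integer vector: names are positions, values columns.
#' @export
build_reference_map <- function(aln, positions) {
  stopifnot(inherits(aln, "ref_alignment"))
  ref <- aln$seq[aln$id == attr(aln, "reference_id")]
  chars <- strsplit(ref, "")[[1]]
  nongap <- which(chars != "-")
  idx <- positions - attr(aln, "offset") + 1L
  if (any(idx < 1) || any(idx > length(nongap))) {
    abort("position beyond reference length")
  }
  setNames(nongap[idx], positions)
}

#' Motif specification
#'
#' Ordered anchors (reference positions with allowed letters); the anchor
#' order is the order in which the motif string is spelled. The default is
#' the sodium-pump RNDQDK motif at KR2 positions 109, 112, 116, 123, 251,
#' 216 — listed in spelling order, not ascending (ascending order would
#' spell RNDQKD). Note the quoted anchor set uses K216 although the
#' retinal-binding lysine of KR2 is elsewhere numbered K255; the anchors
#' are therefore fully user-configurable.
#'
#' @param positions 1-based reference residue numbers, unique, in motif
#'   spelling order.
#' @param allowed_letters List of non-empty character vectors (one set per
#'   anchor), or a single string whose k-th letter is the sole allowed
#'   letter of anchor k. `X` never matches an anchor.
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(positions = c(109, 112, 116, 123, 251, 216),
                       allowed_letters = "RNDQDK") {
  if (anyDuplicated(positions)) abort("anchor positions must be unique")
  if (is.character(allowed_letters) && length(allowed_letters) == 1) {
    allowed_letters <- as.list(strsplit(allowed_letters, "")[[1]])
  }
  stopifnot(length(allowed_letters) == length(positions),
            all(lengths(allowed_letters) >= 1))
  structure(list(positions = as.integer(positions),
                 allowed = lapply(allowed_letters, toupper)),
            class = "motif_spec")
}

#' Extract reference-anchored motifs
#'
#' Reads, for each record, the letters at the alignment columns mapped from
#' the anchor positions, in spelling order; a gap at an anchor column
#' yields `-` in the motif string.
#'
#' @param aln A [ref_alignment()].
#' @param spec A [motif_spec()].
#' @param record_id Optionally a single record id; default all records.
#' @return Tibble with columns `id`, `motif` (single string per record).
#' @export
extract_motif <- function(aln, spec, record_id = NULL) {
  stopifnot(inherits(spec, "motif_spec"))
  cols <- build_reference_map(aln, spec$positions)
  recs <- if (is.null(record_id)) aln else {
    if (!record_id %in% aln$id) abort(paste("unknown record id:", record_id))
    aln[aln$id == record_id, ]
  }
  motifs <- vapply(recs$seq, function(s) {
    paste(vapply(cols, function(cc) substr(s, cc, cc), ""), collapse = "")
  }, "", USE.NAMES = FALSE)
  tibble(id = recs$id, motif = motifs)
}

#' Apply motif, length and duplicate filters
#'
#' A record is kept iff (1) its motif letter at every anchor is in that
#' anchor's allowed set, (2) its ungapped length is strictly greater than
#' `min_length`, and (3) its exact ungapped sequence (case-insensitive) has
#' not occurred earlier in input order.
#'
#' @param aln A [ref_alignment()].
#' @param spec A [motif_spec()].
#' @param min_length Strict lower bound on ungapped length (default 250).
#' @return Tibble: `id`, `motif`, `motif_ok`, `length_ok`, `unique_ok`,
#'   `kept`.
#' @export
apply_filters <- function(aln, spec, min_length = 250) {
  motifs <- extract_motif(aln, spec)
  letters_mat <- do.call(rbind, strsplit(motifs$motif, ""))
  motif_ok <- rep(TRUE, nrow(motifs))
  for (k in seq_along(spec$allowed)) {
    motif_ok <- motif_ok & letters_mat[, k] %in% spec$allowed[[k]]
  }
  length_ok <- ungapped_length(aln$seq) > min_length
  ungapped <- toupper(gsub("-", "", aln$seq, fixed = TRUE))
  unique_ok <- !duplicated(ungapped)
  tibble(id = aln$id, motif = motifs$motif, motif_ok = motif_ok,
         length_ok = length_ok, unique_ok = unique_ok,
         kept = motif_ok & length_ok & unique_ok)
}

#' Pairwise sequence identity
#'
#' Aligned mode: identical matched (both non-gap) columns divided by the
#' smaller ungapped length. Unaligned mode: a global (Needleman-Wunsch)
#' alignment is built first and identity is identical aligned positions
#' over the smaller sequence length — the CD-HIT convention. Symmetric,
#' with `identity(a, a) = 1`.
#'
#' @param a,b Sequence strings (equal length in aligned mode).
#' @param mode `"aligned"` or `"unaligned"`.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, mode = c("aligned", "unaligned")) {
  mode <- match.arg(mode)
  if (nchar(gsub("-", "", a)) == 0 || nchar(gsub("-", "", b)) == 0) {
    abort("empty sequence")
  }
  a <- toupper(a); b <- toupper(b)
  min_len <- min(ungapped_length(a), ungapped_length(b))
  if (mode == "aligned") {
    if (nchar(a) != nchar(b)) abort("aligned mode requires equal-length strings")
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    matches <- sum(ca == cb & ca != "-" & cb != "-")
  } else {
    al <- Biostrings::pairwiseAlignment(
      gsub("-", "", a), gsub("-", "", b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    matches <- Biostrings::nmatch(al)
  }
  matches / min_len
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Records are sorted by ungapped length descending (ties by id); the first
#' seeds a cluster, and each subsequent record joins the first existing
#' representative with identity >= `threshold`, else becomes a new
#' representative. Representatives are thus mutually below the threshold
#' and form the reduced sequence set.
#'
#' @param records Tibble with `id`, `seq`.
#' @param threshold Identity threshold in (0, 1], default 0.90.
#' @param mode Identity mode, see [pairwise_identity()].
#' @return Object of class `identity_clustering`: `representatives`
#'   (ids), `membership` (tibble `id`, `representative`), `threshold`.
#' @export
cluster_by_identity <- function(records, threshold = 0.90,
                                mode = c("aligned", "unaligned")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (nrow(records) < 1) abort("need at least one record")
  ord <- order(-ungapped_length(records$seq), records$id)
  recs <- records[ord, ]
  reps <- character(0)
  member <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    assigned <- NA_character_
    for (r in reps) {
      idv <- pairwise_identity(recs$seq[recs$id == r], recs$seq[i], mode = mode)
      if (idv >= threshold) { assigned <- r; break }
    }
    if (is.na(assigned)) { reps <- c(reps, recs$id[i]); assigned <- recs$id[i] }
    member[i] <- assigned
  }
  structure(list(representatives = reps,
                 membership = tibble(id = recs$id, representative = member),
                 threshold = threshold),
            class = "identity_clustering")
}

#' Subgroup classification from the KR2-74 column letter
#'
#' Sodium-pump rhodopsins split into two subgroups at the position
#' homologous to KR2 L74: glutamate (`E`) marks Subgroup2, leucine or
#' isoleucine (`L`/`I`) Subgroup1; anything else (including gaps) is
#' unassigned.
#'
#' @param letter Character vector of single letters.
#' @return Character vector: `"Subgroup1"`, `"Subgroup2"` or
#'   `"unassigned"`.
#' @export
classify_subgroup <- function(letter) {
  letter <- toupper(letter)
  dplyr::case_when(letter == "E" ~ "Subgroup2",
                   letter %in% c("L", "I") ~ "Subgroup1",
                   TRUE ~ "unassigned")
}

#' Full motif-classification pipeline
#'
#' Extracts motifs at the anchor columns, applies the motif / length /
#' duplicate filters, classifies each record's subgroup from the letter at
#' the subgroup column, and reduces the kept set by greedy identity
#' clustering.
#'
#' @param aln A [ref_alignment()].
#' @param spec A [motif_spec()].
#' @param subgroup_position Reference position of the subgroup site
#'   (default 74).
#' @param min_length Strict length filter (default 250).
#' @param identity_threshold Clustering threshold (default 0.90).
#' @param identity_mode Identity mode for clustering.
#' @return Tibble (`id`, `motif`, filter flags, `kept`,
#'   `subgroup_residue`, `subgroup`, `representative`); attribute
#'   `"clustering"` holds the [cluster_by_identity()] result for the kept
#'   set (NULL if nothing kept).
#' @export
classify_ndq <- function(aln, spec = motif_spec(), subgroup_position = 74,
                         min_length = 250, identity_threshold = 0.90,
                         identity_mode = "aligned") {
  flags <- apply_filters(aln, spec, min_length = min_length)
  sub_col <- build_reference_map(aln, subgroup_position)
  sub_letter <- substr(aln$seq, sub_col, sub_col)
  out <- flags |>
    dplyr::mutate(subgroup_residue = sub_letter,
                  subgroup = classify_subgroup(sub_letter))
  kept <- aln[out$kept, c("id", "seq")]
  clustering <- NULL
  out$representative <- NA_character_
  if (nrow(kept) > 0) {
    clustering <- cluster_by_identity(kept, threshold = identity_threshold,
                                      mode = identity_mode)
    out$representative <- clustering$membership$representative[
      match(out$id, clustering$membership$id)]
  }
  attr(out, "clustering") <- clustering
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Plumbing utility: builds an unrooted NJ tree (via ape) from a symmetric
#' distance matrix (e.g. `1 - identity`) and returns it in Newick form.
#' Additive distances are reproduced exactly.
#'
#' @param dist_matrix Symmetric numeric matrix, zero diagonal, >= 3 leaves,
#'   with row/column names as leaf labels.
#' @return Single Newick string.
#' @export
nj_tree <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 3) abort("need at least 3 leaves")
  if (!isSymmetric(unname(dist_matrix), tol = 1e-9)) abort("non-symmetric input")
  if (any(abs(diag(dist_matrix)) > 1e-12)) abort("diagonal must be zero")
  if (is.null(rownames(dist_matrix))) {
    rownames(dist_matrix) <- colnames(dist_matrix) <-
      paste0("t", seq_len(nrow(dist_matrix)))
  }
  tree <- ape::nj(dist_matrix)
  ape::write.tree(tree)
}

#' Pairwise identity matrix
#'
#' @param records Tibble with `id`, `seq`.
#' @param mode Identity mode, see [pairwise_identity()].
#' @return Symmetric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(records, mode = "aligned") {
  n <- nrow(records)
  M <- diag(1, n)
  dimnames(M) <- list(records$id, records$id)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <-
        pairwise_identity(records$seq[i], records$seq[j], mode = mode)
    }
  }
  M
}
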