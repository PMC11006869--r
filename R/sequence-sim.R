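AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random protein scaffold
#'
#' Uniform random 20-letter amino-acid string, used as the common backbone
#' of a synthetic aligned sequence family.
#'
#' @param length Scaffold length (residues).
#' @param seed Integer seed.
#' @return Single character string.
#' @export
random_scaffold <- function(length = 280, seed = 1L) {
  withr::local_seed(seed)
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

#' Generate a labelled aligned sequence family with planted motif
#'
#' Produces an aligned family in scaffold coordinates: every record carries
#' the planted motif residues at the motif columns and a class-specific
#' letter at the subgroup column; point mutations and gaps are introduced
#' everywhere else, so the planted columns are never touched and downstream
#' motif extraction / subgroup classification can be scored against exact
#' ground truth. The ungapped reference record (`reference_id`) is the
#' scaffold itself with the motif planted.
#'
#' Defaults emulate an NDQ-rhodopsin family: six anchor positions spelling
#' RNDQDK (KR2 numbering order 109, 112, 116, 123, 251, 216), subgroup
#' position 74 with Leu/Ile (Subgroup1) versus Glu (Subgroup2).
#'
#' @param scaffold Backbone string; default a [random_scaffold()] from `seed`.
#' @param motif_positions 1-based scaffold positions of the motif anchors,
#'   in motif spelling order.
#' @param motif_residues Letters planted at those positions (motif order).
#' @param subgroup_position 1-based scaffold position of the subgroup site.
#' @param subgroup_letters Named list: class -> allowed letters; each record
#'   of a class gets one of its letters (cycled deterministically).
#' @param n_per_class Named integer vector of records per class.
#' @param mutation_rate,gap_rate Per-position probabilities outside planted
#'   columns, in `[0, 1]`.
#' @param seed Integer seed.
#' @param reference_id Id of the emitted reference record.
#' @return List with `records` (tibble `id`, `seq`; reference row first),
#'   `labels` (tibble `id`, `class`, `subgroup_letter`), and
#'   `reference_id`.
#' @export
generate_sequence_family <- function(scaffold = NULL,
                                     motif_positions = c(109, 112, 116, 123, 251, 216),
                                     motif_residues = c("R", "N", "D", "Q", "D", "K"),
                                     subgroup_position = 74,
                                     subgroup_letters = list(Subgroup1 = c("L", "I"),
                                                             Subgroup2 = "E"),
                                     n_per_class = c(Subgroup1 = 10, Subgroup2 = 10),
                                     mutation_rate = 0.05, gap_rate = 0,
                                     seed = 1L, reference_id = "REF") {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, gap_rate >= 0, gap_rate <= 1,
            length(motif_positions) == length(motif_residues))
  if (is.null(scaffold)) scaffold <- random_scaffold(280, seed = seed)
  L <- nchar(scaffold)
  planted <- c(motif_positions, subgroup_position)
  if (anyDuplicated(planted)) abort("overlapping planted positions")
  if (any(planted < 1) || any(planted > L)) abort("planted positions outside scaffold")
  base <- strsplit(scaffold, "")[[1]]
  base[motif_positions] <- motif_residues

  withr::local_seed(seed)
  classes <- names(n_per_class)
  stopifnot(!is.null(classes), all(classes %in% names(subgroup_letters)))
  recs <- list(); labs <- list()
  for (cl in classes) {
    letters_cl <- subgroup_letters[[cl]]
    for (m in seq_len(n_per_class[[cl]])) {
      chars <- base
      sub_letter <- letters_cl[((m - 1) %% length(letters_cl)) + 1]
      chars[subgroup_position] <- sub_letter
      free <- setdiff(seq_len(L), planted)
      mut <- free[runif(length(free)) < mutation_rate]
      if (length(mut)) {
        chars[mut] <- vapply(chars[mut], function(a) sample(setdiff(AA20, a), 1), "")
      }
      gap <- free[runif(length(free)) < gap_rate]
      chars[gap] <- "-"
      id <- sprintf("%s_%03d", cl, m)
      recs[[id]] <- paste(chars, collapse = "")
      labs[[id]] <- tibble(id = id, class = cl, subgroup_letter = sub_letter)
    }
  }
  ref_chars <- base
  ref_chars[subgroup_position] <- subgroup_letters[[1]][1]
  records <- dplyr::bind_rows(
    tibble(id = reference_id, seq = paste(ref_chars, collapse = "")),
    tibble(id = names(recs), seq = unname(unlist(recs))))
  list(records = records, labels = dplyr::bind_rows(labs),
       reference_id = reference_id)
}

#' Read / write (aligned) FASTA as a tibble
#'
#' Thin wrappers around Biostrings FASTA I/O; sequences are returned as a
#' tibble with `id` and `seq` columns (gaps preserved).
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble (`id`, `seq`).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(id = names(ss), seq = as.character(ss))
}

#' @rdname read_fasta
#' @param records Tibble with `id`, `seq`.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
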