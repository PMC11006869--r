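test_that("reference map honours gaps and offsets", {
  gapless <- ref_alignment(tibble::tibble(id = c("R", "a"),
                                          seq = c("MNDQK", "MNDQX")),
                           reference_id = "R")
  expect_identical(unname(build_reference_map(gapless, 1:5)), 1:5)
  gapped <- ref_alignment(tibble::tibble(id = "R", seq = "M-AR"),
                          reference_id = "R")
  expect_identical(unname(build_reference_map(gapped, 2)), 3L)
  expect_error(build_reference_map(gapped, 4), "beyond reference length")
  off <- ref_alignment(tibble::tibble(id = "R", seq = "MAR"),
                       reference_id = "R", offset = 10)
  expect_identical(unname(build_reference_map(off, 11)), 2L)
})

test_that("reference map equals a brute-force scan on fuzzed alignments", {
  withr::local_seed(21)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    chars <- sample(c(strsplit("ACDEFG", "")[[1]], "-"), n, replace = TRUE,
                    prob = c(rep(1, 6), 2))
    if (all(chars == "-")) chars[1] <- "A"
    aln <- ref_alignment(tibble::tibble(id = "R", seq = paste(chars, collapse = "")),
                         reference_id = "R")
    n_res <- sum(chars != "-")
    pos <- sample(n_res, min(3, n_res))
    got <- build_reference_map(aln, pos)
    # oracle: scan columns counting non-gap characters
    oracle <- vapply(pos, function(p) {
      cnt <- 0
      for (cc in seq_along(chars)) {
        if (chars[cc] != "-") cnt <- cnt + 1
        if (cnt == p) return(cc)
      }
      NA_integer_
    }, integer(1))
    expect_identical(unname(got), oracle)
  }
})

test_that("motif extraction reads anchor columns in spelling order", {
  aln <- toy_alignment()  # ref "MRND-QDK"
  spec <- motif_spec(positions = c(2, 3, 4, 5, 7, 6),
                     allowed_letters = "RNDQKD")
  m <- extract_motif(aln, spec)
  expect_identical(m$motif[m$id == "KR2"], "RNDQKD")
  # gap at an anchor column yields '-' and fails the filter
  expect_identical(substr(m$motif[m$id == "s2"], 1, 1), "-")
  flags <- apply_filters(aln, spec, min_length = 3)
  expect_false(flags$motif_ok[flags$id == "s2"])
  expect_error(extract_motif(aln, spec, record_id = "nope"), "unknown record")
})

test_that("filters are strict on length and drop exact duplicates", {
  long <- paste(rep("A", 251), collapse = "")
  exact <- paste(rep("A", 250), collapse = "")
  aln <- ref_alignment(tibble::tibble(
    id = c("R", "len250", "dup1", "dup2"),
    seq = c(paste0("R", substr(long, 2, 251)),
            paste0(exact, "-"),
            paste0("R", substr(long, 2, 251)),
            paste0("C", substr(long, 2, 251)))), reference_id = "R")
  spec <- motif_spec(positions = 1, allowed_letters = list(c("R", "A", "C")))
  flags <- apply_filters(aln, spec, min_length = 250)
  expect_false(flags$kept[flags$id == "len250"])   # exactly 250 -> removed
  expect_false(flags$length_ok[flags$id == "len250"])
  expect_false(flags$kept[flags$id == "dup1"])     # duplicate of R
  expect_true(flags$kept[flags$id == "dup2"])
  # idempotence: re-filtering the kept set keeps everything
  kept <- aln[flags$kept, c("id", "seq")]
  aln2 <- ref_alignment(kept, reference_id = "R")
  flags2 <- apply_filters(aln2, spec, min_length = 250)
  expect_true(all(flags2$kept))
  expect_identical(flags2$motif, flags$motif[flags$kept])
})

test_that("planted pass/fail bookkeeping is exact", {
  fam <- generate_sequence_family(n_per_class = c(Subgroup1 = 5, Subgroup2 = 5),
                                  mutation_rate = 0.1, gap_rate = 0, seed = 13)
  # break the motif of two records at the first anchor column
  recs <- fam$records
  col <- unname(build_reference_map(ref_alignment(recs, "REF"), 109))
  broken <- c("Subgroup1_002", "Subgroup2_003")
  idx <- match(broken, recs$id)
  substr(recs$seq[idx], col, col) <- "G"
  aln <- ref_alignment(recs, reference_id = "REF")
  flags <- apply_filters(aln, motif_spec())
  expect_identical(sum(flags$kept), nrow(aln) - 2L)
  expect_identical(flags$id[!flags$kept], broken)
})

test_that("pairwise identity matches direct column counting", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("----", "AAAA"), "empty sequence")
  withr::local_seed(31)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    a <- sample(c("A", "C", "D", "-"), n, replace = TRUE)
    b <- sample(c("A", "C", "D", "-"), n, replace = TRUE)
    if (all(a == "-")) a[1] <- "A"
    if (all(b == "-")) b[1] <- "A"
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    oracle <- sum(a == b & a != "-") / min(sum(a != "-"), sum(b != "-"))
    expect_equal(pairwise_identity(sa, sb), oracle)
    expect_equal(pairwise_identity(sa, sb), pairwise_identity(sb, sa))
  }
  # unaligned mode finds the global alignment first
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL", mode = "unaligned"), 1.0)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDFGHIKL", mode = "unaligned"), 1.0)
})

test_that("greedy clustering honours its representative guarantees", {
  same <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ACDACD", 3))
  cl <- cluster_by_identity(same, 0.9)
  expect_length(cl$representatives, 1)
  distinct <- tibble::tibble(id = c("a", "b", "c"),
                             seq = c("AAAAAA", "CCCCCC", "DDDDDD"))
  expect_length(cluster_by_identity(distinct, 1.0)$representatives, 3)
  expect_error(cluster_by_identity(distinct, 0), "threshold")

  # planted clusters: 5 scaffolds ~50% identical, 4 members each at ~95%
  withr::local_seed(41)
  L <- 100
  base <- sample(c("A", "C"), L, replace = TRUE)
  recs <- list()
  for (g in 1:5) {
    scaf <- base
    flip <- sample(L, L / 2)
    scaf[flip] <- ifelse(scaf[flip] == "A", "C", "A")
    for (m in 1:4) {
      member <- scaf
      flip2 <- sample(L, 2)
      member[flip2] <- vapply(member[flip2], function(x) sample(setdiff(c("A", "C", "D", "E"), x), 1), "")
      recs[[sprintf("g%d_m%d", g, m)]] <- paste(member, collapse = "")
    }
  }
  tbl <- tibble::tibble(id = names(recs), seq = unlist(recs))
  cl5 <- cluster_by_identity(tbl, threshold = 0.90)
  expect_length(cl5$representatives, 5)
  # guarantee: members >= threshold to representative, reps mutually below
  for (i in seq_len(nrow(cl5$membership))) {
    r <- cl5$membership$representative[i]
    idv <- pairwise_identity(tbl$seq[tbl$id == cl5$membership$id[i]],
                             tbl$seq[tbl$id == r])
    expect_gte(idv, if (cl5$membership$id[i] == r) 1 else 0.90)
  }
  reps <- cl5$representatives
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i < j) expect_lt(pairwise_identity(tbl$seq[tbl$id == reps[i]],
                                           tbl$seq[tbl$id == reps[j]]), 0.90)
  }
})

test_that("subgroup rule maps the KR2-74 letter to clades", {
  expect_identical(classify_subgroup(c("E", "I", "L", "A", "-")),
                   c("Subgroup2", "Subgroup1", "Subgroup1", "unassigned",
                     "unassigned"))
})

test_that("NJ tree reproduces additive distances and sister pairings", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(D3)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # additive matrix from a known 4-leaf tree: branch lengths recovered
  true_tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D4 <- cophenetic(true_tree)
  rec <- ape::read.tree(text = nj_tree(D4))
  expect_equal(cophenetic(rec)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)
  # ultrametric case: A,B are sisters
  Du <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 4,
                 6, 6, 4, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tru <- ape::read.tree(text = nj_tree(Du))
  pair_dist <- cophenetic(tru)
  expect_lt(pair_dist["A", "B"], pair_dist["A", "C"])
  bad <- D3; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "non-symmetric")
  expect_error(nj_tree(D3[1:2, 1:2]), "3 leaves")
})

test_that("end-to-end classification matches generator ground truth", {
  fam <- generate_sequence_family(n_per_class = c(Subgroup1 = 8, Subgroup2 = 8),
                                  mutation_rate = 0.2, gap_rate = 0.02, seed = 17)
  aln <- ref_alignment(fam$records, reference_id = "REF")
  rep_ <- classify_ndq(aln)
  got <- rep_$subgroup[match(fam$labels$id, rep_$id)]
  expect_identical(got, fam$labels$class)
  expect_identical(rep_$subgroup_residue[match(fam$labels$id, rep_$id)],
                   fam$labels$subgroup_letter)
})
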