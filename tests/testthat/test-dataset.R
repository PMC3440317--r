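test_that("epitope records are validated, located and deduplicated", {
  ants <- toy_antigens()
  tab <- toy_epitope_table()
  recs <- suppressMessages(read_epitope_table(tab, ants))
  # e1 located by unique substring, e3 a duplicate of it, e4 unresolvable
  expect_identical(recs$epitope_id, c("e1", "e2"))
  expect_identical(substr(ants[["antA"]], recs$start[1] + 1, recs$end[1]),
                   "WQQPFDE")
  rej <- attr(recs, "rejected")
  expect_setequal(rej$reason, c("duplicate_epitope", "unresolved_antigen"))
})

test_that("span mismatches, missing substrings and T-cell records are rejected", {
  ants <- toy_antigens()
  tab <- data.frame(
    epitope_id = c("x1", "x2", "x3", "x4"),
    antigen_id = c("antA", "antA", "antA", "antB"),
    epitope_seq = c("WQQPFDE", "WWWYYY", "AAA", "HHQNPYW"),
    start = c(5L, NA, NA, NA), end = c(11L, NA, NA, NA),
    is_tcell_related = c(FALSE, FALSE, FALSE, TRUE))
  recs <- suppressMessages(read_epitope_table(tab, ants))
  expect_identical(nrow(recs), 0L)
  rej <- attr(recs, "rejected")
  expect_setequal(rej$reason, c("span_mismatch", "not_found_in_antigen",
                                "ambiguous_location", "tcell_related"))
})

test_that("length normalisation trims and extends symmetrically", {
  ant <- paste(AA_ALPHABET[rep(1:20, 3)], collapse = "")  # 60 residues
  # 24-mer at positions 11..34 (0-based 10..34) -> central 20
  w <- normalize_length(ant, 10L, 34L, 20L)
  expect_identical(w$peptide, substr(ant, 13, 32))
  expect_identical(c(w$start, w$end), c(12L, 32L))
  # 16-mer -> 2 appended each side
  w <- normalize_length(ant, 20L, 36L, 20L)
  expect_identical(c(w$start, w$end), c(18L, 38L))
  # odd adjustment leans toward the N-terminus
  w <- normalize_length(ant, 20L, 37L, 20L)   # 17-mer, extend by 3
  expect_identical(c(w$start, w$end), c(18L, 38L))  # 2 on N side, 1 on C side
})

test_that("normalisation at the antigen boundary uses the feasible side", {
  ant <- strrep("ACDEG", 8)                    # 40 residues
  w <- normalize_length(ant, 0L, 10L, 20L)     # epitope at position 0
  expect_identical(c(w$start, w$end), c(0L, 20L))  # all extension C-terminal
  # oracle: the returned window is the feasible window closest to the
  # symmetric ideal
  feasible <- 0:(nchar(ant) - 20L)
  ideal <- 0L - ceiling((20L - 10L) / 2)
  expect_identical(w$start, feasible[which.min(abs(feasible - ideal))])
  expect_null(normalize_length(strrep("A", 10), 0L, 5L, 20L))
})

test_that("redundancy reduction clusters by single linkage", {
  a <- paste0(strrep("W", 13), strrep("A", 7))   # W at 1..13
  b <- paste0(strrep("A", 6), strrep("W", 14))   # shares W at 7..13 with a
  c_ <- paste0(strrep("Y", 13), strrep("W", 7))  # shares W at 14..20 with b
  idm <- pairwise_identity(c(a, b, c_))
  expect_equal(idm[1, 2], 0.35)                  # a~b above ceiling
  expect_equal(idm[2, 3], 0.35)                  # b~c above ceiling
  expect_equal(idm[1, 3], 0)                     # a,c unrelated directly
  kept <- reduce_redundancy(c(a, b, c_), 0.30)
  expect_length(kept, 1L)              # transitive single-linkage merge
  expect_identical(kept[[1]], a)       # first by input order survives

  expect_length(reduce_redundancy(rep(strrep("A", 20), 2), 0.3), 1L)
})

test_that("dissimilar random peptides all survive reduction", {
  peps <- unique(rand_peptides(40, 20, seed = 21))
  idm <- pairwise_identity(peps)
  diag(idm) <- 0
  keepable <- max(idm) < 0.30          # oracle: exhaustive identity matrix
  kept <- reduce_redundancy(peps, 0.30)
  if (keepable) expect_length(kept, length(peps))
  # no retained pair may meet the ceiling directly
  idk <- pairwise_identity(kept)
  diag(idk) <- 0
  expect_lt(max(idk), 0.30)
})

test_that("negative sampling avoids every epitope span and is seeded", {
  ants <- toy_antigens()
  spans <- data.frame(antigen_id = c("antA", "antB"),
                      start = c(13L, 10L), end = c(20L, 17L))
  neg <- sample_negatives(ants, spans, L = 8L, n = 10L, seed = 7L)
  expect_identical(nrow(neg), 10L)
  expect_true(all(nchar(neg$peptide) == 8L))
  for (r in seq_len(nrow(neg))) {      # interval-intersection oracle
    sp <- spans[spans$antigen_id == neg$antigen_id[r], , drop = FALSE]
    if (nrow(sp) > 0)
      expect_true(all(neg$end[r] <= sp$start | neg$start[r] >= sp$end))
    expect_identical(substr(toy_antigens()[[neg$antigen_id[r]]],
                            neg$start[r] + 1, neg$end[r]), neg$peptide[r])
  }
  expect_identical(neg, sample_negatives(ants, spans, L = 8L, n = 10L,
                                         seed = 7L))
  # antigen fully covered by epitopes -> no eligible windows
  expect_error(
    sample_negatives(c(z = strrep("A", 30)),
                     data.frame(antigen_id = "z", start = 0L, end = 30L),
                     L = 10L, n = 1L),
    "eligible")
})

test_that("fold assignment balances clusters and enforces the ceiling", {
  expect_true(all(suppressWarnings(
    assign_folds(rep(strrep("A", 20), 8), k = 4)) == 1L))
  peps <- unique(rand_peptides(60, 20, seed = 31))
  folds <- assign_folds(peps, k = 5, identity_ceiling = 0.35, seed = 1)
  expect_lte(diff(range(tabulate(folds, 5))), 1L)
  # exhaustive cross-fold identity check
  idm <- pairwise_identity(peps)
  cross <- outer(folds, folds, "!=")
  expect_true(all(idm[cross] <= 0.35))
})

test_that("build_dataset yields a balanced, pure, deterministic dataset", {
  corpus <- generate_corpus(generator_spec(n_antigens = 40L, seed = 5L))
  ds <- suppressWarnings(build_dataset(corpus$antigens, corpus$epitopes,
                                       L = 20L, fold_ceiling = 0.35,
                                       seed = 5L))
  expect_identical(sum(ds$label == 1L), sum(ds$label == 0L))  # class balance
  expect_true(all(nchar(ds$peptide) == 20L))                  # homogeneity
  # negative purity against the annotated spans (0-based half-open)
  spans <- data.frame(antigen_id = corpus$epitopes$antigen_id,
                      start = corpus$epitopes$start - 1L,
                      end = corpus$epitopes$end)
  neg <- ds[ds$label == 0L, ]
  for (r in seq_len(nrow(neg))) {
    sp <- spans[spans$antigen_id == neg$antigen_id[r], , drop = FALSE]
    if (nrow(sp) > 0)
      expect_true(all(neg$end[r] <= sp$start | neg$start[r] >= sp$end))
  }
  # windows really are what the antigen says
  i <- which(ds$label == 1L)[1]
  expect_identical(substr(corpus$antigens[[ds$antigen_id[i]]],
                          ds$start[i] + 1, ds$end[i]), ds$peptide[i])
  # determinism: identical inputs and seed -> byte-identical manifests
  ds2 <- suppressWarnings(build_dataset(corpus$antigens, corpus$epitopes,
                                        L = 20L, fold_ceiling = 0.35,
                                        seed = 5L))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_manifest(ds, f1); write_manifest(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # manifest round trip
  back <- read_manifest(f1)
  expect_identical(back$peptide, ds$peptide)
  expect_identical(back$start, ds$start)
  expect_identical(attr(back, "L"), 20L)
})
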