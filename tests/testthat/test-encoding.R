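test_that("window projection follows the pattern geometry", {
  expect_length(extract_subsequences(strrep("A", 20)), 18L)
  expect_identical(extract_subsequences("ACDE", "AA_A"), "ACE")
  expect_identical(extract_subsequences("ACDE", "A_AA"), "ADE")
  expect_identical(extract_subsequences("AAAA"), c("AAA", "AAA"))
  # gapped windows span 4 residues, so an L-mer yields L-3 of them
  expect_length(extract_subsequences(strrep("C", 10), "AA_A"), 7L)
  expect_error(extract_subsequences("AC", "AAA"), "shorter")
  expect_error(extract_subsequences("ACXDE"), "position 3")
})

test_that("tri-peptide index is a stable lexicographic bijection", {
  idx <- tripeptide_index()
  expect_length(idx, 8000L)
  expect_false(anyDuplicated(idx) > 0)
  expect_identical(idx[1:3], c("AAA", "AAC", "AAD"))
  expect_identical(tripeptide_to_index(idx), seq_len(8000L))
})

test_that("similarity kernel matches the brute-force double loop", {
  expect_equal(similarity_vector("AAA", "blosum62")[["AAA"]], 12)
  set.seed(3)
  peps <- rand_peptides(6, 4:12, seed = 3)
  for (mat in c("blosum62", "pam160"))
    for (pat in c("AAA", "A_AA", "AA_A"))
      for (p in peps)
        expect_equal(similarity_vector(p, mat, pat),
                     brute_similarity(p, mat, pat))
})

test_that("spot attributes agree with per-attribute hand sums", {
  # no hidden dependence on attribute order: check individual named entries
  pep <- "WQQPF"
  M <- load_substitution_matrix("blosum62")
  v <- similarity_vector(pep, M, "AAA")
  wins <- extract_subsequences(pep)
  for (a in c("QQP", "AAA", "WYC")) {
    ac <- strsplit(a, "")[[1]]
    hand <- sum(vapply(wins, function(w) {
      wc <- strsplit(w, "")[[1]]
      M[ac[1], wc[1]] + M[ac[2], wc[2]] + M[ac[3], wc[3]]
    }, numeric(1)))
    expect_equal(v[[a]], hand)
  }
})

test_that("propensity frequencies match hand counts and normalise", {
  pos <- c("QQPA", "QQPQ", "AAA")   # windows: QQP,QPA | QQP,QPQ | AAA -> 5 total
  bg <- c("ACDEFGHIKLMNPQRSTVWY", "QQPW")
  pr <- compute_propensity(pos, bg)
  expect_equal(pr$f[tripeptide_to_index("QQP")], 2 / 5)
  expect_equal(pr$f[tripeptide_to_index("AAA")], 1 / 5)
  expect_equal(sum(pr$f), 1, tolerance = 1e-9)
  expect_equal(sum(pr$F), 1, tolerance = 1e-9)
  expect_true(all(pr$P > 0))
  expect_error(compute_propensity(character(0), bg), "empty")
})

test_that("identical positive and background pools give constant propensity", {
  pool <- c("QQPAW", "MKTAY", "GGSGG")
  pr <- compute_propensity(pool, pool)
  expect_true(all(abs(pr$P - 1) < 1e-12))
})

test_that("planted enrichment tops the propensity table", {
  pos <- rep("AQQPA", 30)           # every peptide carries QQP
  bg <- rand_peptides(50, 30, seed = 9)
  pr <- compute_propensity(pos, bg)
  expect_equal(pr$tripeptide[which.max(pr$P)] %in%
                 c("AQQ", "QQP", "QPA"), TRUE)
})

test_that("propensity table round-trips bit-exactly through TSV", {
  pr <- compute_propensity(rand_peptides(20, 15, seed = 5),
                           rand_peptides(40, 40, seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_propensity(pr, path)
  back <- read_propensity(path)
  expect_identical(pr$f, back$f)
  expect_identical(pr$F, back$F)
  expect_identical(pr$P, back$P)
  expect_identical(pr$pseudocount, back$pseudocount)
})

test_that("combined encoding is the similarity kernel modulated elementwise", {
  pos <- rand_peptides(10, 20, seed = 11)
  bg <- rand_peptides(30, 50, seed = 12)
  pr <- compute_propensity(pos, bg)
  cfg <- encoding_config(mode = "combined", propensity = pr)
  pep <- pos[1]
  expect_identical(encode_peptide(pep, cfg),
                   similarity_vector(pep, "blosum62") * pr$P)
})

test_that("unit propensity reduces combined mode to similarity only", {
  pool <- rand_peptides(8, 20, seed = 13)
  unit <- compute_propensity(pool, pool)     # P is identically 1
  cfg_c <- encoding_config(mode = "combined", propensity = unit)
  cfg_s <- encoding_config(mode = "similarity_only")
  for (p in pool[1:4])
    expect_identical(encode_peptide(p, cfg_c), encode_peptide(p, cfg_s))
})

test_that("propensity-only encoding is occurrence count times propensity", {
  pos <- c("QQPQQP", "AAAAA")
  bg <- rand_peptides(20, 40, seed = 14)
  pr <- compute_propensity(pos, bg)
  cfg <- encoding_config(mode = "propensity_only", propensity = pr)
  v <- encode_peptide("QQPQQPA", cfg)
  i <- tripeptide_to_index("QQP")
  expect_equal(v[[i]], 2 * pr$P[i])          # QQP occurs twice
  expect_equal(v[[tripeptide_to_index("AAA")]], 0)
  expect_length(v, 8000L)
})

test_that("modes needing a propensity refuse to run without one", {
  expect_error(encoding_config(mode = "combined"), "propensity")
  expect_error(encoding_config(mode = "propensity_only"), "propensity")
})

test_that("feature matrices are finite with 8000 columns in every mode", {
  pool <- rand_peptides(5, c(10, 20), seed = 15)
  pr <- compute_propensity(pool, rand_peptides(20, 50, seed = 16),
                           pattern = "AA_A")
  for (mode in c("combined", "similarity_only", "propensity_only")) {
    cfg <- encoding_config(mode = mode, pattern = "AA_A", propensity = pr)
    X <- encode_peptides(pool, cfg)
    expect_identical(dim(X), c(5L, 8000L))
    expect_true(all(is.finite(X)))
  }
})
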