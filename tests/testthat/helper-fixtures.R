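# shared fixtures; everything is generated in code, nothing read from disk

rand_peptides <- function(n, lens, seed = 1L) {
  set.seed(seed)
  lens <- if (length(lens) == 1L) rep.int(lens, n)
          else sample(lens, n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
    character(1))
}

# brute-force similarity kernel: explicit double loop over
# (attribute, window) pairs, the independent oracle for similarity_vector
brute_similarity <- function(peptide, matrix, pattern) {
  M <- if (is.character(matrix)) load_substitution_matrix(matrix) else matrix
  wins <- extract_subsequences(peptide, pattern)
  wchar <- matrix(unlist(strsplit(wins, "")), nrow = 3L)
  tris <- tripeptide_index()
  out <- numeric(length(tris))
  for (i in seq_along(tris)) {
    ac <- strsplit(tris[i], "")[[1L]]
    out[i] <- sum(M[ac[1L], wchar[1L, ]]) + sum(M[ac[2L], wchar[2L, ]]) +
      sum(M[ac[3L], wchar[3L, ]])
  }
  names(out) <- tris
  out
}

# exhaustive concordant-pair AUC (Mann-Whitney with ties at 1/2)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# a small hand-made antigen/epitope world for dataset tests
toy_antigens <- function() {
  c(antA = paste0("MKT", strrep("A", 10), "WQQPFDE", strrep("G", 10), "RST"),
    antB = paste0("MV", strrep("L", 8), "HHQNPYW", strrep("S", 8), "KR"),
    antC = paste(rep(c("D", "E", "K", "R"), 10), collapse = ""))
}

toy_epitope_table <- function() {
  data.frame(
    epitope_id = c("e1", "e2", "e3", "e4"),
    antigen_id = c("antA", "antB", "antA", "antD"),
    epitope_seq = c("WQQPFDE", "HHQNPYW", "WQQPFDE", "AAAA"),
    start = NA_integer_, end = NA_integer_,
    is_tcell_related = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# tiny trained model shared across test files (cached per session)
.fixture_cache <- new.env(parent = emptyenv())

tiny_benchmark <- function() {
  if (is.null(.fixture_cache$bm))
    .fixture_cache$bm <- synthetic_benchmark(n_per_class = 150L, seed = 42L,
                                             n_background = 60L)
  .fixture_cache$bm
}

tiny_model <- function() {
  if (is.null(.fixture_cache$model)) {
    bm <- tiny_benchmark()
    .fixture_cache$model <- train_model(bm$dataset, bm$background,
                                        config = svm_config(32, 0.05, 0.5))
  }
  .fixture_cache$model
}

# acceptance-scale benchmark runs, shared by several acceptance blocks
acceptance_run <- function(seed) {
  key <- paste0("acc", seed)
  if (is.null(.fixture_cache[[key]])) {
    bm <- synthetic_benchmark(n_per_class = 2000L, seed = seed)
    cfg <- svm_config(c = 32, g = 0.05, p = 0.5)
    cv_combined <- cross_validate(bm$dataset, bm$background, config = cfg,
                                  mode = "combined")
    cv_simonly <- cross_validate(bm$dataset, bm$background, config = cfg,
                                 mode = "similarity_only")
    model <- train_model(bm$dataset, bm$background, config = cfg)
    weights <- attribute_weights(model)
    .fixture_cache[[key]] <- list(bm = bm, cv_combined = cv_combined,
                                  cv_simonly = cv_simonly, model = model,
                                  weights = weights)
  }
  .fixture_cache[[key]]
}
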