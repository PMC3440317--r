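#' Subsequence window patterns
#'
#' The attribute space is always the 8000 tri-peptides, but the windows
#' projected from an input peptide can be contiguous (`AAA`) or "discrete":
#' a 4-residue window with one ignored position, either `A_AA` (gap after
#' the first compared residue) or `AA_A` (gap before the last). Gapped
#' windows still compare exactly three positions, so the attribute space
#' stays at \eqn{20^3}.
#'
#' @param kind `"AAA"` (alias `"contiguous"`), `"A_AA"` (alias
#'   `"gap_first"`) or `"AA_A"` (alias `"gap_last"`).
#' @return An object of class `"trip_pattern"` with fields `kind`,
#'   `offsets` (the compared positions within the window) and `width`
#'   (residues spanned: 3 contiguous, 4 gapped).
#' @export
subseq_pattern <- function(kind = c("AAA", "A_AA", "AA_A",
                                    "contiguous", "gap_first", "gap_last")) {
  kind <- match.arg(kind)
  kind <- switch(kind, contiguous = "AAA", gap_first = "A_AA",
                 gap_last = "AA_A", kind)
  offsets <- switch(kind,
    AAA  = c(1L, 2L, 3L),
    A_AA = c(1L, 3L, 4L),
    AA_A = c(1L, 2L, 4L))
  structure(list(kind = kind, offsets = offsets, width = max(offsets)),
            class = "trip_pattern")
}

as_trip_pattern <- function(pattern) {
  if (inherits(pattern, "trip_pattern")) pattern else subseq_pattern(pattern)
}

#' Project the tri-peptide windows of a peptide
#'
#' Slides the pattern window along the peptide and returns the projected
#' tri-peptides in order. A peptide of length L yields `L - width + 1`
#' windows; for a 20-mer under the contiguous pattern that is the 18
#' tri-peptides the similarity kernel sums over.
#'
#' @param peptide Single residue string over the 20-letter alphabet.
#' @param pattern A [subseq_pattern()] or its kind string.
#' @return Character vector of projected tri-peptides, in window order.
#' @examples
#' extract_subsequences("ACDE", "AA_A")   # "ACE"
#' @export
extract_subsequences <- function(peptide, pattern = "AAA") {
  pattern <- as_trip_pattern(pattern)
  ints <- peptide_ints(peptide)
  n <- length(ints) - pattern$width + 1L
  if (n < 1L)
    stop(sprintf("peptide of length %d is shorter than the %d-residue '%s' window",
                 length(ints), pattern$width, pattern$kind), call. = FALSE)
  starts <- seq_len(n)
  paste0(AA_ALPHABET[ints[starts + pattern$offsets[1L] - 1L]],
         AA_ALPHABET[ints[starts + pattern$offsets[2L] - 1L]],
         AA_ALPHABET[ints[starts + pattern$offsets[3L] - 1L]])
}

# window tri-peptide attribute indices for one integer-encoded peptide
window_indices <- function(ints, pattern) {
  n <- length(ints) - pattern$width + 1L
  if (n < 1L) stop("peptide shorter than the pattern window", call. = FALSE)
  starts <- seq_len(n)
  (ints[starts + pattern$offsets[1L] - 1L] - 1L) * 400L +
    (ints[starts + pattern$offsets[2L] - 1L] - 1L) * 20L +
     ints[starts + pattern$offsets[3L] - 1L]
}

#' Tri-peptide subsequence similarity kernel of one peptide
#'
#' For each attribute tri-peptide \eqn{\Phi^{(i)}}, sums the position-wise
#' substitution-matrix scores against every projected window
#' \eqn{\Omega_j} of the input:
#' \deqn{T^{(i)} = \sum_j \sum_{p=1}^{3} S(\Phi^{(i)}_p, \Omega_{jp}).}
#' Because the score decomposes over positions, the 8000-entry vector is
#' computed from three 20-bin residue counts and three matrix-vector
#' products rather than an 8000-by-windows double loop; the two routes are
#' checked against each other in the test-suite.
#'
#' @param peptide Single residue string.
#' @param matrix A substitution matrix from [load_substitution_matrix()]
#'   (or its name).
#' @param pattern A [subseq_pattern()] or kind string.
#' @return Numeric vector of length 8000 (the similarity-only feature
#'   vector), named by tri-peptide.
#' @examples
#' v <- similarity_vector("AAA", "blosum62")
#' v[["AAA"]]   # 12: one window, three A:A pairs at self-score 4
#' @export
similarity_vector <- function(peptide, matrix = "blosum62", pattern = "AAA") {
  if (is.character(matrix)) matrix <- load_substitution_matrix(matrix)
  pattern <- as_trip_pattern(pattern)
  ints <- peptide_ints(peptide)
  n <- length(ints) - pattern$width + 1L
  if (n < 1L)
    stop(sprintf("peptide of length %d is shorter than the %d-residue '%s' window",
                 length(ints), pattern$width, pattern$kind), call. = FALSE)
  starts <- seq_len(n)
  v <- numeric(N_TRIPEPTIDES)
  u <- vector("list", 3L)
  for (p in 1:3) {
    counts <- tabulate(ints[starts + pattern$offsets[p] - 1L], nbins = 20L)
    u[[p]] <- as.numeric(matrix %*% counts)
  }
  v <- u[[1L]][.tri_pos1] + u[[2L]][.tri_pos2] + u[[3L]][.tri_pos3]
  names(v) <- tripeptide_index()
  v
}

#' Tri-peptide propensity table
#'
#' Estimates, for every tri-peptide, its frequency `f` among windows of the
#' positive (epitope) peptides and its frequency `F` among windows of a
#' background protein pool, and forms the propensity
#' \deqn{P^{(i)} = (f(i) + \epsilon) / (F(i) + \epsilon)} with a pseudocount
#' \eqn{\epsilon} that keeps `P` finite for tri-peptides absent from the
#' background. `f` and `F` are plain window frequencies (each sums to 1);
#' the pseudocount enters only the ratio.
#'
#' @param positives Character vector of epitope peptides (or `AAStringSet`).
#' @param background Character vector of background sequences (full-length
#'   proteins are fine; all their windows are counted) or `AAStringSet`.
#' @param pseudocount Smoothing constant \eqn{\epsilon}; default
#'   `1 / (total windows counted in both pools)`.
#' @param pattern Window pattern used for counting; defaults to contiguous
#'   and should match the encoding pattern.
#' @return Object of class `"trip_propensity"`: a list with `tripeptide`,
#'   `f`, `F`, `P` (length-8000 numeric vectors), `pseudocount`, `pattern`.
#' @export
compute_propensity <- function(positives, background, pseudocount = NULL,
                               pattern = "AAA") {
  pattern <- as_trip_pattern(pattern)
  positives <- as_peptide_chars(positives)
  background <- as_peptide_chars(background)
  if (length(positives) == 0L) stop("empty positive peptide collection")
  if (length(background) == 0L) stop("empty background collection")
  cpos <- count_windows(positives, pattern)
  cbg <- count_windows(background, pattern)
  npos <- sum(cpos); nbg <- sum(cbg)
  if (npos == 0L) stop("no countable windows in positives")
  if (nbg == 0L) stop("no countable windows in background")
  if (is.null(pseudocount)) pseudocount <- 1 / (npos + nbg)
  f <- cpos / npos
  F <- cbg / nbg
  if (all(F + pseudocount == 0))
    stop("background has zero mass after smoothing")
  P <- (f + pseudocount) / (F + pseudocount)
  structure(list(tripeptide = tripeptide_index(), f = f, F = F, P = P,
                 pseudocount = pseudocount, pattern = pattern$kind),
            class = "trip_propensity")
}

# sum of per-tri-peptide window counts over a peptide collection
count_windows <- function(peptides, pattern) {
  counts <- integer(N_TRIPEPTIDES)
  for (p in peptides) {
    ints <- peptide_ints(p)
    if (length(ints) < pattern$width) next
    counts <- counts + tabulate(window_indices(ints, pattern),
                                nbins = N_TRIPEPTIDES)
  }
  counts
}

as_peptide_chars <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  unname(x)
}

#' @export
print.trip_propensity <- function(x, ...) {
  occupied <- sum(x$f > 0)
  cat(sprintf(
    "trip_propensity: %d/%d tri-peptides seen in positives (pattern %s, eps %.3g)\n",
    occupied, N_TRIPEPTIDES, x$pattern, x$pseudocount))
  top <- order(x$P, decreasing = TRUE)[1:5]
  cat("top propensities:",
      paste(sprintf("%s=%.2f", x$tripeptide[top], x$P[top]), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a propensity table as TSV
#'
#' Tab-delimited with columns `tripeptide`, `f`, `F`, `P`; full double
#' precision (17 significant digits) so a write/read round trip is
#' bit-exact.
#'
#' @param x A `"trip_propensity"`.
#' @param path File path.
#' @return `read_propensity` returns the `"trip_propensity"`;
#'   `write_propensity` returns `path` invisibly.
#' @export
write_propensity <- function(x, path) {
  stopifnot(inherits(x, "trip_propensity"))
  header <- sprintf("# pattern=%s pseudocount=%.17g", x$pattern, x$pseudocount)
  lines <- c(header, "tripeptide\tf\tF\tP",
             sprintf("%s\t%.17g\t%.17g\t%.17g", x$tripeptide, x$f, x$F, x$P))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_propensity
#' @export
read_propensity <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)][1L]
  pattern <- sub(".*pattern=(\\S+).*", "\\1", meta)
  eps <- as.numeric(sub(".*pseudocount=(\\S+).*", "\\1", meta))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  ord <- match(tripeptide_index(), tab$tripeptide)
  if (anyNA(ord)) stop("propensity table does not cover all 8000 tri-peptides")
  structure(list(tripeptide = tripeptide_index(), f = tab$f[ord],
                 F = tab$F[ord], P = tab$P[ord],
                 pseudocount = eps, pattern = pattern),
            class = "trip_propensity")
}

#' Encoding configuration
#'
#' Bundles everything needed to map a peptide to its 8000-entry attribute
#' vector: the substitution matrix, the window pattern, the encoding mode,
#' and (for modes that use it) the propensity table.
#'
#' Modes:
#' * `combined` — \eqn{K^{(i)} = T^{(i)} \cdot P^{(i)}}: similarity kernel
#'   modulated by propensity (the full model);
#' * `similarity_only` — \eqn{K^{(i)} = T^{(i)}} (the "without propensity"
#'   ablation);
#' * `propensity_only` — \eqn{K^{(i)} = c_i \cdot P^{(i)}} where `c_i` is
#'   the occurrence count of tri-peptide `i` in the peptide (no
#'   substitution matrix consulted).
#'
#' @param matrix Substitution matrix name or object (`blosum62` default).
#' @param pattern Window pattern (default contiguous `"AAA"`).
#' @param mode One of `"combined"`, `"similarity_only"`, `"propensity_only"`.
#' @param propensity A [compute_propensity()] table; required unless
#'   `mode = "similarity_only"`.
#' @return Object of class `"trip_encoding"`.
#' @export
encoding_config <- function(matrix = "blosum62", pattern = "AAA",
                            mode = c("combined", "similarity_only",
                                     "propensity_only"),
                            propensity = NULL) {
  mode <- match.arg(mode)
  if (is.character(matrix)) matrix <- load_substitution_matrix(matrix)
  pattern <- as_trip_pattern(pattern)
  if (mode != "similarity_only") {
    if (is.null(propensity))
      stop("mode '", mode, "' requires a propensity table", call. = FALSE)
    stopifnot(inherits(propensity, "trip_propensity"))
    if (propensity$pattern != pattern$kind)
      warning("propensity table was counted with pattern ", propensity$pattern,
              " but encoding uses ", pattern$kind)
  }
  structure(list(matrix = matrix, matrix_name = attr(matrix, "name"),
                 pattern = pattern, mode = mode, propensity = propensity),
            class = "trip_encoding")
}

#' @export
print.trip_encoding <- function(x, ...) {
  cat(sprintf("trip_encoding: mode=%s matrix=%s pattern=%s propensity=%s\n",
              x$mode, x$matrix_name %||% "none", x$pattern$kind,
              if (is.null(x$propensity)) "none" else "attached"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a peptide into the tri-peptide attribute space
#'
#' @param peptide Single residue string.
#' @param config An [encoding_config()].
#' @return Named numeric vector of length 8000 (raw attribute scores; any
#'   normalisation is applied downstream at the model layer).
#' @export
encode_peptide <- function(peptide, config) {
  stopifnot(inherits(config, "trip_encoding"))
  switch(config$mode,
    similarity_only = similarity_vector(peptide, config$matrix, config$pattern),
    combined = similarity_vector(peptide, config$matrix, config$pattern) *
               config$propensity$P,
    propensity_only = {
      ints <- peptide_ints(peptide)
      counts <- tabulate(window_indices(ints, config$pattern),
                         nbins = N_TRIPEPTIDES)
      v <- counts * config$propensity$P
      names(v) <- tripeptide_index()
      v
    })
}

#' Encode a collection of peptides into a feature matrix
#'
#' @param peptides Character vector of equal-treatment peptides (lengths may
#'   vary; each yields its own window set).
#' @param config An [encoding_config()].
#' @return Numeric matrix, one row per peptide, 8000 columns.
#' @export
encode_peptides <- function(peptides, config) {
  peptides <- as_peptide_chars(peptides)
  B <- encode_base_matrix(peptides, config$matrix, config$pattern, config$mode)
  X <- apply_propensity(B, config)
  rownames(X) <- names(peptides)
  X
}

# mode-agnostic, propensity-free part of the encoding: the similarity kernel
# matrix (combined / similarity_only) or the window count matrix
# (propensity_only). Fold-dependent propensities can then be applied as a
# cheap column scaling without re-walking the sequences.
encode_base_matrix <- function(peptides, matrix, pattern, mode) {
  if (is.character(matrix)) matrix <- load_substitution_matrix(matrix)
  pattern <- as_trip_pattern(pattern)
  peptides <- as_peptide_chars(peptides)
  n <- length(peptides)
  X <- matrix(0, nrow = n, ncol = N_TRIPEPTIDES)
  if (mode == "propensity_only") {
    for (k in seq_len(n)) {
      ints <- peptide_ints(peptides[[k]])
      X[k, ] <- tabulate(window_indices(ints, pattern), nbins = N_TRIPEPTIDES)
    }
  } else {
    M <- matrix
    for (k in seq_len(n)) {
      ints <- peptide_ints(peptides[[k]])
      nw <- length(ints) - pattern$width + 1L
      if (nw < 1L)
        stop("peptide ", k, " shorter than the pattern window", call. = FALSE)
      starts <- seq_len(nw)
      u1 <- as.numeric(M %*% tabulate(ints[starts + pattern$offsets[1L] - 1L], 20L))
      u2 <- as.numeric(M %*% tabulate(ints[starts + pattern$offsets[2L] - 1L], 20L))
      u3 <- as.numeric(M %*% tabulate(ints[starts + pattern$offsets[3L] - 1L], 20L))
      X[k, ] <- u1[.tri_pos1] + u2[.tri_pos2] + u3[.tri_pos3]
    }
  }
  X
}

apply_propensity <- function(B, config) {
  if (config$mode == "similarity_only") return(B)
  B * rep(config$propensity$P, each = nrow(B))
}

# L2 row normalisation; zero rows left untouched
l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  nrm[nrm == 0] <- 1
  X / nrm
}
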