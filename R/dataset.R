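#' Read and validate an epitope annotation table
#'
#' Reads a tab-delimited table of linear-epitope annotations (columns
#' `epitope_id`, `antigen_id`, `epitope_seq`, and optionally `start`,
#' `end` — 1-based inclusive — and `is_tcell_related`) together with the
#' antigen sequences, and validates every record: the antigen id must
#' resolve, the epitope must match the antigen at the stated span (or be
#' locatable by a unique exact substring search when the span is absent),
#' residues must be canonical, and T-cell-related records are dropped.
#' Identical epitope sequences are collapsed to the first occurrence.
#'
#' @param path TSV file, or a data.frame with the same columns.
#' @param antigens FASTA path or a named `AAStringSet`/character vector.
#' @return data.frame of validated records with columns `epitope_id`,
#'   `antigen_id`, `epitope_seq`, `start`, `end` (0-based half-open,
#'   internal convention). Rejected records (with reasons) are attached as
#'   `attr(, "rejected")`.
#' @export
read_epitope_table <- function(path, antigens) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  ant <- as_antigen_set(antigens)
  need <- c("antigen_id", "epitope_seq")
  if (!all(need %in% names(tab)))
    stop("epitope table must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$epitope_id)) tab$epitope_id <- sprintf("ep%05d", seq_len(nrow(tab)))
  if (is.null(tab$start)) tab$start <- NA_integer_
  if (is.null(tab$end)) tab$end <- NA_integer_
  if (is.null(tab$is_tcell_related)) tab$is_tcell_related <- FALSE
  tab$is_tcell_related[is.na(tab$is_tcell_related)] <- FALSE

  keep <- logical(nrow(tab))
  reason <- character(nrow(tab))
  start0 <- integer(nrow(tab)); end0 <- integer(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    ep <- toupper(tab$epitope_seq[r])
    if (isTRUE(tab$is_tcell_related[r] == TRUE)) { reason[r] <- "tcell_related"; next }
    aseq <- ant[[tab$antigen_id[r]]]
    if (is.null(aseq)) { reason[r] <- "unresolved_antigen"; next }
    if (!is_standard_peptide(ep)) { reason[r] <- "nonstandard_residue"; next }
    if (!is.na(tab$start[r]) && !is.na(tab$end[r])) {
      s <- as.integer(tab$start[r]); e <- as.integer(tab$end[r])
      if (s < 1L || e > nchar(aseq) || e - s + 1L != nchar(ep) ||
          substr(aseq, s, e) != ep) { reason[r] <- "span_mismatch"; next }
      start0[r] <- s - 1L; end0[r] <- e
    } else {
      hits <- gregexpr(ep, aseq, fixed = TRUE)[[1L]]
      hits <- hits[hits > 0L]
      if (length(hits) == 0L) { reason[r] <- "not_found_in_antigen"; next }
      if (length(hits) > 1L) { reason[r] <- "ambiguous_location"; next }
      start0[r] <- hits - 1L; end0[r] <- hits - 1L + nchar(ep)
    }
    keep[r] <- TRUE
  }
  recs <- data.frame(epitope_id = tab$epitope_id, antigen_id = tab$antigen_id,
                     epitope_seq = toupper(tab$epitope_seq),
                     start = start0, end = end0,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  dup <- duplicated(recs$epitope_seq)
  rejected <- rbind(
    data.frame(epitope_id = tab$epitope_id[!keep],
               reason = reason[!keep], stringsAsFactors = FALSE),
    data.frame(epitope_id = recs$epitope_id[dup],
               reason = rep("duplicate_epitope", sum(dup)),
               stringsAsFactors = FALSE))
  recs <- recs[!dup, , drop = FALSE]
  rownames(recs) <- NULL
  if (nrow(rejected) > 0L)
    message(nrow(rejected), " epitope record(s) rejected (",
            paste(sprintf("%s: %d", names(table(rejected$reason)),
                          table(rejected$reason)), collapse = ", "), ")")
  attr(recs, "rejected") <- rejected
  recs
}

as_antigen_set <- function(antigens) {
  if (is.character(antigens) && length(antigens) == 1L && file.exists(antigens))
    antigens <- Biostrings::readAAStringSet(antigens)
  if (methods::is(antigens, "XStringSet")) antigens <- as.character(antigens)
  if (is.list(antigens)) antigens <- unlist(antigens)
  stopifnot(is.character(antigens), !is.null(names(antigens)))
  names(antigens) <- sub("\\s.*$", "", names(antigens))
  as.list(toupper(antigens))
}

#' Normalise an epitope to a fixed peptide length
#'
#' Long epitopes are trimmed symmetrically about their centre; short ones
#' are extended symmetrically into the antigen. When the adjustment is odd,
#' the window leans toward the N-terminus (one fewer residue trimmed from,
#' or one more added to, the N-terminal side). If a symmetric window would
#' overrun the antigen it is shifted back inside; if the antigen cannot
#' supply `L` residues at all, `NULL` is returned.
#'
#' @param antigen_seq Full antigen sequence.
#' @param start,end Epitope span, 0-based half-open.
#' @param L Target peptide length.
#' @return List with `peptide`, `start`, `end` (0-based half-open window in
#'   the antigen), or `NULL` when infeasible.
#' @export
normalize_length <- function(antigen_seq, start, end, L) {
  alen <- nchar(antigen_seq)
  stopifnot(start >= 0L, end <= alen, end > start)
  if (alen < L) return(NULL)
  extra <- L - (end - start)
  ns <- start - ceiling(extra / 2)
  ns <- min(max(ns, 0L), alen - L)
  list(peptide = substr(antigen_seq, ns + 1L, ns + L),
       start = as.integer(ns), end = as.integer(ns + L))
}

#' Pairwise sequence identity of equal-length peptides
#'
#' Identity is the fraction of positions carrying the same residue in an
#' ungapped position-by-position comparison (identical positions / L) —
#' the desk-scale stand-in for an alignment-based similarity.
#'
#' @param peptides Character vector of equal-length peptides.
#' @return Symmetric numeric matrix of identity fractions.
#' @export
pairwise_identity <- function(peptides) {
  peptides <- as_peptide_chars(peptides)
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must all have equal length")
  ints <- t(vapply(peptides, peptide_ints, integer(L)))
  pairwise_match_counts(ints) / L
}

# single-linkage clusters of peptides whose identity meets `ceiling`
# under comparison `op` (">=" for redundancy reduction, ">" for folds)
cluster_peptides <- function(peptides, ceiling, op = c(">=", ">")) {
  op <- match.arg(op)
  n <- length(peptides)
  if (n == 0L) return(integer(0))
  idm <- pairwise_identity(peptides)
  hit <- if (op == ">=") idm >= ceiling else idm > ceiling
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    js <- which(hit[i, (i + 1L):n]) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Remove redundant peptides by single-linkage identity clustering
#'
#' Peptides with pairwise identity at or above the ceiling are clustered
#' (single linkage, so chains are merged transitively) and only the first
#' member of each cluster, by input order, is retained. Callers wanting a
#' specific representative should pre-sort deterministically.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param identity_ceiling Identity fraction at which two peptides are
#'   considered redundant (default 0.30).
#' @return The retained peptides, with `attr(, "kept_index")` giving their
#'   positions in the input and `attr(, "cluster")` the full cluster
#'   assignment.
#' @export
reduce_redundancy <- function(peptides, identity_ceiling = 0.30) {
  peptides <- as_peptide_chars(peptides)
  cl <- cluster_peptides(peptides, identity_ceiling, op = ">=")
  kept <- which(!duplicated(cl))
  out <- peptides[kept]
  attr(out, "kept_index") <- kept
  attr(out, "cluster") <- cl
  out
}

#' Sample negative peptides from non-epitopic antigen segments
#'
#' Draws `n` length-`L` windows uniformly at random (seeded) from the set
#' of all antigen windows that have zero overlap with any annotated
#' epitope span of their antigen. Windows containing non-standard residues
#' are ineligible, and duplicate sequences are excluded from the sample.
#'
#' @param antigens Named character vector / `AAStringSet` / FASTA path.
#' @param epitope_spans data.frame with `antigen_id`, `start`, `end`
#'   (0-based half-open) of every annotated epitope.
#' @param L Window length.
#' @param n Number of negatives required.
#' @param seed Integer seed; fixed seed gives an identical sample.
#' @return data.frame `peptide`, `antigen_id`, `start`, `end`
#'   (0-based half-open).
#' @export
sample_negatives <- function(antigens, epitope_spans, L, n, seed = 1L) {
  ant <- as_antigen_set(antigens)
  elig <- eligible_windows(ant, epitope_spans, L)
  if (nrow(elig) == 0L)
    stop("no eligible non-epitopic windows of length ", L, call. = FALSE)
  ord <- with_seed(seed, sample.int(nrow(elig)))
  elig <- elig[ord, , drop = FALSE]
  first <- !duplicated(elig$peptide)
  picked <- which(first)
  if (length(picked) < n)
    stop(sprintf(
      "insufficient eligible windows: need %d unique negatives, only %d available",
      n, length(picked)), call. = FALSE)
  out <- elig[picked[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

eligible_windows <- function(ant, epitope_spans, L) {
  res <- vector("list", length(ant))
  ids <- names(ant)
  for (k in seq_along(ant)) {
    aseq <- ant[[k]]
    alen <- nchar(aseq)
    if (alen < L) next
    starts <- 0:(alen - L)
    spans <- epitope_spans[epitope_spans$antigen_id == ids[k], , drop = FALSE]
    if (nrow(spans) > 0L) {
      win <- IRanges::IRanges(start = starts + 1L, width = L)
      epi <- IRanges::IRanges(start = spans$start + 1L,
                              end = spans$end)
      starts <- starts[IRanges::countOverlaps(win, epi) == 0L]
    }
    if (length(starts) == 0L) next
    peps <- substring(aseq, starts + 1L, starts + L)
    ok <- is_standard_peptide(peps)
    if (!any(ok)) next
    res[[k]] <- data.frame(peptide = peps[ok], antigen_id = ids[k],
                           start = starts[ok], end = starts[ok] + L,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    data.frame(peptide = character(), antigen_id = character(),
               start = integer(), end = integer())
  else out
}

#' Similarity-aware fold assignment
#'
#' Peptides more similar than the cross-fold ceiling are first merged into
#' single-linkage clusters, which are then distributed whole to `k` folds
#' by greedy size balancing (largest cluster first, to the currently
#' smallest fold). The result guarantees that no two peptides in different
#' folds exceed the identity ceiling.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param k Number of folds.
#' @param identity_ceiling Maximum allowed cross-fold identity (default
#'   0.20).
#' @param seed Seed used to break ties among equal-size clusters.
#' @return Integer fold ids in `1..k`, one per peptide.
#' @export
assign_folds <- function(peptides, k = 5L, identity_ceiling = 0.20, seed = 1L) {
  stopifnot(k >= 2L)
  peptides <- as_peptide_chars(peptides)
  cl <- cluster_peptides(peptides, identity_ceiling, op = ">")
  sizes <- tabulate(cl)
  if (max(sizes) > length(peptides) / 2)
    warning(sprintf(
      "one similarity cluster holds %d of %d peptides; folds will be imbalanced",
      max(sizes), length(peptides)))
  jitter <- with_seed(seed, stats::runif(length(sizes)))
  cl_order <- order(-sizes, jitter)
  fold_load <- integer(k)
  fold_of_cluster <- integer(length(sizes))
  for (c_id in cl_order) {
    target <- which.min(fold_load)
    fold_of_cluster[c_id] <- target
    fold_load[target] <- fold_load[target] + sizes[c_id]
  }
  fold_of_cluster[cl]
}

#' Build a labelled, non-redundant, fold-assigned epitope dataset
#'
#' Runs the full dataset-preparation pipeline: validate annotations,
#' normalise epitopes to length `L`, remove redundant positives
#' (single-linkage identity clustering at `identity_ceiling`), sample an
#' equal number of negatives from non-epitopic segments, and assign
#' similarity-aware folds (cross-fold identity at most `fold_ceiling`)
#' jointly over positives and negatives.
#'
#' @param antigens FASTA path / named character / `AAStringSet`.
#' @param epitopes Epitope table (path or data.frame, see
#'   [read_epitope_table()]), or an already-validated record set.
#' @param L Peptide length, one of 10, 12, 14, 16, 18, 20 (default 20).
#' @param k Number of folds (default 5).
#' @param identity_ceiling Redundancy ceiling among positives (default 0.30).
#' @param fold_ceiling Cross-fold identity ceiling (default 0.20).
#' @param seed Integer seed for negative sampling and fold tie-breaking.
#' @return A `"trip_dataset"`: data.frame with columns `peptide`, `label`
#'   (1 positive / 0 negative), `fold`, `antigen_id`, `start`, `end`
#'   (0-based half-open window in the antigen), with attributes `L` and
#'   `seed`.
#' @export
build_dataset <- function(antigens, epitopes, L = 20L, k = 5L,
                          identity_ceiling = 0.30, fold_ceiling = 0.20,
                          seed = 1L) {
  stopifnot(L %in% c(10L, 12L, 14L, 16L, 18L, 20L))
  ant <- as_antigen_set(antigens)
  recs <- if (is.data.frame(epitopes) && !is.null(attr(epitopes, "rejected")))
    epitopes else read_epitope_table(epitopes, antigens)
  recs <- recs[order(recs$antigen_id, recs$epitope_id), , drop = FALSE]

  pos <- vector("list", nrow(recs))
  for (r in seq_len(nrow(recs))) {
    w <- normalize_length(ant[[recs$antigen_id[r]]], recs$start[r],
                          recs$end[r], L)
    if (is.null(w) || !is_standard_peptide(w$peptide)) next
    pos[[r]] <- data.frame(peptide = w$peptide,
                           antigen_id = recs$antigen_id[r],
                           start = w$start, end = w$end,
                           stringsAsFactors = FALSE)
  }
  pos <- do.call(rbind, pos[!vapply(pos, is.null, logical(1))])
  if (is.null(pos) || nrow(pos) == 0L)
    stop("no epitope could be normalised to length ", L, call. = FALSE)
  pos <- pos[!duplicated(pos$peptide), , drop = FALSE]

  kept <- reduce_redundancy(pos$peptide, identity_ceiling)
  pos <- pos[attr(kept, "kept_index"), , drop = FALSE]

  neg <- sample_negatives(ant, recs[, c("antigen_id", "start", "end")],
                          L = L, n = nrow(pos), seed = seed)

  dat <- rbind(cbind(pos, label = 1L),
               cbind(neg[, c("peptide", "antigen_id", "start", "end")],
                     label = 0L))
  dat$fold <- assign_folds(dat$peptide, k = k,
                           identity_ceiling = fold_ceiling, seed = seed)
  dat <- dat[, c("peptide", "label", "fold", "antigen_id", "start", "end")]
  rownames(dat) <- NULL
  structure(dat, L = L, seed = seed, class = c("trip_dataset", "data.frame"))
}

#' Write / read a dataset manifest as TSV
#'
#' Columns `peptide`, `label`, `fold`, `antigen_id`, `start`, `end`; spans
#' are written 1-based inclusive (the human-readable convention) and
#' converted back on read.
#'
#' @param dataset A `"trip_dataset"`.
#' @param path File path.
#' @export
write_manifest <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out$start <- out$start + 1L  # 1-based inclusive on disk
  header <- sprintf("# tripitope dataset L=%d seed=%d", attr(dataset, "L"),
                    attr(dataset, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)][1L]
  L <- as.integer(sub(".*L=(\\d+).*", "\\1", meta))
  seed <- as.integer(sub(".*seed=(\\d+).*", "\\1", meta))
  dat <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  dat$start <- dat$start - 1L
  structure(dat, L = L, seed = seed, class = c("trip_dataset", "data.frame"))
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
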