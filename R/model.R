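#' Train a full epitope prediction model
#'
#' Computes the tri-peptide propensity table from all positive peptides
#' against the background pool, encodes every peptide into the 8000-entry
#' attribute space, L2-normalises the vectors (see Details) and fits the
#' RBF-kernel support vector classifier. The returned object bundles the
#' SVM (dual coefficients and support vectors), the complete encoding
#' configuration and the propensity table, so any new peptide can be
#' re-encoded and scored identically.
#'
#' @details Raw similarity-kernel entries grow with the window count and
#' the substitution-score scale, which would make the conventional RBF
#' grid (`g` around 0.05) degenerate; encoded vectors are therefore
#' projected to the unit sphere before the kernel (disable with
#' `normalize = FALSE`).
#'
#' @param dataset A `"trip_dataset"` (or data.frame with `peptide`,
#'   `label`).
#' @param background Background sequences for the propensity denominator
#'   (character / `AAStringSet` / FASTA path).
#' @param config An [svm_config()] triplet.
#' @param matrix,pattern,mode Encoding settings, see [encoding_config()].
#' @param normalize L2-normalise feature vectors (default `TRUE`).
#' @param pseudocount Propensity smoothing, see [compute_propensity()].
#' @return Object of class `"trip_model"`.
#' @export
train_model <- function(dataset, background, config = svm_config(),
                        matrix = "blosum62", pattern = "AAA",
                        mode = "combined", normalize = TRUE,
                        pseudocount = NULL) {
  stopifnot(inherits(config, "trip_svm_config"))
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- Biostrings::readAAStringSet(background)
  background <- as_peptide_chars(background)
  peptides <- dataset$peptide
  y <- dataset$label
  enc <- build_encoding(peptides[y == 1L], background, matrix, pattern, mode,
                        pseudocount)
  X <- encode_peptides(peptides, enc)
  if (normalize) X <- l2_normalize_rows(X)
  svm <- svm_train(X, y, cost = config$c, gamma = config$g,
                   epsilon = config$p)
  structure(list(svm = svm, encoding = enc, config = config,
                 L = attr(dataset, "L") %||% unique(nchar(peptides))[1L],
                 normalize = normalize),
            class = "trip_model")
}

build_encoding <- function(positives, background, matrix, pattern, mode,
                           pseudocount) {
  prop <- if (mode != "similarity_only")
    compute_propensity(positives, background, pseudocount = pseudocount,
                       pattern = pattern) else NULL
  encoding_config(matrix = matrix, pattern = pattern, mode = mode,
                  propensity = prop)
}

#' @export
print.trip_model <- function(x, ...) {
  cat(sprintf("trip_model: L=%d, mode=%s, matrix=%s, pattern=%s\n",
              x$L, x$encoding$mode, x$encoding$matrix_name,
              x$encoding$pattern$kind))
  print(x$svm)
  invisible(x)
}

#' Score peptides with a trained model
#'
#' @param model A `"trip_model"`.
#' @param peptides Character vector of peptides (typically of the model's
#'   training length).
#' @return Real-valued decision scores; a positive score calls the peptide
#'   a putative epitope.
#' @export
score_peptides <- function(model, peptides) {
  stopifnot(inherits(model, "trip_model"))
  X <- encode_peptides(peptides, model$encoding)
  if (model$normalize) X <- l2_normalize_rows(X)
  predict(model$svm, X)
}

#' Save / load a trained model archive
#'
#' The archive is a single self-contained RDS file bundling the SVM dual
#' coefficients and support vectors, the bias, the kernel parameters, the
#' full encoding configuration and the propensity table.
#'
#' @param model A `"trip_model"`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trip_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trip_model"))
  model
}

# ---- cross-validation ---------------------------------------------------

# Precompute everything (c,g,p)-independent for a CV run: per fold the
# train/test inner-product blocks (and squared row norms when vectors are
# not unit-normalised). Propensities are recomputed from the training
# folds only, so no test-fold peptide leaks into its own encoding.
prepare_cv_kernels <- function(dataset, background, matrix = "blosum62",
                               pattern = "AAA", mode = "combined",
                               normalize = TRUE, leak_free = TRUE,
                               pseudocount = NULL) {
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- Biostrings::readAAStringSet(background)
  background <- as_peptide_chars(background)
  peptides <- dataset$peptide
  y <- dataset$label
  folds <- sort(unique(dataset$fold))
  if (length(folds) < 2L) stop("dataset must carry at least two folds")
  B <- encode_base_matrix(peptides, matrix, pattern, mode)

  global_enc <- NULL
  if (mode == "similarity_only" || !leak_free)
    global_enc <- build_encoding(peptides[y == 1L], background, matrix,
                                 pattern, mode, pseudocount)

  per_fold <- lapply(folds, function(fd) {
    te <- which(dataset$fold == fd)
    tr <- which(dataset$fold != fd)
    enc <- if (!is.null(global_enc)) global_enc else
      build_encoding(peptides[intersect(tr, which(y == 1L))], background,
                     matrix, pattern, mode, pseudocount)
    X <- apply_propensity(B, enc)
    if (normalize) X <- l2_normalize_rows(X)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    list(fold = fd, tr = tr, te = te,
         y_tr = y[tr], y_te = y[te],
         G_tr = tcrossprod(Xtr),
         G_cross = tcrossprod(Xte, Xtr),
         d_tr = rowSums(Xtr * Xtr), d_te = rowSums(Xte * Xte),
         propensity = enc$propensity)
  })
  list(per_fold = per_fold, folds = folds, y = y,
       n = length(peptides), mode = mode, normalize = normalize)
}

cv_run_config <- function(prep, config) {
  per_fold <- lapply(prep$per_fold, function(fb) {
    K_tr <- rbf_from_gram(fb$G_tr, config$g, d1 = fb$d_tr)
    K_cross <- rbf_from_gram(fb$G_cross, config$g, d1 = fb$d_te, d2 = fb$d_tr)
    fit <- svm_train_kernel(K_tr, fb$y_tr, cost = config$c)
    scores <- svm_score_kernel(fit, K_cross)
    ev <- roc_and_max_f(scores, fb$y_te)
    list(fold = fb$fold,
         metrics = data.frame(fold = fb$fold, sn = ev$max_f$sn,
                              p = ev$max_f$p, f = ev$max_f$f, auc = ev$auc,
                              threshold = ev$max_f$threshold),
         scores = data.frame(index = fb$te, fold = fb$fold,
                             score = scores, label = fb$y_te))
  })
  metrics <- do.call(rbind, lapply(per_fold, `[[`, "metrics"))
  scores <- do.call(rbind, lapply(per_fold, `[[`, "scores"))
  rownames(metrics) <- rownames(scores) <- NULL
  structure(list(config = config, per_fold = metrics, scores = scores,
                 summary = summarize_folds(metrics)),
            class = "trip_cv")
}

#' Similarity-aware k-fold cross-validation
#'
#' Evaluates one SVM parameter triplet with the dataset's prebuilt folds.
#' Inside each round the propensity table is recomputed from the training
#' folds only (leak-free; set `leak_free = FALSE` to reproduce a
#' global-table variant), all peptides are re-encoded under that table,
#' and the held-out fold is scored. Sensitivity, precision and F are
#' reported at each fold's maximal-F threshold; AUC by trapezoidal rule.
#'
#' @inheritParams train_model
#' @param leak_free Recompute propensities per training fold (default
#'   `TRUE`).
#' @return A `"trip_cv"`: `per_fold` metrics, pooled `scores`, and
#'   `summary` with fold means and 95% t-interval half-widths.
#' @export
cross_validate <- function(dataset, background, config = svm_config(),
                           matrix = "blosum62", pattern = "AAA",
                           mode = "combined", normalize = TRUE,
                           leak_free = TRUE, pseudocount = NULL) {
  prep <- prepare_cv_kernels(dataset, background, matrix, pattern, mode,
                             normalize, leak_free, pseudocount)
  cv_run_config(prep, config)
}

#' @export
print.trip_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "trip_cv (c=%g g=%g p=%g): Sn %.1f%%±%.1f P %.1f%%±%.1f F %.3f±%.3f AUC %.3f\n",
    x$config$c, x$config$g, x$config$p,
    100 * s$mean["sn"], 100 * s$ci_half_width["sn"],
    100 * s$mean["p"], 100 * s$ci_half_width["p"],
    s$mean["f"], s$ci_half_width["f"], s$mean["auc"]))
  invisible(x)
}

#' Grid search over SVM parameter triplets
#'
#' For every `(c, g, p)` triplet the five-fold cross-validation is run and
#' the mean maximal F-measure across test folds recorded; the triplet with
#' the largest mean max-F wins (ties broken by grid order). The `p`
#' parameter does not affect the classification backend, so triplets
#' sharing `(c, g)` reuse one CV run. All expensive, parameter-independent
#' work (encoding, per-fold propensities, inner-product blocks) is done
#' once up front.
#'
#' @inheritParams cross_validate
#' @param grid data.frame of triplets from [svm_grid()] (or any columns
#'   `c`, `g`, `p`).
#' @return List: `best_config` ([svm_config()]), `best_cv` (its
#'   `"trip_cv"`), and `results` (one row per triplet with the mean and CI
#'   of the max-F).
#' @export
grid_search_cv <- function(dataset, background, grid = svm_grid(),
                           matrix = "blosum62", pattern = "AAA",
                           mode = "combined", normalize = TRUE,
                           leak_free = TRUE, pseudocount = NULL) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  stopifnot(all(c("c", "g", "p") %in% names(grid)))
  prep <- prepare_cv_kernels(dataset, background, matrix, pattern, mode,
                             normalize, leak_free, pseudocount)
  cache <- new.env(parent = emptyenv())
  runs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    key <- sprintf("c%.17g_g%.17g", grid$c[r], grid$g[r])
    if (is.null(cache[[key]]))
      cache[[key]] <- cv_run_config(prep, svm_config(grid$c[r], grid$g[r],
                                                     grid$p[r]))
    runs[[r]] <- cache[[key]]
  }
  mean_f <- vapply(runs, function(cv) cv$summary$mean[["f"]], numeric(1))
  ci_f <- vapply(runs, function(cv) cv$summary$ci_half_width[["f"]], numeric(1))
  mean_auc <- vapply(runs, function(cv) cv$summary$mean[["auc"]], numeric(1))
  best <- which.max(mean_f)
  best_cv <- runs[[best]]
  best_cv$config <- svm_config(grid$c[best], grid$g[best], grid$p[best])
  list(best_config = best_cv$config,
       best_cv = best_cv,
       results = cbind(grid, mean_f = mean_f, ci_f = ci_f,
                       mean_auc = mean_auc))
}

# ---- model introspection ------------------------------------------------

#' Attribute weights of a trained model
#'
#' Computes \eqn{w = \sum_i \alpha_i x_i} over the support vectors (with
#' \eqn{\alpha_i} the signed dual coefficients) — the exact primal weight
#' vector for a linear kernel and the customary linear proxy under the RBF
#' kernel — and returns the tri-peptides ranked by descending weight.
#'
#' @param model A `"trip_model"` or `"trip_svm"`.
#' @return data.frame `tripeptide`, `weight`, `rank` (1 = largest weight).
#' @export
attribute_weights <- function(model) {
  svm <- if (inherits(model, "trip_model")) model$svm else model
  stopifnot(inherits(svm, "trip_svm"))
  w <- as.numeric(crossprod(svm$SV, svm$coefs))
  labels <- if (length(w) == N_TRIPEPTIDES) tripeptide_index()
            else colnames(svm$SV) %||% as.character(seq_along(w))
  ord <- order(w, decreasing = TRUE)
  data.frame(tripeptide = labels[ord], weight = w[ord],
             rank = seq_along(w), stringsAsFactors = FALSE)
}

#' Tendency screen between two peptide pools
#'
#' Scores every peptide of both pools with the model, ranks the combined
#' set by descending score (ties broken by stable input order: pool A
#' first, then pool B, each in given order), and reports, for each
#' requested `N`, how many of the top-`N` peptides come from each pool —
#' the virus-versus-human style independent test.
#'
#' @param model A `"trip_model"`.
#' @param pool_a,pool_b Character vectors of equal-length peptides.
#' @param top_ns Integer vector of top-list sizes.
#' @return data.frame `top_n`, `n_a`, `n_b`, `frac_a`.
#' @export
tendency_test <- function(model, pool_a, pool_b,
                          top_ns = c(100L, 200L, 400L, 800L)) {
  pool_a <- as_peptide_chars(pool_a)
  pool_b <- as_peptide_chars(pool_b)
  total <- length(pool_a) + length(pool_b)
  if (total == 0L) stop("both pools are empty", call. = FALSE)
  if (any(top_ns > total))
    stop("top_n exceeds the pooled peptide count (", total, ")",
         call. = FALSE)
  scores <- score_peptides(model, c(pool_a, pool_b))
  from_a <- c(rep(TRUE, length(pool_a)), rep(FALSE, length(pool_b)))
  ord <- order(-scores)  # radix sort: stable, preserves input order on ties
  ranked_a <- from_a[ord]
  data.frame(top_n = as.integer(top_ns),
             n_a = vapply(top_ns, function(n) sum(ranked_a[seq_len(n)]),
                          integer(1)),
             n_b = vapply(top_ns, function(n) sum(!ranked_a[seq_len(n)]),
                          integer(1)),
             frac_a = vapply(top_ns, function(n)
               mean(ranked_a[seq_len(n)]), numeric(1)))
}
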