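#' ROC curve, AUC and the maximal-F operating point
#'
#' Sweeps the decision threshold over the unique scores (ties grouped),
#' computing the ROC curve, the trapezoidal AUC (identical to the
#' Mann-Whitney concordance statistic with ties counted 1/2), and the
#' operating point maximising \deqn{F = 2\,Sn\,P / (Sn + P)} where
#' `Sn = TP/(TP+FN)` (sensitivity) and `P = TP/(TP+FP)` (precision).
#'
#' @param scores Real-valued decision scores.
#' @param labels Binary labels (logical, 0/1 or -1/+1); positives are the
#'   larger class value.
#' @return List of class `"trip_roc"`: `roc` (data.frame `threshold`,
#'   `tpr`, `fpr`, `precision`, `f`), `auc`, and `max_f` (list `sn`, `p`,
#'   `f`, `threshold`). At a threshold `t` instances with `score >= t` are
#'   called positive.
#' @export
roc_and_max_f <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  y <- as_svm_labels(labels) == 1L
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yp <- y[ord]
  tp <- cumsum(yp); fp <- cumsum(!yp)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  precision <- tp / (tp + fp)
  f <- ifelse(tpr + precision > 0, 2 * tpr * precision / (tpr + precision), 0)
  auc <- sum(diff(c(0, fpr)) * (c(0, tpr)[-length(tpr) - 1L] + tpr) / 2)
  best <- which.max(f)
  structure(list(
    roc = data.frame(threshold = thr, tpr = tpr, fpr = fpr,
                     precision = precision, f = f),
    auc = auc,
    max_f = list(sn = tpr[best], p = precision[best], f = f[best],
                 threshold = thr[best])
  ), class = "trip_roc")
}

#' @export
print.trip_roc <- function(x, ...) {
  cat(sprintf("trip_roc: AUC %.4f; max-F %.4f (Sn %.3f, P %.3f at thr %.4g)\n",
              x$auc, x$max_f$f, x$max_f$sn, x$max_f$p, x$max_f$threshold))
  invisible(x)
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Both score vectors must be computed on the same labelled instances.
#' Uses the structural-component (placement value) formulation with
#' midranks; returns the two-sided normal-approximation p-value for the
#' AUC difference.
#'
#' @param scores_a,scores_b Decision scores of the two methods.
#' @param labels Shared binary labels.
#' @return List: `auc_a`, `auc_b`, `delta`, `var`, `z`, `p_value`.
#'   If the variance of the difference is degenerate (zero), `z` and
#'   `p_value` are `NA` with a warning (except for the exact-tie case
#'   `scores_a == scores_b`, which is reported as `p_value = 1`).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  y <- as_svm_labels(labels) == 1L
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) stop("both classes required", call. = FALSE)
  comp_a <- delong_components(scores_a[y], scores_a[!y])
  comp_b <- delong_components(scores_b[y], scores_b[!y])
  auc <- c(comp_a$auc, comp_b$auc)
  V10 <- cbind(comp_a$v10, comp_b$v10)
  V01 <- cbind(comp_a$v01, comp_b$v01)
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  S <- S10 / m + S01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- auc[1] - auc[2]
  if (var_delta <= .Machine$double.eps) {
    if (isTRUE(all.equal(scores_a, scores_b)) || delta == 0) {
      z <- 0; p <- 1
    } else {
      warning("degenerate variance in DeLong test; p-value not computable")
      z <- NA_real_; p <- NA_real_
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc[1], auc_b = auc[2], delta = delta,
       var = var_delta, z = z, p_value = p)
}

# placement values via midranks: v10_i = Pr(score of pos i beats a random neg)
delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = sum(r_all[seq_len(m)] - r_pos) / (m * n), v10 = v10, v01 = v01)
}

# mean and 95% t-interval half-width over folds
fold_ci <- function(x) {
  x <- x[is.finite(x)]
  k <- length(x)
  if (k < 2L) return(c(mean = mean(x), half_width = NA_real_))
  c(mean = mean(x),
    half_width = stats::qt(0.975, df = k - 1L) * stats::sd(x) / sqrt(k))
}

# per-fold Sn/P/F/AUC table -> summary with means and 95% CIs
summarize_folds <- function(per_fold) {
  stats_cols <- c("sn", "p", "f", "auc")
  out <- lapply(stats_cols, function(col) fold_ci(per_fold[[col]]))
  names(out) <- stats_cols
  list(mean = vapply(out, `[[`, numeric(1), "mean"),
       ci_half_width = vapply(out, `[[`, numeric(1), "half_width"))
}
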