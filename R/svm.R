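#' SVM configuration
#'
#' The parameter triplet searched by the grid: `c` (soft-margin trade-off),
#' `g` (RBF kernel width, \eqn{K(x,z)=\exp(-g\|x-z\|^2)}) and `p`
#' (SVM-light's epsilon parameter, accepted and recorded for configuration
#' fidelity but not consumed by the classification backend). The default
#' grid spans `c = 2^-10..2^-1`, `g = 2^-12..2^-3`, `p = 2^-5..2^-2` in
#' powers of two; [svm_grid()] can extend it to include any reported
#' optimum such as `c = 32, g = 0.05, p = 0.5`.
#'
#' @param c,g,p Positive scalars.
#' @return Object of class `"trip_svm_config"`.
#' @export
svm_config <- function(c = 32, g = 0.05, p = 0.5) {
  stopifnot(c > 0, g > 0, p > 0)
  structure(list(c = c, g = g, p = p), class = "trip_svm_config")
}

#' @rdname svm_config
#' @param c_range,g_range,p_range Numeric vectors of grid values.
#' @return `svm_grid()`: a data.frame of (c, g, p) triplets.
#' @export
svm_grid <- function(c_range = 2^(-10:-1), g_range = 2^(-12:-3),
                     p_range = 2^(-5:-2)) {
  stopifnot(length(c_range) > 0, length(g_range) > 0, length(p_range) > 0)
  expand.grid(c = c_range, g = g_range, p = p_range, KEEP.OUT.ATTRS = FALSE)
}

#' Train a support vector classifier
#'
#' C-SVC with an RBF (default) or linear kernel, solved by sequential
#' minimal optimisation on the precomputed kernel matrix. Deterministic:
#' the solver has no random component, so identical data and parameters
#' give identical models.
#'
#' @param X Numeric feature matrix, one row per instance.
#' @param y Labels: logical, 0/1, or -1/+1 (positives are `TRUE`/`1`).
#' @param cost Soft-margin parameter C.
#' @param gamma RBF width; ignored for the linear kernel.
#' @param kernel `"rbf"` or `"linear"`.
#' @param epsilon SVM-light-style `p` parameter; stored, not consumed.
#' @param tol KKT stopping tolerance of the SMO solver.
#' @param max_iter Iteration cap (0 = automatic).
#' @return Object of class `"trip_svm"` carrying the support vectors, the
#'   signed dual coefficients `coefs` (\eqn{\alpha_i y_i}), the bias `rho`,
#'   and the kernel settings. `predict()` returns real-valued decision
#'   scores.
#' @export
svm_train <- function(X, y, cost = 32, gamma = 0.05,
                      kernel = c("rbf", "linear"), epsilon = 0.5,
                      tol = 1e-3, max_iter = 0L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as_svm_labels(y)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (length(y) != nrow(X)) stop("label/feature size mismatch")
  G <- tcrossprod(X)
  K <- if (kernel == "rbf") rbf_from_gram(G, gamma = gamma) else G
  fit <- smo_csvc(K, y, C = cost, tol = tol, max_iter = as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("SMO stopped at iteration cap (KKT gap %.3g)", fit$gap))
  sv <- which(fit$alpha > 0)
  structure(list(
    SV = X[sv, , drop = FALSE],
    coefs = fit$alpha[sv] * y[sv],
    rho = fit$rho,
    cost = cost, gamma = gamma, kernel = kernel, epsilon = epsilon,
    iterations = fit$iterations,
    n_train = nrow(X)
  ), class = "trip_svm")
}

as_svm_labels <- function(y) {
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  if (is.factor(y)) stop("supply labels as logical, 0/1 or -1/+1")
  y <- as.integer(y)
  if (all(y %in% c(0L, 1L))) y <- ifelse(y == 1L, 1L, -1L)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be logical, 0/1 or -1/+1")
  y
}

# RBF kernel from inner products: K_ij = exp(-g (x_i.x_i + x_j.x_j - 2 x_i.x_j))
rbf_from_gram <- function(G, gamma, d1 = diag(G), d2 = d1) {
  D2 <- outer(d1, d2, "+") - 2 * G
  D2[D2 < 0] <- 0
  exp(-gamma * D2)
}

# cross kernel between new rows and stored support vectors
svm_cross_kernel <- function(object, X) {
  if (object$kernel == "linear") return(tcrossprod(X, object$SV))
  G <- tcrossprod(X, object$SV)
  rbf_from_gram(G, object$gamma,
                d1 = rowSums(X * X), d2 = rowSums(object$SV * object$SV))
}

#' @export
predict.trip_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  K <- svm_cross_kernel(object, X)
  as.numeric(K %*% object$coefs) - object$rho
}

#' @export
print.trip_svm <- function(x, ...) {
  cat(sprintf("trip_svm: %s kernel, C=%g gamma=%g, %d SVs of %d points\n",
              x$kernel, x$cost, x$gamma, nrow(x$SV), x$n_train))
  invisible(x)
}

# kernel-level training for cross-validation: K is the full train-fold
# kernel matrix; returns what is needed to score a precomputed cross kernel
svm_train_kernel <- function(K, y, cost, tol = 1e-3, max_iter = 0L) {
  y <- as_svm_labels(y)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  fit <- smo_csvc(K, y, C = cost, tol = tol, max_iter = as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("SMO stopped at iteration cap (KKT gap %.3g)", fit$gap))
  list(alpha_y = fit$alpha * y, rho = fit$rho, iterations = fit$iterations)
}

# scores for a cross-kernel slice K_new_train
svm_score_kernel <- function(fit, K_cross) {
  as.numeric(K_cross %*% fit$alpha_y) - fit$rho
}
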