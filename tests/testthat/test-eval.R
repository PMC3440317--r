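test_that("ROC handles perfect, tied and hand-computed cases", {
  r <- roc_and_max_f(c(5, 4, 3, 2, 1, 0), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$max_f$f, 1)
  # hand-listed pairs with a tie across classes
  s <- c(0.9, 0.8, 0.8, 0.6, 0.4, 0.3)
  y <- c(1, 1, 0, 0, 1, 0)
  r <- roc_and_max_f(s, y)
  expect_equal(r$auc, pair_count_auc(s, y))      # exhaustive pair counting
  # F consistency at every threshold row
  with(r$roc, expect_equal(f, ifelse(tpr + precision > 0,
                                     2 * tpr * precision / (tpr + precision),
                                     0)))
  expect_error(roc_and_max_f(1:5, rep(1, 5)), "both classes")
})

test_that("trapezoidal AUC equals concordant-pair counting on random sets", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(10:200, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    expect_equal(roc_and_max_f(s, y)$auc, pair_count_auc(s, y))
  }
})

test_that("max-F point is the maximiser over the threshold sweep", {
  set.seed(18)
  y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(80) + y
  r <- roc_and_max_f(s, y)
  # oracle: recompute F at every unique threshold directly
  fs <- vapply(sort(unique(s)), function(t) {
    tp <- sum(s >= t & y == 1); fp <- sum(s >= t & y == 0)
    sn <- tp / sum(y == 1); p <- tp / (tp + fp)
    if (sn + p == 0) 0 else 2 * sn * p / (sn + p)
  }, numeric(1))
  expect_equal(r$max_f$f, max(fs))
  expect_equal(r$max_f$f,
               2 * r$max_f$sn * r$max_f$p / (r$max_f$sn + r$max_f$p))
})

# naive O(mn) DeLong oracle: explicit placement-value loops and covariances
delong_naive <- function(sa, sb, y) {
  psi <- function(x, ys) ifelse(x > ys, 1, ifelse(x == ys, 0.5, 0))
  comp <- function(s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    m <- length(pos); n <- length(neg)
    v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
    v01 <- vapply(neg, function(x) mean(psi(pos, x)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(sa); b <- comp(sb)
  s10 <- stats::cov(cbind(a$v10, b$v10)); s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / sum(y == 1) + s01 / sum(y == 0)
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- (a$auc - b$auc) / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, var = v, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

test_that("DeLong test matches the naive placement-value oracle", {
  set.seed(19)
  y <- rbinom(120, 1, 0.5); y[1:2] <- c(0, 1)
  sa <- rnorm(120) + 0.8 * y
  sb <- 0.6 * sa + rnorm(120) * 0.8
  got <- delong_test(sa, sb, y)
  want <- delong_naive(sa, sb, y)
  expect_equal(got$auc_a, want$auc_a)
  expect_equal(got$auc_b, want$auc_b)
  expect_equal(got$var, want$var)
  expect_equal(got$z, want$z)
  expect_equal(got$p_value, want$p)
})

test_that("DeLong edge cases behave", {
  set.seed(20)
  y <- rep(c(1, 0), 50)
  s <- rnorm(100)
  expect_equal(delong_test(s, s, y)$p_value, 1)         # identical scores
  strong <- y + rnorm(100, sd = 0.1)                     # near-perfect
  weak <- rnorm(100)
  expect_lt(delong_test(strong, weak, y)$p_value, 1e-4)
})

test_that("fold summaries use the t-based 95 percent interval", {
  x <- c(0.7, 0.75, 0.8, 0.72, 0.78)
  ci <- tripitope:::fold_ci(x)
  expect_equal(ci[["mean"]], mean(x))
  expect_equal(ci[["half_width"]], qt(0.975, 4) * sd(x) / sqrt(5))
})

test_that("grid search returns singleton grids and dominant triplets", {
  bm <- tiny_benchmark()
  single <- data.frame(c = 32, g = 0.05, p = 0.5)
  gs <- grid_search_cv(bm$dataset, bm$background, grid = single)
  expect_equal(gs$best_config$c, 32)
  expect_identical(nrow(gs$results), 1L)
  # a reasonable triplet dominates a degenerate one on every fold
  grid <- data.frame(c = c(32, 1e-6), g = c(0.05, 0.05), p = c(0.5, 0.5))
  gs2 <- grid_search_cv(bm$dataset, bm$background, grid = grid)
  expect_equal(gs2$best_config$c, 32)
  expect_true(all(gs2$results$mean_f[1] >= gs2$results$mean_f[2]))
  # deterministic: same inputs give the same argmax and metrics
  gs3 <- grid_search_cv(bm$dataset, bm$background, grid = grid)
  expect_identical(gs2$results, gs3$results)
  expect_error(grid_search_cv(bm$dataset, bm$background,
                              grid = data.frame()), "empty")
})
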