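# transforms, MLR partial correlations, Pearson matrices, PCR decomposition

test_that("recombination transform is log10(rate + 1)", {
  expect_equal(transform_recombination(0), 0)
  expect_equal(transform_recombination(9), 1)
  expect_equal(transform_recombination(3.4), log10(4.4))
  expect_error(transform_recombination(-1), ">= 0")
})

test_that("z_transform standardises with denominator n - 1", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(100, 5, 3)
  z <- z_transform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 10)), "constant")
})

test_that("partial correlations match the residual-residual definition", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 150
    X <- cbind(a = rnorm(n), b = rnorm(n) + 0.5 * rnorm(n), c = runif(n))
    y <- 0.4 * X[, 1] - 0.2 * X[, 3] + rnorm(n)
    m <- mlr_partial(X, y)
    rr <- sapply(1:3, function(j) {
      ry <- resid(lm(y ~ X[, -j]))
      rx <- resid(lm(X[, j] ~ X[, -j]))
      cor(ry, rx)
    })
    expect_lt(max(abs(m$partial$partial_correlation - rr)), 1e-10)
    expect_true(all(abs(m$partial$partial_correlation) <= 1))
    expect_gte(m$r.squared, 0); expect_lte(m$r.squared, 1)
  }
})

test_that("an exact predictor gives partial correlation 1 and R2 1", {
  set.seed(32)
  x1 <- rnorm(50); x2 <- rnorm(50)
  m <- suppressWarnings(mlr_partial(cbind(x1 = x1, x2 = x2), x1))
  expect_equal(m$partial$partial_correlation[1], 1, tolerance = 1e-7)
  expect_equal(m$r.squared, 1, tolerance = 1e-12)
})

test_that("a null response gives small partials and large p-values", {
  set.seed(33)
  n <- 1000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rnorm(n)
  m <- mlr_partial(X, y)
  expect_lt(max(abs(m$partial$partial_correlation)), 0.1)
})

test_that("listwise deletion: a row with missing data changes nothing", {
  set.seed(34)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- X[, 1] + rnorm(40)
  m1 <- mlr_partial(X, y)
  X2 <- rbind(X, c(NA, 1)); y2 <- c(y, 5)
  m2 <- mlr_partial(X2, y2)
  expect_equal(m1$partial, m2$partial, tolerance = 1e-14)
  expect_equal(m1$n, m2$n)
})

test_that("degenerate designs are rejected with informative errors", {
  x <- rnorm(20)
  expect_error(mlr_partial(cbind(a = x, b = 2 * x), rnorm(20)), "collinear")
  expect_error(mlr_partial(cbind(a = x[1:2]), rnorm(2)), "n > p")
})

test_that("pearson_matrix computes pairwise r with p-values", {
  set.seed(35)
  x <- rnorm(60)
  pm <- pearson_matrix(cbind(x1 = x, x2 = x, x3 = -x))
  expect_equal(pm$r["x1", "x2"], 1)
  expect_equal(pm$r["x1", "x3"], -1)
  n <- 3000
  pm2 <- pearson_matrix(cbind(a = rnorm(n), b = rnorm(n)))
  expect_lt(abs(pm2$r["a", "b"]), 0.08)
  pm3 <- pearson_matrix(cbind(a = rnorm(10), b = rep(1, 10)))
  expect_true(is.na(pm3$r["a", "b"]))
  expect_equal(pm2$r, t(pm2$r))
})

test_that("PCR decomposes the full-model R2 over orthogonal components", {
  set.seed(36)
  for (rep in 1:3) {
    n <- 120
    X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    X[, 2] <- X[, 2] + 0.6 * X[, 1]
    y <- 0.3 * X[, 1] - 0.5 * X[, 3] + rnorm(n)
    p <- pcr(X, y)
    m <- mlr_partial(X, y)
    expect_lt(abs(sum(p$variance_share) - m$r.squared), 1e-10)
    expect_lt(max(abs(crossprod(p$loadings) - diag(3))), 1e-10)
    expect_equal(unname(colSums(p$contribution)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(diff(p$eigenvalues) <= 1e-12))
  }
})

test_that("PC directions and shares match the analytic two-predictor case", {
  # for two positively correlated standardised predictors the PCs are exactly
  # (1, 1)/sqrt(2) and (1, -1)/sqrt(2), whatever the correlation
  set.seed(37)
  n <- 300
  a <- rnorm(n)
  b <- 0.6 * a + 0.8 * rnorm(n)
  y <- a - 0.5 * b + rnorm(n)
  p <- pcr(cbind(a = a, b = b), y)
  expect_equal(abs(unname(p$loadings)), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-10)
  za <- z_transform(a); zb <- z_transform(b)
  expect_equal(unname(p$variance_share),
               c(cor(y, za + zb)^2, cor(y, za - zb)^2), tolerance = 1e-10)
})

test_that("PCR flags the truly predictive component across seeds", {
  pc1_hits <- 0L
  null_hits <- 0L
  for (seed in 1:10) {
    set.seed(seed + 400)
    n <- 200
    X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    X[, 2] <- 0.7 * X[, 1] + 0.7 * X[, 2]          # correlated pair -> PC1
    Z <- apply(X, 2, z_transform)
    pc1 <- Z %*% eigen(cor(Z), symmetric = TRUE)$vectors[, 1]
    y <- 0.5 * as.numeric(pc1) + rnorm(n)
    p <- pcr(X, y)
    if (p$p_value[1] < 0.05) pc1_hits <- pc1_hits + 1L
    null_hits <- null_hits + sum(p$p_value[-1] < 0.05)
  }
  expect_gte(pc1_hits, 9L)
  # 20 null component tests at alpha = 0.05: expect ~1 false positive
  expect_lte(null_hits, 3L)
})
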