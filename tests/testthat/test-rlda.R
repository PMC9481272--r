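test_that("Ledoit-Wolf shrinkage matches the reference formulas to 1e-10", {
  set.seed(17)
  for (dims in list(c(50, 8), c(20, 30), c(200, 5))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1]) %*%
      matrix(rnorm(dims[2]^2, sd = 0.5), dims[2])
    got <- ledoit_wolf_cov(X)
    ref <- lw_reference(X)
    expect_equal(got$intensity, ref$intensity, tolerance = 1e-10)
    expect_lt(max(abs(got$cov - ref$cov)), 1e-10)
    expect_gte(got$intensity, 0)
    expect_lte(got$intensity, 1)
    expect_true(all(eigen(got$cov, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("shrinkage vanishes for well-conditioned data and saturates at n = 2", {
  set.seed(23)
  # many observations, few features: nearly no shrinkage
  X <- matrix(rnorm(5000 * 4), 5000) %*% diag(c(3, 2, 1, 0.5))
  lw <- ledoit_wolf_cov(X)
  expect_lt(lw$intensity, 0.02)
  expect_lt(max(abs(lw$cov - lw$sample_cov)), 0.05)
  # few observations in 30 dimensions: strong pull toward the scaled
  # identity (at exactly n = 2 the estimator is degenerate: both centered
  # points give the same outer product, so the estimated dispersion of the
  # per-sample covariances, and with it lambda, is 0)
  X2 <- matrix(rnorm(5 * 30), 5)
  lw2 <- ledoit_wolf_cov(X2)
  expect_gt(lw2$intensity, 0.3)
  shrunk_off <- lw2$cov - diag(diag(lw2$cov))
  sample_off <- lw2$sample_cov - diag(diag(lw2$sample_cov))
  expect_lt(max(abs(shrunk_off)), max(abs(sample_off)))
  expect_equal(ledoit_wolf_cov(matrix(rnorm(60), 2))$intensity, 0)
  expect_error(ledoit_wolf_cov(matrix(1, 1, 3)), "at least 2")
})

test_that("symmetric classes put the decision boundary through the origin", {
  set.seed(31)
  Z <- matrix(rnorm(200 * 5), 200)
  mu <- c(1, -0.5, 0.3, 0, 2)
  X1 <- sweep(Z, 2, mu, `+`)
  feats <- list(X = rbind(X1, -X1),     # exact mirror symmetry
                classes = rep(c(1L, -1L), each = 200))
  m <- fit_rlda(feats)
  expect_equal(decision_value(m, rep(0, 5)), 0, tolerance = 1e-9)
})

test_that("the 1-D two-class problem has its boundary at the midpoint", {
  feats <- list(X = matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1),
                classes = c(-1L, -1L, -1L, 1L, 1L, 1L))
  m <- fit_rlda(feats)
  expect_equal(decision_value(m, 1), 0, tolerance = 1e-12)
  expect_equal(predict(m, 0.99), -1L)
  expect_equal(predict(m, 1.01), 1L)
  expect_equal(predict(m, 1), -1L)      # exact tie goes to idle
})

test_that("predictions equal the pooled-covariance Gaussian Bayes rule", {
  set.seed(41)
  p <- 30
  A <- matrix(rnorm(p * p, sd = 0.3), p)
  m1 <- rnorm(p, 0.5); m2 <- rnorm(p, -0.5)
  X <- rbind(sweep(matrix(rnorm(80 * p), 80) %*% A, 2, m1, `+`),
             sweep(matrix(rnorm(60 * p), 60) %*% A, 2, m2, `+`))
  feats <- list(X = X, classes = rep(c(1L, -1L), c(80, 60)))
  m <- fit_rlda(feats)
  Xtest <- sweep(matrix(rnorm(50 * p), 50) %*% A, 2, (m1 + m2) / 2, `+`)
  # brute-force Bayes: higher Gaussian log-density under (mean, C_pooled)
  # plus log prior wins
  Cinv <- solve(m$C_pooled)
  logdens <- function(x, mu) -0.5 * t(x - mu) %*% Cinv %*% (x - mu)
  bayes <- apply(Xtest, 1, function(x) {
    s1 <- logdens(x, m$m1) + log(m$priors[["1"]])
    s2 <- logdens(x, m$m_neg1) + log(m$priors[["-1"]])
    if (s1 > s2) 1L else -1L
  })
  expect_equal(predict(m, Xtest), bayes)
  # decision value equals the log posterior odds of class 1
  odds <- apply(Xtest, 1, function(x)
    logdens(x, m$m1) + log(m$priors[["1"]]) -
      logdens(x, m$m_neg1) - log(m$priors[["-1"]]))
  expect_equal(decision_value(m, Xtest), unname(odds), tolerance = 1e-8)
})

test_that("unbalanced priors shift the bias by the log prior odds", {
  set.seed(43)
  X <- rbind(matrix(rnorm(90, 1), ncol = 3),
             matrix(rnorm(30, -1), ncol = 3))
  feats <- list(X = X, classes = rep(c(1L, -1L), c(30, 10)))
  m <- fit_rlda(feats)
  expect_equal(unname(m$priors), c(0.75, 0.25))
  expect_error(fit_rlda(list(X = X[1:30, ], classes = rep(1L, 30))),
               "both classes")
})

test_that("decision values increase monotonically along the weight vector", {
  set.seed(47)
  feats <- list(X = matrix(rnorm(100 * 4), 100),
                classes = rep(c(1L, -1L), 50))
  feats$X[feats$classes == 1L, 1] <- feats$X[feats$classes == 1L, 1] + 2
  m <- fit_rlda(feats)
  x0 <- rnorm(4)
  steps <- seq(0, 3, by = 0.5)
  vals <- vapply(steps, function(s)
    decision_value(m, x0 + s * m$b), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(decision_value(m, rnorm(5)), "dimension mismatch")
})

test_that("prediction is equivariant under rotation, scaling and shift", {
  # the shrinkage target (scaled identity) is rotation- and
  # scale-equivariant, so predictions are exactly preserved under
  # orthogonal maps combined with a global scale and shift; a general
  # affine map would alter the target direction and perturb the boundary
  set.seed(53)
  p <- 6
  X <- rbind(matrix(rnorm(60 * p, 1), 60), matrix(rnorm(60 * p, -1), 60))
  cls <- rep(c(1L, -1L), each = 60)
  Xtest <- matrix(rnorm(40 * p, 0.2), 40)
  m <- fit_rlda(list(X = X, classes = cls))
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  shift <- rnorm(p)
  tr <- function(M) sweep(3.7 * M %*% Q, 2, shift, `+`)
  m2 <- fit_rlda(list(X = tr(X), classes = cls))
  expect_equal(m2$shrinkage, m$shrinkage, tolerance = 1e-10)
  expect_equal(predict(m2, tr(Xtest)), predict(m, Xtest))
})

test_that("training accuracy on separable generator features is high", {
  feats <- offline_features()
  m <- fit_rlda(feats)
  acc <- mean(predict(m, feats$X) == feats$classes)
  expect_gt(acc, 0.8)
})
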