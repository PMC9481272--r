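test_that("filter bank kernels route narrowband energy to the right band", {
  fs <- 250
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  es <- epoch_set(array(x, c(1, 1, 500)), "MotorImageryA", fs, -1, "C3")
  banded <- apply_filter_bank(es, filter_bank())
  v_in <- var(x)
  v_alpha <- var(banded$data[1, 1, , 2])
  v_theta <- var(banded$data[1, 1, , 1])
  expect_gt(v_alpha / v_in, 0.9)
  expect_lt(v_theta / v_in, 0.15)
})

test_that("band outputs vanish for zero input and never exceed input variance", {
  es <- epoch_set(array(0, c(2, 2, 400)),
                  c("MotorImageryA", "IdleStateA"), 250, -1, c("a", "b"))
  banded <- apply_filter_bank(es)
  expect_true(all(banded$data == 0))
  ne <- noise_epochs(4, 3, 500, seed = 9)
  bd <- apply_filter_bank(ne)
  for (b in 1:5)
    for (e in 1:4)
      for (ch in 1:3)
        expect_lte(var(bd$data[e, ch, , b]),
                   var(ne$data[e, ch, ]) * 1.01)
})

test_that("CSP solves the 2x2 toy problem in closed form", {
  # trace-normalized class covariances diag(4,1)/5 and diag(1,4)/5
  fit <- csp_from_covariances(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(fit$eigvals, c(0.8, 0.2), tolerance = 1e-8)
  expect_equal(abs(fit$W), diag(2), tolerance = 1e-8)
})

test_that("identical class covariances give all-0.5 eigenvalues", {
  set.seed(4)
  A <- crossprod(matrix(rnorm(25), 5))
  A <- A / sum(diag(A))
  fit <- csp_from_covariances(A, A)
  expect_equal(fit$eigvals, rep(0.5, 5), tolerance = 1e-8)
})

test_that("CSP jointly diagonalizes both class covariances", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(3:4, 1)
    C1 <- crossprod(matrix(rnorm(n * n), n)); C1 <- C1 / sum(diag(C1))
    C2 <- crossprod(matrix(rnorm(n * n), n)); C2 <- C2 / sum(diag(C2))
    fit <- csp_from_covariances(C1, C2)
    D1 <- fit$W %*% C1 %*% t(fit$W)
    D2 <- fit$W %*% C2 %*% t(fit$W)
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
    expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
    expect_equal(diag(D1) + diag(D2), rep(1, n), tolerance = 1e-8)
    # eigenvalues agree with the brute-force generalized eigenproblem
    ref <- sort(Re(eigen(solve(C1 + C2, C1))$values), decreasing = TRUE)
    expect_equal(fit$eigvals, ref, tolerance = 1e-8)
  }
})

test_that("swapping the class arguments reverses the eigenvalue spectrum", {
  set.seed(3)
  C1 <- crossprod(matrix(rnorm(16), 4)); C1 <- C1 / sum(diag(C1))
  C2 <- crossprod(matrix(rnorm(16), 4)); C2 <- C2 / sum(diag(C2))
  a <- csp_from_covariances(C1, C2)
  b <- csp_from_covariances(C2, C1)
  expect_equal(b$eigvals, rev(1 - a$eigvals), tolerance = 1e-8)
})

test_that("rank-deficient covariances are rejected with the offending channel", {
  C1 <- diag(c(1, 0, 1)); C2 <- diag(c(1, 0, 1))
  err <- tryCatch(csp_from_covariances(C1 / 2, C2 / 2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "rank deficient")
  expect_match(err, "2")
})

test_that("filter selection keeps the first and last three filters", {
  expect_equal(select_filters(seq(1, 0, length.out = 17)),
               c(1, 2, 3, 15, 16, 17))
  expect_equal(select_filters(seq(1, 0, length.out = 6)), 1:6)
  expect_error(select_filters(c(0.9, 0.5, 0.1)), "at least 6")
  expect_error(select_filters(c(0.2, 0.8, 0.5, 0.4, 0.3, 0.1)), "descending")
})

test_that("offline features have the 30 x 180 geometry and scale as log-variance", {
  feats <- offline_features()
  expect_equal(dim(feats$X), c(180, 30))
  expect_equal(nrow(feats$feature_info), 30)
  expect_equal(sum(feats$window_ids == 1), 90)

  banded <- offline_banded()
  scaled <- banded
  scaled$data <- scaled$data * 2
  f2 <- logvar_features(scaled, offline_csp())
  expect_equal(f2$X, feats$X + log(4), tolerance = 1e-10)
})

test_that("features are invariant to a consistent channel permutation", {
  banded <- offline_banded()
  csp <- offline_csp()
  perm <- sample(17)
  banded_p <- banded
  banded_p$data <- banded$data[, perm, , , drop = FALSE]
  csp_p <- csp
  csp_p$W_per_band <- lapply(csp$W_per_band,
                             function(W) W[, perm, drop = FALSE])
  f1 <- logvar_features(banded, csp)
  f2 <- logvar_features(banded_p, csp_p)
  expect_equal(f2$X, f1$X, tolerance = 1e-10)
})

test_that("the top CSP pattern recovers the simulated source topography", {
  csp <- offline_csp()
  topo <- standbci:::smr_topography(standard_montage()$names)
  A <- solve(csp$W_per_band[[2]])          # alpha-band patterns
  cors <- abs(stats::cor(A, topo))
  best <- which.max(cors)
  expect_gt(max(cors), 0.9)
  expect_true(best %in% csp$retained)
})

test_that("Fisher scores follow the direct formula and rank ERD bands on top", {
  # two features: one with unit separation, one pure noise
  set.seed(6)
  X <- cbind(c(rnorm(200, 1, 1), rnorm(200, -1, 1)), rnorm(400))
  feats <- structure(list(X = X, classes = rep(c(1L, -1L), each = 200),
                          feature_info = data.frame(
                            band = c("alpha", "theta"), filter = c(1, 2))),
                     class = "bci_features")
  fs <- fisher_scores(feats)
  m1 <- colMeans(X[1:200, , drop = FALSE])
  m2 <- colMeans(X[201:400, , drop = FALSE])
  ref <- (m1 - m2)^2 / (apply(X[1:200, ], 2, var) + apply(X[201:400, ], 2, var))
  expect_equal(sort(fs$score, decreasing = TRUE), sort(ref, decreasing = TRUE))
  expect_equal(fs$band[1], "alpha")

  # exact value at means +/-1, unit variances
  n <- 40000
  set.seed(8)
  z <- rnorm(n)
  Xe <- matrix(c(z - mean(z) + 1, z - mean(z) - 1), ncol = 1)
  fe <- structure(list(X = Xe, classes = rep(c(1L, -1L), each = n),
                       feature_info = data.frame(band = "alpha", filter = 1)),
                  class = "bci_features")
  sc <- fisher_scores(fe)$score
  expect_equal(sc, (2)^2 / (var(z) + var(z)), tolerance = 1e-10)

  # ERD sessions put an alpha or beta feature on top
  top <- fisher_scores(offline_features())
  expect_true(top$band[1] %in% c("alpha", "low_beta", "mid_beta",
                                 "high_beta"))
})

test_that("fit_csp on banded class subsets matches covariance-level fitting", {
  banded <- offline_banded()
  mi <- which(banded$classes == 1L)
  idle <- which(banded$classes == -1L)
  sub <- function(idx) {
    out <- banded
    out$data <- banded$data[idx, , , , drop = FALSE]
    out$labels <- banded$labels[idx]
    out$classes <- banded$classes[idx]
    out
  }
  fit <- fit_csp(sub(mi), sub(idle), band = 2)
  bank_fit <- offline_csp()
  expect_equal(fit$W, bank_fit$W_per_band[[2]], tolerance = 1e-8)
  expect_equal(fit$eigvals, bank_fit$eigvals_per_band[[2]],
               tolerance = 1e-10)
})
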