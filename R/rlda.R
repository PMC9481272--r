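# Regularized linear discriminant analysis.
#
# Class covariances are estimated with the Ledoit-Wolf well-conditioned
# shrinkage estimator (convex combination of the sample covariance and a
# scaled identity, with the optimal intensity estimated from the data). The
# discriminant is the Gaussian equal-covariance Bayes rule on the pooled
# (averaged) class covariance: w = C_pooled^-1 (m1 - m_-1), bias from the
# class means and log prior odds. The decision value is the log posterior
# odds of the motor-imagery class; the sign threshold at 0 assigns labels,
# with an exact 0 mapping to the idle class (conservative for an online
# system).

#' Ledoit-Wolf shrinkage covariance estimator
#'
#' Computes `(1 - lambda) S + lambda (tr(S)/p) I` where `S` is the sample
#' covariance (denominator `n`) and `lambda` the Ledoit-Wolf optimal
#' shrinkage intensity estimated from the data.
#'
#' The intensity estimate needs at least three observations to be
#' informative: with exactly two, both centered points yield the same outer
#' product, the estimated dispersion of per-sample covariances is zero, and
#' `lambda` degenerates to 0.
#'
#' @param X Observations x features matrix with at least 2 rows.
#' @return List with `cov` (positive-definite estimate), `intensity`
#'   (`lambda` in `[0, 1]`), and `sample_cov`.
#' @export
ledoit_wolf_cov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  D <- S - mu * diag(p)
  d2 <- sum(D^2) / p
  if (d2 == 0) {
    # sample covariance already equals the target; shrinkage is moot
    return(list(cov = S, intensity = 0, sample_cov = S))
  }
  # sum_k ||x_k x_k' - S||_F^2 = sum_k (x_k'x_k)^2 - 2 sum_k x_k'Sx_k + n||S||_F^2
  q <- rowSums(Xc^2)
  xSx <- rowSums((Xc %*% S) * Xc)
  b_bar2 <- (sum(q^2) - 2 * sum(xSx) + n * sum(S^2)) / (p * n^2)
  b2 <- min(b_bar2, d2)
  lambda <- b2 / d2
  list(cov = (1 - lambda) * S + lambda * mu * diag(p),
       intensity = lambda, sample_cov = S)
}

#' Fit a regularized LDA classifier on log-variance features
#'
#' @param feats A `bci_features` object (see [logvar_features()]) or a list
#'   with `X` and `classes` in `{1, -1}`; both classes must have at least
#'   two observations.
#' @return A list of class `rlda`: class means `m1`/`m_neg1`, regularized
#'   covariances `C1`/`C_neg1`, pooled covariance, weights `b`, bias `d`,
#'   empirical `priors`, and per-class shrinkage intensities.
#' @export
fit_rlda <- function(feats) {
  X <- as.matrix(feats$X)
  cls <- feats$classes
  stopifnot(nrow(X) == length(cls))
  if (!all(sort(unique(cls)) %in% c(-1L, 1L)) || length(unique(cls)) != 2)
    stop("both classes (1 and -1) must be present", call. = FALSE)
  X1 <- X[cls == 1L, , drop = FALSE]
  X2 <- X[cls == -1L, , drop = FALSE]
  if (nrow(X1) < 2 || nrow(X2) < 2)
    stop("need at least 2 observations per class", call. = FALSE)
  lw1 <- ledoit_wolf_cov(X1)
  lw2 <- ledoit_wolf_cov(X2)
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  Cp <- (lw1$cov + lw2$cov) / 2
  b <- solve(Cp, m1 - m2)
  p1 <- nrow(X1) / nrow(X)
  p2 <- nrow(X2) / nrow(X)
  d <- -0.5 * sum((m1 + m2) * b) + log(p1 / p2)
  structure(list(m1 = m1, m_neg1 = m2, C1 = lw1$cov, C_neg1 = lw2$cov,
                 C_pooled = Cp, b = b, d = d,
                 priors = c(`1` = p1, `-1` = p2),
                 shrinkage = c(`1` = lw1$intensity, `-1` = lw2$intensity)),
            class = "rlda")
}

#' Linear decision value (log posterior odds before thresholding)
#'
#' @param model A fitted [fit_rlda()] model.
#' @param x A feature vector, or a matrix with one observation per row.
#' @return Numeric vector `b'x + d`, one value per observation.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "rlda"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$b))
    stop("feature dimension mismatch: model expects ", length(model$b),
         ", got ", ncol(x), call. = FALSE)
  as.numeric(x %*% model$b + model$d)
}

#' Predict class labels (+1 motor imagery, -1 idle)
#'
#' Values strictly above 0 map to class 1; 0 or below map to -1, so a tie
#' falls on the idle side.
#'
#' @param object A fitted [fit_rlda()] model.
#' @param x Feature vector or matrix (rows = observations).
#' @param ... Unused.
#' @return Integer vector of labels in `{1, -1}`.
#' @export
predict.rlda <- function(object, x, ...) {
  ifelse(decision_value(object, x) > 0, 1L, -1L)
}
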