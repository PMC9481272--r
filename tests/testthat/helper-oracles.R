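# Independent reference implementations used as test oracles. These are
# literal, loop-based transcriptions of the published formulas and share no
# code with the package.

# Ledoit-Wolf well-conditioned shrinkage estimator
lw_reference <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- matrix(0, p, p)
  for (k in seq_len(n)) S <- S + tcrossprod(Xc[k, ])
  S <- S / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2) / p
  bb <- 0
  for (k in seq_len(n)) bb <- bb + sum((tcrossprod(Xc[k, ]) - S)^2) / p
  bb <- bb / n^2
  b2 <- min(bb, d2)
  lam <- b2 / d2
  list(cov = (1 - lam) * S + lam * mu * diag(p), intensity = lam)
}
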