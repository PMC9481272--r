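# Filter-bank common spatial patterns.
#
# Epochs are decomposed into five subbands (theta 4-8, alpha 8-12, low-beta
# 12-16, mid-beta 16-20, high-beta 20-30 Hz) by frequency-domain Gaussian
# kernels with unit peak gain. Per subband, CSP solves the generalized
# eigenproblem of the class-average (trace-normalized) spatial covariances;
# the first and last three spatial filters are retained, and log-variance of
# the projected signals inside analysis time windows yields the feature
# vector (6 filters x 5 bands = 30 features).

#' The five-band filter bank
#'
#' @param bands List of `(low, high)` band edges in Hz.
#' @return A list of class `filter_bank` with `bands` and band names.
#' @export
filter_bank <- function(bands = list(theta = c(4, 8), alpha = c(8, 12),
                                     low_beta = c(12, 16),
                                     mid_beta = c(16, 20),
                                     high_beta = c(20, 30))) {
  stopifnot(length(bands) >= 1)
  for (b in bands) stopifnot(length(b) == 2, b[1] < b[2])
  lows <- vapply(bands, `[`, 0, 1)
  if (is.unsorted(lows)) stop("bands must be ordered by lower edge",
                              call. = FALSE)
  structure(list(bands = bands), class = "filter_bank")
}

# two-sided Gaussian band kernel over the FFT frequency axis, peak gain 1
gaussian_band_kernel <- function(n, lo, hi, fs) {
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)
  fc <- (lo + hi) / 2
  sdev <- (hi - lo) / 2
  exp(-(f - fc)^2 / (2 * sdev^2))
}

#' Apply the filter bank to an epoch set
#'
#' Each channel's Fourier transform is multiplied by the band's Gaussian
#' kernel and inverted, adding a band axis to the data.
#'
#' @param epochs A [epoch_set()].
#' @param bank A [filter_bank()].
#' @return A list of class `banded_epochs`: `data` is an
#'   epochs x channels x samples x bands array; labels and geometry are
#'   carried over.
#' @export
apply_filter_bank <- function(epochs, bank = filter_bank()) {
  stopifnot(inherits(epochs, "bci_epochs"), inherits(bank, "filter_bank"))
  d <- dim(epochs$data)
  n_b <- length(bank$bands)
  kerns <- lapply(bank$bands, function(b)
    gaussian_band_kernel(d[3], b[1], b[2], epochs$fs))
  out <- array(0, dim = c(d, n_b))
  for (e in seq_len(d[1])) {
    X <- stats::mvfft(t(epochs$data[e, , , drop = TRUE]))  # samples x channels
    if (d[2] == 1L) X <- stats::mvfft(matrix(epochs$data[e, 1, ], ncol = 1))
    for (b in seq_len(n_b)) {
      out[e, , , b] <- t(Re(stats::mvfft(X * kerns[[b]], inverse = TRUE)) / d[3])
    }
  }
  structure(list(data = out, labels = epochs$labels,
                 classes = epochs$classes, fs = epochs$fs,
                 t0_offset = epochs$t0_offset,
                 channel_names = epochs$channel_names, bank = bank),
            class = "banded_epochs")
}

# trace-normalized spatial covariance of one epoch (channels x samples)
epoch_covariance <- function(X) {
  C <- X %*% t(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("epoch with zero total power", call. = FALSE)
  C / tr
}

# class-average covariances per band, from a banded_epochs object
class_covariances <- function(banded, band) {
  d <- dim(banded$data)
  covs <- list(`1` = 0, `-1` = 0)
  counts <- c(`1` = 0, `-1` = 0)
  for (e in seq_len(d[1])) {
    key <- as.character(banded$classes[e])
    covs[[key]] <- covs[[key]] + epoch_covariance(
      matrix(banded$data[e, , , band], nrow = d[2]))
    counts[[key]] <- counts[[key]] + 1
  }
  if (any(counts == 0)) stop("both classes required to fit CSP", call. = FALSE)
  list(C1 = covs[["1"]] / counts[["1"]], C2 = covs[["-1"]] / counts[["-1"]])
}

#' CSP spatial filters from a pair of class covariances
#'
#' Solves the generalized eigenproblem of `(C1, C1 + C2)`: returns `W` with
#' rows sorted by descending eigenvalue, satisfying
#' `W (C1 + C2) W' = I`, so `W C1 W'` and `W C2 W'` are diagonal with
#' entries summing to 1 per component. The sign of each filter is fixed so
#' its largest-magnitude coefficient is positive; eigen-sort ties keep the
#' original order.
#'
#' @param C1,C2 Class-average spatial covariance matrices.
#' @param ridge Relative ridge added to the composite covariance.
#' @return List with `W` (filters in rows) and `eigvals` (descending, in
#'   `[0, 1]`).
#' @export
csp_from_covariances <- function(C1, C2, ridge = 1e-10) {
  n_e <- nrow(C1)
  stopifnot(identical(dim(C1), dim(C2)))
  Cc <- C1 + C2
  zero_var <- which(diag(Cc) <= .Machine$double.eps * sum(diag(Cc)))
  if (length(zero_var))
    stop("composite covariance is rank deficient; zero-variance channel(s): [",
         paste(zero_var, collapse = ", "), "]", call. = FALSE)
  Cc <- Cc + ridge * sum(diag(Cc)) * diag(n_e)
  ew <- eigen(Cc, symmetric = TRUE)
  if (min(ew$values) <= 1e-12 * max(ew$values))
    stop("composite covariance is numerically rank deficient", call. = FALSE)
  P <- diag(1 / sqrt(ew$values)) %*% t(ew$vectors)     # whitener
  S <- P %*% C1 %*% t(P)
  S <- (S + t(S)) / 2
  eu <- eigen(S, symmetric = TRUE)                      # descending values
  W <- t(eu$vectors) %*% P
  # reproducible sign: largest |coefficient| of each filter positive
  for (i in seq_len(n_e)) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  list(W = W, eigvals = pmin(pmax(eu$values, 0), 1))
}

#' Fit CSP for one subband from banded epochs of the two classes
#'
#' @param Y1,Y2 `banded_epochs` restricted to class 1 / class -1 epochs (or
#'   any two banded epoch sets to contrast).
#' @param band Band index to fit.
#' @param ridge Relative ridge for the composite covariance.
#' @return As [csp_from_covariances()].
#' @export
fit_csp <- function(Y1, Y2, band = 1, ridge = 1e-10) {
  avg_cov <- function(Y) {
    d <- dim(Y$data)
    stopifnot(d[1] >= 2)
    Reduce(`+`, lapply(seq_len(d[1]), function(e)
      epoch_covariance(matrix(Y$data[e, , , band], nrow = d[2])))) / d[1]
  }
  csp_from_covariances(avg_cov(Y1), avg_cov(Y2), ridge)
}

#' Retained spatial filter indices (first three and last three)
#'
#' @param eigvals Eigenvalues of a fitted CSP decomposition, which must be
#'   sorted in descending order.
#' @param n_retained Total number of retained filters (split evenly between
#'   the head and tail of the eigenvalue sort).
#' @return Integer indices into the rows of `W`.
#' @export
select_filters <- function(eigvals, n_retained = 6) {
  n_e <- length(eigvals)
  if (is.unsorted(rev(eigvals)))
    stop("eigenvalues must be sorted in descending order", call. = FALSE)
  if (n_e < n_retained)
    stop("need at least ", n_retained, " spatial filters, got ", n_e,
         call. = FALSE)
  m <- n_retained %/% 2
  c(seq_len(m), seq(n_e - m + 1L, n_e))
}

#' Fit the full CSP bank (all subbands)
#'
#' @param banded A `banded_epochs` object (see [apply_filter_bank()]) with
#'   both classes present.
#' @param n_retained Retained filters per band.
#' @param ridge Relative ridge for the composite covariance.
#' @return A list of class `csp_bank`: per-band projection matrices `W`,
#'   eigenvalues, retained indices, and geometry.
#' @export
fit_csp_bank <- function(banded, n_retained = 6, ridge = 1e-10) {
  stopifnot(inherits(banded, "banded_epochs"))
  n_b <- length(banded$bank$bands)
  Ws <- vector("list", n_b)
  evs <- vector("list", n_b)
  for (b in seq_len(n_b)) {
    cc <- class_covariances(banded, b)
    fit <- csp_from_covariances(cc$C1, cc$C2, ridge)
    Ws[[b]] <- fit$W
    evs[[b]] <- fit$eigvals
  }
  retained <- select_filters(evs[[1]], n_retained)
  structure(list(W_per_band = Ws, eigvals_per_band = evs,
                 retained = retained, n_retained = n_retained,
                 bank = banded$bank, n_channels = dim(banded$data)[2],
                 channel_names = banded$channel_names),
            class = "csp_bank")
}

#' Default offline analysis windows
#'
#' The two 1-s windows `[-1, 0)` and `[0, 1)` s around the imagery onset.
#'
#' @return List of two `(start, end)` pairs in seconds.
#' @export
default_windows <- function() list(c(-1, 0), c(0, 1))

#' Windowed log-variance features from banded epochs
#'
#' For each epoch and analysis window, the retained CSP filters of each band
#' project the banded signal and the log of the per-component sample
#' variance inside the window is taken. Features are ordered band-major
#' (band 1 filters 1..m, band 2 filters 1..m, ...); with 6 filters and 5
#' bands this yields 30 features per observation and one observation per
#' (epoch, window).
#'
#' @param banded A `banded_epochs` object.
#' @param model A fitted [fit_csp_bank()] model.
#' @param windows List of `(start, end)` pairs in seconds relative to the
#'   imagery onset; defaults to [default_windows()].
#' @return A list of class `bci_features`: `X` (observations x features),
#'   `classes` (+1/-1), `labels`, `epoch_ids`, `window_ids`, and
#'   `feature_info` (band/filter identity per column).
#' @export
logvar_features <- function(banded, model, windows = default_windows()) {
  stopifnot(inherits(banded, "banded_epochs"), inherits(model, "csp_bank"))
  d <- dim(banded$data)
  fs <- banded$fs
  n_b <- length(model$W_per_band)
  ret <- model$retained
  n_m <- length(ret)
  win_idx <- lapply(windows, function(w) {
    i0 <- as.integer(round((w[1] - banded$t0_offset) * fs)) + 1L
    i1 <- as.integer(round((w[2] - banded$t0_offset) * fs))
    if (i0 < 1L || i1 > d[3])
      stop("analysis window [", w[1], ", ", w[2], ") lies outside the epoch",
           call. = FALSE)
    if (i1 - i0 + 1L < 2L)
      stop("analysis window shorter than 2 samples", call. = FALSE)
    i0:i1
  })
  n_w <- length(windows)
  n_obs <- d[1] * n_w
  X <- matrix(0, n_obs, n_m * n_b)
  epoch_ids <- rep(seq_len(d[1]), each = n_w)
  window_ids <- rep(seq_len(n_w), d[1])
  Wr <- lapply(model$W_per_band, function(W) W[ret, , drop = FALSE])
  # all epochs of one (band, window) are projected in a single BLAS call;
  # per-epoch variances are then reduced over the sample axis
  for (b in seq_len(n_b)) {
    cols <- ((b - 1L) * n_m + 1L):(b * n_m)
    for (w in seq_len(n_w)) {
      nt <- length(win_idx[[w]])
      big <- aperm(banded$data[, , win_idx[[w]], b, drop = FALSE],
                   c(2, 3, 1, 4))
      dim(big) <- c(d[2], nt * d[1])
      Z <- Wr[[b]] %*% big                       # n_m x (nt * n_epochs)
      dim(Z) <- c(n_m, nt, d[1])
      s1 <- colSums(aperm(Z, c(2, 1, 3)), dims = 1)     # n_m x n_epochs
      s2 <- colSums(aperm(Z^2, c(2, 1, 3)), dims = 1)
      v <- (s2 - s1^2 / nt) / (nt - 1)
      rows <- (seq_len(d[1]) - 1L) * n_w + w
      X[rows, cols] <- t(log(v))
    }
  }
  band_names <- names(model$bank$bands)
  if (is.null(band_names)) band_names <- paste0("band", seq_len(n_b))
  feature_info <- data.frame(
    band = rep(band_names, each = n_m),
    filter = rep(seq_len(n_m), n_b),
    stringsAsFactors = FALSE)
  structure(list(X = X,
                 classes = banded$classes[epoch_ids],
                 labels = banded$labels[epoch_ids],
                 epoch_ids = epoch_ids, window_ids = window_ids,
                 feature_info = feature_info),
            class = "bci_features")
}

#' Fisher discriminability score per feature
#'
#' `score_j = (mean_1j - mean_-1j)^2 / (var_1j + var_-1j)`, ranked in
#' descending order with the band/filter identity of each feature. A zero
#' pooled variance yields `+Inf` with a warning.
#'
#' @param feats A [logvar_features()] result with both classes present.
#' @return Data frame: `feature`, `band`, `filter`, `score`, sorted by
#'   decreasing score.
#' @export
fisher_scores <- function(feats) {
  stopifnot(inherits(feats, "bci_features"))
  cls <- feats$classes
  if (length(unique(cls)) < 2)
    stop("both classes required for Fisher scoring", call. = FALSE)
  X1 <- feats$X[cls == 1L, , drop = FALSE]
  X2 <- feats$X[cls == -1L, , drop = FALSE]
  num <- (colMeans(X1) - colMeans(X2))^2
  den <- apply(X1, 2, stats::var) + apply(X2, 2, stats::var)
  if (any(den == 0))
    warning("zero pooled variance for some feature(s); score set to +Inf",
            call. = FALSE)
  score <- ifelse(den == 0, Inf, num / den)
  out <- data.frame(feature = seq_along(score),
                    band = feats$feature_info$band,
                    filter = feats$feature_info$filter,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
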