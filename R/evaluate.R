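# Offline and online evaluation.
#
# Offline: stratification-free five-fold cross-validation at the trial
# level (both analysis windows of a trial stay in the same fold), with the
# CSP bank and the RLDA classifier refitted inside every training split so
# no spatial-filter information leaks into the test folds. Accuracies are
# per-class percentages of correctly classified observations, pooled over
# folds; the overall accuracy is their unweighted mean. Significance is
# assessed by permutation: the same cross-validation repeated with class
# labels shuffled at the trial level.

# subset a banded_epochs object by epoch index
banded_subset <- function(banded, idx) {
  out <- banded
  out$data <- banded$data[idx, , , , drop = FALSE]
  out$labels <- banded$labels[idx]
  out$classes <- banded$classes[idx]
  out
}

# per-epoch trace-normalized covariances for every band, vectorized as one
# (n_ch^2) x n_epochs matrix per band (computed once per session)
precompute_band_covs <- function(banded) {
  d <- dim(banded$data)
  lapply(seq_len(d[4]), function(b) {
    m <- matrix(0, d[2]^2, d[1])
    for (e in seq_len(d[1]))
      m[, e] <- as.vector(epoch_covariance(
        matrix(banded$data[e, , , b], nrow = d[2])))
    m
  })
}

# CSP bank from precomputed covariances restricted to `idx` epochs
fit_csp_bank_from_covs <- function(banded, covs, classes, idx,
                                   n_retained = 6, ridge = 1e-10) {
  n_b <- length(covs)
  Ws <- vector("list", n_b)
  evs <- vector("list", n_b)
  i1 <- idx[classes[idx] == 1L]
  i2 <- idx[classes[idx] == -1L]
  if (!length(i1) || !length(i2))
    stop("both classes required in every training split", call. = FALSE)
  n_ch <- dim(banded$data)[2]
  for (b in seq_len(n_b)) {
    C1 <- matrix(rowMeans(covs[[b]][, i1, drop = FALSE]), n_ch)
    C2 <- matrix(rowMeans(covs[[b]][, i2, drop = FALSE]), n_ch)
    fit <- csp_from_covariances(C1, C2, ridge)
    Ws[[b]] <- fit$W
    evs[[b]] <- fit$eigvals
  }
  structure(list(W_per_band = Ws, eigvals_per_band = evs,
                 retained = select_filters(evs[[1]], n_retained),
                 n_retained = n_retained, bank = banded$bank,
                 n_channels = dim(banded$data)[2],
                 channel_names = banded$channel_names),
            class = "csp_bank")
}

# one full cross-validation run over given per-epoch classes
cv_engine <- function(banded, classes, k, seed, windows, n_retained, ridge,
                      covs = NULL) {
  d <- dim(banded$data)
  n_trials <- d[1]
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n_trials) stop("k = ", k, " exceeds the ", n_trials,
                         " available trials", call. = FALSE)
  if (is.null(covs)) covs <- precompute_band_covs(banded)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- rep(seq_len(k), length.out = n_trials)[sample(n_trials)]

  conf <- matrix(0, 2, 2, dimnames = list(truth = c("1", "-1"),
                                          pred = c("1", "-1")))
  per_fold <- data.frame(fold = seq_len(k), acc_mi = NA_real_,
                         acc_idle = NA_real_)
  bnd <- banded
  bnd$classes <- classes
  for (f in seq_len(k)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    model <- fit_csp_bank_from_covs(bnd, covs, classes, tr,
                                    n_retained, ridge)
    fall <- logvar_features(bnd, model, windows)     # all epochs, one pass
    tr_obs <- fall$epoch_ids %in% tr
    te_obs <- fall$epoch_ids %in% te
    clf <- fit_rlda(list(X = fall$X[tr_obs, , drop = FALSE],
                         classes = fall$classes[tr_obs]))
    pred <- predict(clf, fall$X[te_obs, , drop = FALSE])
    truth <- fall$classes[te_obs]
    tp <- sum(truth == 1L & pred == 1L); fn <- sum(truth == 1L & pred == -1L)
    fp <- sum(truth == -1L & pred == 1L); tn <- sum(truth == -1L & pred == -1L)
    conf["1", "1"] <- conf["1", "1"] + tp
    conf["1", "-1"] <- conf["1", "-1"] + fn
    conf["-1", "1"] <- conf["-1", "1"] + fp
    conf["-1", "-1"] <- conf["-1", "-1"] + tn
    per_fold$acc_mi[f] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    per_fold$acc_idle[f] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  tp <- conf["1", "1"]; fn <- conf["1", "-1"]
  fp <- conf["-1", "1"]; tn <- conf["-1", "-1"]
  acc_mi <- 100 * tp / (tp + fn)
  acc_idle <- 100 * tn / (tn + fp)
  structure(list(per_fold = per_fold,
                 acc_MotorImagery = acc_mi,
                 acc_IdleState = acc_idle,
                 acc_overall = 0.5 * (acc_mi + acc_idle),
                 confusion = conf, k = k),
            class = "cv_result")
}

#' Five-fold cross-validated offline evaluation
#'
#' Trials are randomly partitioned into `k` folds of sizes differing by at
#' most one; for each fold the filter bank's CSP projections and the RLDA
#' classifier are fitted on the training trials only and evaluated on the
#' held-out trials' observations (one per epoch and analysis window).
#'
#' @param epochs A [epoch_set()] of retained epochs (or a pre-banded
#'   `banded_epochs` object).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param bank Filter bank (ignored if `epochs` is already banded).
#' @param windows Analysis windows, see [default_windows()].
#' @param n_retained Retained CSP filters per band.
#' @param ridge Relative ridge for the composite covariances.
#' @return A list of class `cv_result`: per-fold and pooled per-class
#'   accuracies (%), `acc_overall`, and the pooled confusion matrix.
#' @export
crossvalidate <- function(epochs, k = 5, seed = 1L, bank = filter_bank(),
                          windows = default_windows(), n_retained = 6,
                          ridge = 1e-10) {
  banded <- if (inherits(epochs, "banded_epochs")) epochs else
    apply_filter_bank(epochs, bank)
  cv_engine(banded, banded$classes, k, seed, windows, n_retained, ridge)
}

#' Permutation test of the cross-validated overall accuracy
#'
#' Repeats the cross-validation with class labels shuffled at the trial
#' level and reports the add-one permutation p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which can never be 0.
#'
#' @inheritParams crossvalidate
#' @param n_perm Number of label permutations.
#' @return A list of class `perm_result`: `observed_overall`, `null_accs`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_test <- function(epochs, k = 5, n_perm = 1000, seed = 1L,
                             bank = filter_bank(),
                             windows = default_windows(), n_retained = 6,
                             ridge = 1e-10) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  banded <- if (inherits(epochs, "banded_epochs")) epochs else
    apply_filter_bank(epochs, bank)
  covs <- precompute_band_covs(banded)
  set.seed(seed)
  observed <- cv_engine(banded, banded$classes, k, seed = NULL, windows,
                        n_retained, ridge, covs = covs)$acc_overall
  null_accs <- numeric(n_perm)
  n_trials <- dim(banded$data)[1]
  for (i in seq_len(n_perm)) {
    perm <- banded$classes[sample(n_trials)]
    null_accs[i] <- cv_engine(banded, perm, k, seed = NULL, windows,
                              n_retained, ridge, covs = covs)$acc_overall
  }
  structure(list(observed_overall = observed, null_accs = null_accs,
                 p_value = (1 + sum(null_accs >= observed)) / (1 + n_perm),
                 n_permutations = n_perm),
            class = "perm_result")
}

#' Online detection metrics from replayed trial outcomes
#'
#' Motor-imagery detections count as positives, idle detections as
#' negatives; a timed-out trial counts as a misdetection of its cued class
#' (a cued motor-imagery timeout is a false negative, a cued idle timeout a
#' false positive). The mean detection time `T` averages over detected
#' (non-timeout) trials only.
#'
#' @param outcomes Data frame of trial outcomes (see [replay_session()])
#'   with columns `detected_label`, `detection_time`, `timed_out`.
#' @param truths Cued classes: `1`/`-1` or `"MotorImagery"`/`"IdleState"`
#'   (task labels with an experiment suffix are accepted).
#' @return A list of class `online_metrics`: confusion counts, `TPR`,
#'   `TNR`, `acc_online`, `PPV`, `NPV` (proportions), `mean_detection_time`
#'   (s) and `itr` (bits/min).
#' @export
online_metrics <- function(outcomes, truths) {
  if (!nrow(outcomes)) stop("no trial outcomes given", call. = FALSE)
  if (is.character(truths)) truths <- task_class(truths)
  stopifnot(length(truths) == nrow(outcomes), all(truths %in% c(1L, -1L)))
  detected <- !outcomes$timed_out
  pred <- integer(nrow(outcomes))
  pred[detected] <- ifelse(outcomes$detected_label[detected] == "MotorImagery",
                           1L, -1L)
  pred[!detected] <- -truths[!detected]   # timeout = miss of the cued class
  tp <- sum(truths == 1L & pred == 1L)
  fn <- sum(truths == 1L & pred == -1L)
  fp <- sum(truths == -1L & pred == 1L)
  tn <- sum(truths == -1L & pred == -1L)
  rate <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  t_mean <- if (any(detected)) mean(outcomes$detection_time[detected]) else
    NA_real_
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 TPR = rate(tp, fn), TNR = rate(tn, fp),
                 acc_online = acc,
                 PPV = rate(tp, fp), NPV = rate(tn, fn),
                 mean_detection_time = t_mean,
                 itr = if (is.na(t_mean)) NA_real_ else itr(acc, t_mean)),
            class = "online_metrics")
}

#' Information transfer rate of a binary selection, bits per minute
#'
#' `ITR = 60/T * (1 + a log2 a + (1-a) log2(1-a))` with the convention
#' `0 log2 0 = 0`; `a` is the online accuracy and `T` the mean detection
#' time in seconds.
#'
#' @param acc Accuracy as a proportion in `[0, 1]`.
#' @param T_detect Mean detection time in seconds (> 0).
#' @return Bits per minute.
#' @export
itr <- function(acc, T_detect) {
  if (T_detect <= 0) stop("detection time must be positive", call. = FALSE)
  if (acc < 0 || acc > 1) stop("accuracy must lie in [0, 1]", call. = FALSE)
  plog <- function(p) if (p == 0) 0 else p * log2(p)
  (60 / T_detect) * (1 + plog(acc) + plog(1 - acc))
}
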