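# Event-related spectral perturbation.
#
# Full-trial epochs are decomposed with complex Morlet wavelets (cycles
# growing linearly from 7 at the lowest frequency to 14 at the highest),
# per-trial power is averaged and sampled on a 200-point time grid that
# excludes the edge region where the widest wavelet would spill over the
# epoch limits. Power is normalized to a pre-stimulus baseline in dB, so
# event-related desynchronization is negative and synchronization positive.
# Significance against the baseline is assessed with an EEGLAB-style
# bootstrap that resamples baseline time points per trial.

#' Morlet wavelet time-frequency decomposition of full-trial epochs
#'
#' @param epochs A [epoch_set()] covering whole trials (e.g. `[-7, 4)` s
#'   around the imagery onset).
#' @param freqs Analysis frequencies in Hz.
#' @param n_times Number of output time points (default 200).
#' @param cycles Length-2 vector: wavelet cycles at the lowest and highest
#'   analysis frequency; interpolated linearly in between.
#' @param keep_trials Keep per-trial power (required for the bootstrap).
#' @return A list of class `tf_decomposition`: `power` (channels x
#'   frequencies x times, averaged over trials), `trial_power` (trials x
#'   channels x frequencies x times, if kept), `freqs`, `times`, `cycles`.
#' @export
morlet_tfa <- function(epochs, freqs = seq(4, 30), n_times = 200,
                       cycles = c(7, 14), keep_trials = TRUE) {
  stopifnot(inherits(epochs, "bci_epochs"), length(cycles) == 2)
  d <- dim(epochs$data)
  fs <- epochs$fs
  n_e <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  f_lo <- min(freqs); f_hi <- max(freqs)
  n_cyc <- if (f_hi > f_lo)
    cycles[1] + (cycles[2] - cycles[1]) * (freqs - f_lo) / (f_hi - f_lo)
  else rep(cycles[1], length(freqs))

  sigma_t <- n_cyc / (2 * pi * freqs)
  half_max <- 3.5 * max(sigma_t)            # widest wavelet half-support, s
  if (n_samp / fs <= 2 * half_max)
    stop("epochs shorter than the widest wavelet support (",
         signif(2 * half_max, 3), " s)", call. = FALSE)
  t0 <- epochs$t0_offset
  t_end <- t0 + n_samp / fs
  times <- seq(t0 + half_max, t_end - half_max, length.out = n_times)
  t_idx <- as.integer(round((times - t0) * fs)) + 1L
  t_idx <- pmin(pmax(t_idx, 1L), n_samp)

  # unit-energy complex Morlet kernels, padded FFTs precomputed
  kern <- lapply(seq_along(freqs), function(i) {
    ht <- 3.5 * sigma_t[i]
    tt <- seq(-ht, ht, by = 1 / fs)
    w <- exp(2i * pi * freqs[i] * tt) * exp(-tt^2 / (2 * sigma_t[i]^2))
    w / sqrt(sum(Mod(w)^2))
  })
  max_klen <- max(lengths(kern))
  nfft <- stats::nextn(n_samp + max_klen - 1L, 2)
  kfft <- lapply(kern, function(w) fft(c(w, rep(0, nfft - length(w)))))
  klen <- lengths(kern)

  trial_power <- if (keep_trials)
    array(0, dim = c(n_e, n_ch, length(freqs), n_times)) else NULL
  power <- array(0, dim = c(n_ch, length(freqs), n_times))
  for (e in seq_len(n_e)) {
    for (ch in seq_len(n_ch)) {
      x <- epochs$data[e, ch, ]
      Fx <- fft(c(x, rep(0, nfft - n_samp)))
      for (fi in seq_along(freqs)) {
        y <- fft(Fx * kfft[[fi]], inverse = TRUE) / nfft
        # 'same' alignment: sample s of x sits at s + (klen-1)/2 in y
        off <- (klen[fi] - 1L) %/% 2L
        p <- Mod(y[t_idx + off])^2
        if (keep_trials) trial_power[e, ch, fi, ] <- p
        power[ch, fi, ] <- power[ch, fi, ] + p / n_e
      }
    }
  }
  structure(list(power = power, trial_power = trial_power, freqs = freqs,
                 times = times, cycles = n_cyc, fs = fs,
                 channel_names = epochs$channel_names),
            class = "tf_decomposition")
}

baseline_time_index <- function(tf, baseline) {
  stopifnot(length(baseline) == 2, baseline[1] < baseline[2])
  idx <- which(tf$times >= baseline[1] & tf$times < baseline[2])
  if (length(idx) < 2)
    stop("baseline window [", baseline[1], ", ", baseline[2],
         ") covers fewer than 2 time points of the decomposition",
         call. = FALSE)
  idx
}

#' Baseline-normalize a time-frequency decomposition (dB)
#'
#' `ersp_db = 10 log10(power / mean baseline power)` per channel and
#' frequency; desynchronization (power drop) is negative, synchronization
#' positive.
#'
#' @param tf A [morlet_tfa()] decomposition.
#' @param baseline `(start, end)` of the baseline window in seconds
#'   (default `(-3.5, -3)`, the pre-movement fixation-free interval).
#' @return A list of class `ersp_result`: `ersp_db` (channels x
#'   frequencies x times), `baseline_window`, `freqs`, `times`.
#' @export
baseline_normalize <- function(tf, baseline = c(-3.5, -3)) {
  stopifnot(inherits(tf, "tf_decomposition"))
  idx <- baseline_time_index(tf, baseline)
  base <- apply(tf$power[, , idx, drop = FALSE], c(1, 2), mean)
  if (any(base <= 0))
    stop("zero baseline power for some channel/frequency", call. = FALSE)
  ersp <- 10 * log10(sweep(tf$power, c(1, 2), base, `/`))
  structure(list(ersp_db = ersp, baseline_window = baseline,
                 freqs = tf$freqs, times = tf$times,
                 channel_names = tf$channel_names),
            class = "ersp_result")
}

#' Bootstrap significance mask for ERSP deviations from baseline
#'
#' Per channel and frequency, the tested statistic is the deviation of the
#' trial-averaged power at each time point from the mean baseline power.
#' Its null distribution is built by bootstrap: each replicate draws trials
#' with replacement and one random baseline time point per trial, twice
#' independently, and records the difference of the two means. Resampling
#' trials keeps the surrogate variance honest when the baseline is short
#' relative to the wavelet autocorrelation time (baseline points within a
#' trial are then nearly collinear), and differencing two draws accounts
#' for the sampling error of the baseline mean itself, which with a 0.5-s
#' baseline is as large as that of any single tested cell. A cell is
#' significant (two-tailed) when its deviation falls outside the `alpha/2`
#' and `1 - alpha/2` quantiles of the null differences. No
#' multiple-comparison correction is applied.
#'
#' @param tf A [morlet_tfa()] decomposition with `keep_trials = TRUE`.
#' @param baseline Baseline window `(start, end)` in seconds.
#' @param alpha Two-tailed significance level.
#' @param n_boot Number of bootstrap replicates (>= 200 recommended).
#' @param seed RNG seed.
#' @return Logical array channels x frequencies x times.
#' @export
bootstrap_significance <- function(tf, baseline = c(-3.5, -3), alpha = 0.05,
                                   n_boot = 500, seed = 1L) {
  stopifnot(inherits(tf, "tf_decomposition"))
  if (is.null(tf$trial_power))
    stop("per-trial power required; rerun morlet_tfa(keep_trials = TRUE)",
         call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  idx <- baseline_time_index(tf, baseline)
  set.seed(seed)
  d <- dim(tf$trial_power)                 # trials, channels, freqs, times
  n_e <- d[1]
  mask <- array(FALSE, dim = dim(tf$power))
  for (ch in seq_len(d[2])) {
    for (fi in seq_len(d[3])) {
      M <- tf$trial_power[, ch, fi, idx, drop = TRUE]
      if (n_e == 1L) M <- matrix(M, nrow = 1)
      boot_mean <- function() {
        dt <- sample.int(length(idx), n_e * n_boot, replace = TRUE)
        de <- sample.int(n_e, n_e * n_boot, replace = TRUE)
        colMeans(matrix(M[cbind(de, dt)], nrow = n_e))
      }
      null_diff <- boot_mean() - boot_mean()
      q <- stats::quantile(null_diff, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE)
      dev <- tf$power[ch, fi, ] - mean(M)
      mask[ch, fi, ] <- dev < q[1] | dev > q[2]
    }
  }
  mask
}
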