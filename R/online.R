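# Streaming detection engine.
#
# Timing contract of one online trial: the first 1-s EEG epoch is acquired
# over [0, 1) s from the imagery cue; its five 50-sample sub-windows are
# classified over the following second, producing labels at 1.2, 1.4, ...,
# 2.0 s; each subsequent epoch adds five more labels at 0.2-s intervals. A
# FIFO buffer holds the five most recent labels; when all five agree the
# decision fires and the command is emitted one selection-second later, so
# the earliest possible emission is 3.0 s. If no decision is possible
# before the 15-s limit the trial times out. All replay is pure and
# deterministic: simulated time advances by sample count only.

#' Online engine configuration
#'
#' @param epoch_len Epoch length in samples (one second at 250 Hz).
#' @param window_len Classification window length in samples.
#' @param n_windows Windows per epoch; must satisfy
#'   `n_windows * window_len == epoch_len` in the default contiguous mode.
#' @param required_consecutive Number of identical consecutive labels that
#'   triggers a decision.
#' @param timeout Trial time limit in seconds.
#' @param selection_delay Seconds between the decision firing and command
#'   emission.
#' @param sliding If `TRUE`, windows are `epoch_len` long and slide by
#'   `window_len` samples instead of being contiguous sub-windows (an
#'   alternative reading of the protocol; not the default).
#' @return A list of class `online_config`.
#' @export
online_config <- function(epoch_len = 250, window_len = 50, n_windows = 5,
                          required_consecutive = 5, timeout = 15,
                          selection_delay = 1, sliding = FALSE) {
  if (!sliding && n_windows * window_len != epoch_len)
    stop("n_windows * window_len must equal epoch_len", call. = FALSE)
  stopifnot(required_consecutive >= 1, timeout > 0, selection_delay >= 0)
  structure(list(epoch_len = epoch_len, window_len = window_len,
                 n_windows = n_windows,
                 required_consecutive = required_consecutive,
                 timeout = timeout, selection_delay = selection_delay,
                 sliding = sliding),
            class = "online_config")
}

#' Feature vectors of one streaming epoch
#'
#' The full 1-s epoch is filtered through the bank (50 samples are too
#' short to band-pass at 4 Hz), projected with the retained CSP filters,
#' and log-variance is computed inside each of the five contiguous
#' 50-sample sub-windows, yielding five 30-dimensional feature vectors.
#'
#' @param epoch_1s Channels x `epoch_len` samples matrix.
#' @param csp A fitted [fit_csp_bank()] model.
#' @param bank The [filter_bank()] used at training time.
#' @param cfg An [online_config()].
#' @param fs Sampling rate, Hz.
#' @return `n_windows` x features matrix.
#' @export
window_features <- function(epoch_1s, csp, bank = csp$bank,
                            cfg = online_config(), fs = 250) {
  epoch_1s <- as.matrix(epoch_1s)
  if (ncol(epoch_1s) != cfg$epoch_len)
    stop("epoch must have exactly ", cfg$epoch_len, " samples, got ",
         ncol(epoch_1s), call. = FALSE)
  es <- epoch_set(array(epoch_1s, dim = c(1, dim(epoch_1s))),
                  labels = "MotorImageryA", fs = fs, t0_offset = 0,
                  channel_names = csp$channel_names)
  banded <- apply_filter_bank(es, bank)
  step <- cfg$window_len / fs
  windows <- lapply(seq_len(cfg$n_windows) - 1L,
                    function(i) c(i * step, (i + 1) * step))
  feats <- logvar_features(banded, csp, windows)
  feats$X
}

#' Consecutive-label voting over a streamed label sequence
#'
#' Maintains a FIFO buffer of the `required_consecutive` most recent window
#' labels; the decision fires as soon as the whole buffer agrees, and the
#' command is emitted `selection_delay` seconds later. Labels arrive at
#' `1 + 0.2 k` seconds (first epoch acquired over second one, classified
#' over second two). Any label whose emission would fall beyond the
#' timeout is not waited for; without a decision the trial times out at
#' `timeout` seconds.
#'
#' @param label_stream Integer (+1/-1) or character vector of window labels
#'   in stream order.
#' @param cfg An [online_config()].
#' @return A list of class `trial_outcome`: `detected_label`
#'   (`"MotorImagery"`, `"IdleState"` or `"none"`), `detection_time`
#'   (emission time, s from imagery onset; `NA` on timeout), `timed_out`,
#'   `elapsed` (trial duration: the emission time, or the time limit when
#'   the trial timed out), and `label_stream`.
#' @export
detection_loop <- function(label_stream, cfg = online_config()) {
  if (!length(label_stream)) stop("empty label stream", call. = FALSE)
  if (is.character(label_stream))
    label_stream <- ifelse(grepl("^MotorImagery", label_stream), 1L, -1L)
  label_period <- cfg$window_len / cfg$epoch_len     # s between labels (0.2)
  # label k (1-based) becomes available at 1 + k * label_period seconds
  r <- cfg$required_consecutive
  n <- length(label_stream)
  for (k in seq_len(n)) {
    t_label <- 1 + k * label_period
    t_emit <- t_label + cfg$selection_delay
    if (t_emit > cfg$timeout + 1e-9) break
    if (k >= r && length(unique(label_stream[(k - r + 1L):k])) == 1L) {
      lab <- if (label_stream[k] == 1L) "MotorImagery" else "IdleState"
      return(structure(list(detected_label = lab, detection_time = t_emit,
                            timed_out = FALSE, elapsed = t_emit,
                            label_stream = label_stream),
                       class = "trial_outcome"))
    }
  }
  structure(list(detected_label = "none", detection_time = NA_real_,
                 timed_out = TRUE, elapsed = cfg$timeout,
                 label_stream = label_stream),
            class = "trial_outcome")
}

#' Feedback state from the recent label buffer
#'
#' Majority of motor-imagery labels leans the feedback toward the imagery
#' figure, majority of idle labels toward the idle figure; a tie (or empty
#' buffer) is neutral, and a full buffer of identical labels means the
#' decision rule has fired.
#'
#' @param buffer Integer (+1/-1) or character labels, most recent last;
#'   at most `required_consecutive` long.
#' @param cfg An [online_config()].
#' @return One of `"MI_LEANING"`, `"IDLE_LEANING"`, `"NEUTRAL"`,
#'   `"DECIDED"`.
#' @export
feedback_state <- function(buffer, cfg = online_config()) {
  if (is.character(buffer))
    buffer <- ifelse(grepl("^MotorImagery", buffer), 1L, -1L)
  if (length(buffer) > cfg$required_consecutive)
    stop("buffer longer than required_consecutive", call. = FALSE)
  if (length(buffer) == cfg$required_consecutive &&
      length(unique(buffer)) == 1L)
    return("DECIDED")
  n_mi <- sum(buffer == 1L)
  n_idle <- sum(buffer == -1L)
  if (n_mi > n_idle) "MI_LEANING"
  else if (n_idle > n_mi) "IDLE_LEANING"
  else "NEUTRAL"
}

#' Replay a recording through the online engine
#'
#' For every imagery-stage marker, consumes the signal from the marker
#' onset in `epoch_len`-sample steps, produces the 5 Hz label stream via
#' [window_features()] and the classifier, and runs [detection_loop()].
#' Deterministic given its inputs.
#'
#' @param rec A [recording()] with imagery-stage markers.
#' @param csp A fitted [fit_csp_bank()] model.
#' @param rlda A fitted [fit_rlda()] model.
#' @param cfg An [online_config()].
#' @param bank Filter bank used at training time.
#' @return A data.frame with one row per trial: `trial`, `truth_label`,
#'   `detected_label`, `detection_time`, `timed_out`.
#' @export
replay_session <- function(rec, csp, rlda, cfg = online_config(),
                           bank = csp$bank) {
  stopifnot(inherits(rec, "bci_recording"))
  tasks <- task_events(rec)
  if (!nrow(tasks)) stop("recording has no imagery-stage markers",
                         call. = FALSE)
  fs <- rec$fs
  n_total <- ncol(rec$signals)
  out <- vector("list", nrow(tasks))
  for (k in seq_len(nrow(tasks))) {
    s0 <- as.integer(round(tasks$onset[k] * fs))
    if (s0 < 0 || s0 >= n_total)
      stop("marker ", k, " outside the recording", call. = FALSE)
    max_epochs <- floor(min(cfg$timeout * fs, n_total - s0) / cfg$epoch_len)
    labels <- integer(0)
    outcome <- NULL
    for (ep in seq_len(max_epochs)) {
      lo <- s0 + (ep - 1L) * cfg$epoch_len + 1L
      hi <- s0 + ep * cfg$epoch_len
      feats <- window_features(rec$signals[, lo:hi, drop = FALSE], csp,
                               bank, cfg, fs)
      labels <- c(labels, predict(rlda, feats))
      outcome <- detection_loop(labels, cfg)
      if (!outcome$timed_out) break
    }
    if (is.null(outcome)) outcome <- list(detected_label = "none",
                                          detection_time = NA_real_,
                                          timed_out = TRUE)
    out[[k]] <- data.frame(trial = k, truth_label = tasks$label[k],
                           detected_label = outcome$detected_label,
                           detection_time = outcome$detection_time,
                           timed_out = outcome$timed_out,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
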