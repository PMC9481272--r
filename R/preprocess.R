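# Epoching and artifact screening.
#
# Trials are cut into 2-s epochs around the imagery-stage onset ([-1, +1) s,
# 500 samples at 250 Hz). Three per-channel statistics are computed on
# FIR-filtered copies of each epoch and compared against fixed thresholds:
# peak-to-peak amplitude and standard deviation on the 4-40 Hz signal, and
# the 20-40 / 4-40 Hz sum-of-squares power ratio as a muscle-noise index.
# An epoch is discarded if any channel violates any criterion.

#' Construct an epoch set
#'
#' @param data Numeric array, epochs x channels x samples, microvolts.
#' @param labels Character vector of imagery-stage task labels, one per epoch.
#' @param fs Sampling rate, Hz.
#' @param t0_offset Epoch start relative to imagery onset, seconds.
#' @param channel_names Channel labels.
#' @return A list of class `bci_epochs`.
#' @export
epoch_set <- function(data, labels, fs, t0_offset = -1,
                      channel_names = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels))
  bad <- setdiff(unique(labels), TASK_LABELS)
  if (length(bad))
    stop("epoch labels must be task labels; offending: [",
         paste(bad, collapse = ", "), "]", call. = FALSE)
  structure(list(data = data, labels = as.character(labels),
                 classes = task_class(labels), fs = fs,
                 t0_offset = t0_offset,
                 channel_names = channel_names),
            class = "bci_epochs")
}

#' @export
print.bci_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bci_epochs> %d epochs x %d channels x %d samples @ %g Hz (t0 %+g s)\n",
              d[1], d[2], d[3], x$fs, x$t0_offset))
  if (d[1]) print(table(x$labels))
  invisible(x)
}

#' Cut imagery-stage epochs out of a continuous recording
#'
#' One epoch per imagery-stage marker, spanning the half-open window
#' `[window[1], window[2])` seconds around the marker onset (default
#' `[-1, +1)`, i.e. `round(2 fs)` samples). Markers too close to the
#' recording edges are skipped with a warning.
#'
#' @param rec A [recording()] containing imagery-stage task markers.
#' @param window Two-element numeric, epoch limits in seconds relative to
#'   the marker onset.
#' @return A [epoch_set()] with labels copied from the markers.
#' @export
extract_epochs <- function(rec, window = c(-1, 1)) {
  stopifnot(inherits(rec, "bci_recording"), length(window) == 2,
            window[1] < window[2])
  fs <- rec$fs
  tasks <- task_events(rec)
  if (nrow(tasks) == 0)
    stop("recording contains no imagery-stage markers", call. = FALSE)
  off0 <- as.integer(round(window[1] * fs))
  off1 <- as.integer(round(window[2] * fs))
  n_samp <- off1 - off0
  n_total <- ncol(rec$signals)
  keep <- logical(nrow(tasks))
  slices <- vector("list", nrow(tasks))
  for (k in seq_len(nrow(tasks))) {
    s0 <- as.integer(round(tasks$onset[k] * fs))
    lo <- s0 + off0 + 1L
    hi <- s0 + off1
    if (lo < 1L || hi > n_total) next
    keep[k] <- TRUE
    slices[[k]] <- rec$signals[, lo:hi, drop = FALSE]
  }
  if (any(!keep))
    warning(sum(!keep), " marker(s) too close to the recording edge; ",
            "corresponding epoch(s) skipped", call. = FALSE)
  slices <- slices[keep]
  data <- array(0, dim = c(length(slices), nrow(rec$signals), n_samp))
  for (k in seq_along(slices)) data[k, , ] <- slices[[k]]
  epoch_set(data, tasks$label[keep], fs, t0_offset = window[1],
            channel_names = rec$channel_names)
}

#' Band-pass filter an epoch set with a linear-phase FIR filter
#'
#' Windowed-sinc (Hamming) design of order `fs` (a 1-s kernel), applied per
#' channel with group-delay compensation so the output stays aligned with
#' the input timebase.
#'
#' @param epochs A [epoch_set()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order FIR order (rounded up to even).
#' @return The filtered epoch set.
#' @export
fir_bandpass <- function(epochs, low, high, order = epochs$fs) {
  stopifnot(inherits(epochs, "bci_epochs"))
  kern <- fir_bandpass_kernel(low, high, epochs$fs, order)
  out <- epochs
  d <- dim(epochs$data)
  for (e in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out$data[e, ch, ] <- fir_apply(kern, epochs$data[e, ch, ])
  out
}

#' Per-epoch, per-channel artifact statistics
#'
#' Computes, for each epoch and channel: the peak-to-peak amplitude
#' `vpp = max(x) - min(x)` and the standard deviation `sigma` (with `n-1`
#' denominator around the channel mean `mu`) on the 4-40 Hz filtered
#' signal, and the noise-to-signal power ratio
#' `pnorm = sum(x_2040^2) / sum(x_440^2)`. A channel with zero 4-40 Hz
#' energy gets `pnorm = NA` and is flagged as undefined rather than
#' propagating NaN.
#'
#' @param epochs4_40 Epoch set filtered to 4-40 Hz.
#' @param epochs20_40 The same epochs filtered to 20-40 Hz.
#' @return A list of class `artifact_metrics` with epoch x channel matrices
#'   `vpp`, `sigma`, `pnorm`, `mu`, and `pnorm_undefined`.
#' @export
artifact_metrics <- function(epochs4_40, epochs20_40) {
  stopifnot(inherits(epochs4_40, "bci_epochs"),
            inherits(epochs20_40, "bci_epochs"),
            identical(dim(epochs4_40$data), dim(epochs20_40$data)))
  d <- dim(epochs4_40$data)
  n_e <- d[1]; n_ch <- d[2]; n_t <- d[3]
  vpp <- sigma <- pnorm <- mu <- matrix(0, n_e, n_ch)
  undef <- matrix(FALSE, n_e, n_ch)
  for (e in seq_len(n_e)) {
    x4 <- epochs4_40$data[e, , , drop = TRUE]
    x20 <- epochs20_40$data[e, , , drop = TRUE]
    if (n_ch == 1L) { x4 <- matrix(x4, 1); x20 <- matrix(x20, 1) }
    vpp[e, ] <- apply(x4, 1, max) - apply(x4, 1, min)
    mu[e, ] <- rowMeans(x4)
    sigma[e, ] <- sqrt(rowSums((x4 - mu[e, ])^2) / (n_t - 1))
    den <- rowSums(x4^2)
    num <- rowSums(x20^2)
    undef[e, ] <- den == 0
    pnorm[e, ] <- ifelse(den == 0, NA_real_, num / den)
  }
  cn <- epochs4_40$channel_names
  dimnames(vpp) <- dimnames(sigma) <- dimnames(pnorm) <- dimnames(mu) <-
    dimnames(undef) <- list(NULL, cn)
  structure(list(vpp = vpp, sigma = sigma, pnorm = pnorm, mu = mu,
                 pnorm_undefined = undef),
            class = "artifact_metrics")
}

#' Default artifact rejection thresholds
#'
#' Peak-to-peak 200 microvolts, standard deviation 50 microvolts,
#' noise-to-signal power ratio 0.7.
#'
#' @return Named list with `vpp`, `sigma`, `pnorm`.
#' @export
default_thresholds <- function() list(vpp = 200, sigma = 50, pnorm = 0.7)

#' Flag epochs that violate any artifact criterion on any channel
#'
#' An epoch is rejected if any channel exceeds any of the three thresholds
#' (strictly greater), or has an undefined power ratio. The report lists
#' every violation with its epoch, channel, criterion and value.
#'
#' @param metrics An [artifact_metrics()] result.
#' @param thresholds Named list as from [default_thresholds()].
#' @return List with `keep` (logical per epoch) and `report` (data.frame:
#'   `epoch`, `channel`, `criterion`, `value`).
#' @export
reject_epochs <- function(metrics, thresholds = default_thresholds()) {
  stopifnot(inherits(metrics, "artifact_metrics"))
  viol <- list(
    vpp = metrics$vpp > thresholds$vpp,
    sigma = metrics$sigma > thresholds$sigma,
    pnorm = !is.na(metrics$pnorm) & metrics$pnorm > thresholds$pnorm,
    pnorm_undefined = metrics$pnorm_undefined)
  n_e <- nrow(metrics$vpp)
  cn <- colnames(metrics$vpp)
  if (is.null(cn)) cn <- as.character(seq_len(ncol(metrics$vpp)))
  rows <- list()
  for (crit in names(viol)) {
    idx <- which(viol[[crit]], arr.ind = TRUE)
    if (nrow(idx)) {
      val <- switch(crit,
                    vpp = metrics$vpp[idx],
                    sigma = metrics$sigma[idx],
                    pnorm = metrics$pnorm[idx],
                    pnorm_undefined = rep(NA_real_, nrow(idx)))
      rows[[crit]] <- data.frame(epoch = idx[, 1], channel = cn[idx[, 2]],
                                 criterion = crit, value = val,
                                 stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoch = integer(), channel = character(),
               criterion = character(), value = numeric(),
               stringsAsFactors = FALSE)
  report <- report[order(report$epoch), , drop = FALSE]
  rownames(report) <- NULL
  flagged <- Reduce(`|`, lapply(viol, function(m) rowSums(m, na.rm = TRUE) > 0))
  list(keep = !flagged, report = report)
}

# subset an epoch set
epochs_subset <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$fs, epochs$t0_offset, epochs$channel_names)
}

#' Full preprocessing pipeline for one recording
#'
#' Extracts 2-s imagery epochs, computes the 4-40 / 20-40 Hz artifact
#' statistics, applies threshold rejection, and returns the retained raw
#' epochs together with the audit report.
#'
#' @param rec A [recording()].
#' @param thresholds Rejection thresholds, see [default_thresholds()].
#' @param window Epoch window in seconds around the imagery onset.
#' @return List with `epochs` (retained [epoch_set()]), `metrics`, `keep`,
#'   `report`, `n_rejected`.
#' @export
preprocess_session <- function(rec, thresholds = default_thresholds(),
                               window = c(-1, 1)) {
  epochs <- extract_epochs(rec, window)
  e440 <- fir_bandpass(epochs, 4, 40)
  e2040 <- fir_bandpass(epochs, 20, 40)
  metrics <- artifact_metrics(e440, e2040)
  rej <- reject_epochs(metrics, thresholds)
  list(epochs = epochs_subset(epochs, which(rej$keep)),
       metrics = metrics, keep = rej$keep, report = rej$report,
       n_rejected = sum(!rej$keep))
}
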