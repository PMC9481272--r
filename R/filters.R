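# Filter design helpers.
#
# The acquisition-chain band-pass (0.01-60 Hz, 6th-order Butterworth) is
# realized as a cascade of second-order sections derived from the analog
# prototype via the bilinear transform. At 250 Hz the 0.01 Hz edge has a
# normalized cutoff of 8e-5; a direct transfer-function realization of that
# filter is numerically degenerate, whereas biquads are well conditioned.

# analog Butterworth poles of order n (left half plane, unit cutoff)
butter_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# second-order sections of a digital Butterworth low- or high-pass
# returns list of list(b = c(b0,b1,b2), a = c(1,a1,a2))
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n %% 2 == 0, fc > 0, fc < fs / 2)
  K <- 2 * fs
  wa <- K * tan(pi * fc / fs)            # prewarped analog cutoff (rad/s)
  p <- butter_poles(n)
  q <- if (type == "low") p * wa else wa / p
  pairs <- lapply(seq_len(n / 2), function(i) {
    q1 <- q[i]; q2 <- Conj(q[i])         # poles come in conjugate pairs
    a0 <- Re((K - q1) * (K - q2))
    a1 <- Re(-((K - q1) * (K + q2) + (K + q1) * (K - q2)))
    a2 <- Re((K + q1) * (K + q2))
    b <- if (type == "low") wa^2 * c(1, 2, 1) else K^2 * c(1, -2, 1)
    list(b = b / a0, a = c(1, a1 / a0, a2 / a0))
  })
  pairs
}

sos_filter_once <- function(sos, x) {
  for (sec in sos) x <- as.numeric(signal::filter(sec$b, sec$a, x))
  x
}

# forward-backward (zero-phase) cascade application
sos_filtfilt <- function(sos, x) {
  x <- sos_filter_once(sos, x)
  x <- rev(sos_filter_once(sos, rev(x)))
  x
}

#' Acquisition-chain band-pass filter (0.01-60 Hz Butterworth)
#'
#' Reproduces the amplifier's digital acquisition filter: a 6th-order
#' Butterworth band-pass with cutoffs 0.01 and 60 Hz, applied per channel.
#' The filter is realized as cascaded high-pass and low-pass second-order
#' sections and applied forward-backward, so the output is zero-phase.
#'
#' @param rec A [recording()] with `fs > 120`.
#' @param low,high Cutoff frequencies in Hz.
#' @param order Filter order of each (high-pass and low-pass) section chain.
#' @return The filtered recording.
#' @export
acquisition_filter <- function(rec, low = 0.01, high = 60, order = 6) {
  stopifnot(inherits(rec, "bci_recording"))
  if (rec$fs <= 2 * high)
    stop("sampling rate ", rec$fs, " Hz too low for a ", high,
         " Hz upper cutoff", call. = FALSE)
  hp <- butter_sos(order, low, rec$fs, "high")
  lp <- butter_sos(order, high, rec$fs, "low")
  out <- rec
  for (ch in seq_len(nrow(rec$signals))) {
    x <- sos_filtfilt(hp, rec$signals[ch, ])
    out$signals[ch, ] <- sos_filtfilt(lp, x)
  }
  out
}

# linear-phase FIR band-pass kernel (windowed sinc, Hamming), odd length
fir_bandpass_kernel <- function(low, high, fs, order = fs) {
  stopifnot(low > 0, low < high, high < fs / 2)
  order <- as.integer(round(order))
  if (order %% 2 == 1) order <- order + 1L   # even order -> type I, integer delay
  as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
}

# delay-compensated single-pass FIR filtering of a vector
fir_apply <- function(kernel, x) {
  delay <- (length(kernel) - 1L) %/% 2L
  xp <- c(x, rep(0, delay))
  y <- as.numeric(signal::filter(kernel, 1, xp))
  y[(delay + 1L):(delay + length(x))]
}
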