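# Synthetic motor-imagery sessions.
#
# Every downstream stage of the stack is exercised against sessions drawn
# from this generator, which emulates the offline/online protocol: trials of
# fixation (4 s), action observation (3 s), imagery or idle (4 s) and rest
# (4 s); 45 motor-imagery and 45 idle trials per dataset; sensorimotor alpha
# and beta rhythms concentrated over central/centro-parietal electrodes; and
# event-related desynchronization (ERD) of those rhythms during motor-imagery
# trials only. Oscillations are amplitude-modulated narrowband noise rather
# than pure tones so that spatial covariances are full rank, which is what
# CSP estimation sees in real EEG.

#' Simulation configuration
#'
#' @param fs Sampling rate, Hz.
#' @param n_trials_per_class Trials per class (motor imagery / idle).
#' @param timing Named list of stage durations in seconds:
#'   `fixation`, `observation`, `imagery`, `rest`.
#' @param erd_depth Fractional attenuation (0-1) of the central alpha/beta
#'   source amplitude during motor-imagery trials. 0 disables the effect
#'   (null sessions).
#' @param ers_gain Fractional amplitude increase of the beta source in the
#'   final second of motor-imagery (event-related synchronization).
#' @param erd_onset Start of the ERD ramp in seconds relative to imagery
#'   onset. The default -1 places the ramp in the late action-observation
#'   stage: in a cued paradigm the subject knows the upcoming task, so
#'   preparatory desynchronization precedes the imagery cue.
#' @param erd_ramp Raised-cosine ramp duration, seconds.
#' @param band_amplitudes Named numeric vector, baseline oscillation
#'   amplitudes (standard deviation, microvolts) of the `alpha` (8-12 Hz)
#'   and `beta` (16-24 Hz) sources at unit-weight channels.
#' @param background_amplitude Amplitude of spatially unstructured alpha/beta
#'   background activity present on every channel, microvolts.
#' @param pink_noise_scale Standard deviation of per-channel 1/f noise,
#'   microvolts.
#' @param artifact_rates Named per-trial probabilities for `blink`,
#'   `clipping` and `emg` artifacts.
#' @param seed RNG seed; the whole session (including artifact placement)
#'   consumes a single stream seeded once.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 250,
                       n_trials_per_class = 45,
                       timing = list(fixation = 4, observation = 3,
                                     imagery = 4, rest = 4),
                       erd_depth = 0.5,
                       ers_gain = 0.3,
                       erd_onset = -1,
                       erd_ramp = 0.5,
                       band_amplitudes = c(alpha = 6, beta = 3),
                       background_amplitude = 2,
                       pink_noise_scale = 6,
                       artifact_rates = c(blink = 0, clipping = 0, emg = 0),
                       seed = 1L) {
  stopifnot(fs > 0, n_trials_per_class >= 1)
  stopifnot(all(c("fixation", "observation", "imagery", "rest") %in%
                  names(timing)))
  if (!all(unlist(timing) > 0)) stop("all stage durations must be > 0",
                                     call. = FALSE)
  if (erd_depth < 0 || erd_depth > 1)
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  if (ers_gain < 0) stop("ers_gain must be >= 0", call. = FALSE)
  stopifnot(all(c("alpha", "beta") %in% names(band_amplitudes)))
  rates <- artifact_rates[c("blink", "clipping", "emg")]
  rates[is.na(rates)] <- 0
  names(rates) <- c("blink", "clipping", "emg")
  if (any(rates < 0 | rates > 1))
    stop("artifact rates must be probabilities in [0, 1]", call. = FALSE)
  structure(list(fs = fs, n_trials_per_class = n_trials_per_class,
                 timing = timing, erd_depth = erd_depth, ers_gain = ers_gain,
                 erd_onset = erd_onset, erd_ramp = erd_ramp,
                 band_amplitudes = band_amplitudes,
                 background_amplitude = background_amplitude,
                 pink_noise_scale = pink_noise_scale,
                 artifact_rates = rates, seed = seed),
            class = "sim_config")
}

# unit-variance noise with a Gaussian spectral profile centered in [lo, hi]
narrowband_noise <- function(n, lo, hi, fs) {
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  fc <- (lo + hi) / 2
  sdev <- (hi - lo) / 4                       # band edges at +/- 2 sd
  shape <- exp(-(f - fc)^2 / (2 * sdev^2))
  x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE)) / n
  x / sd(x)
}

# unit-variance 1/f ("pink") noise
pink_noise <- function(n, fs) {
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE)) / n
  x / sd(x)
}

# spatial weights of the sensorimotor source over the standard montage
smr_topography <- function(channel_names) {
  w <- c(F3 = 0.15, Fz = 0.15, F4 = 0.15,
         FC5 = 0.25, FC1 = 0.4, FC2 = 0.4, FC6 = 0.25,
         C3 = 1, Cz = 1, C4 = 1,
         CP5 = 0.4, CP1 = 0.8, CP2 = 0.8, CP6 = 0.4,
         P3 = 0.5, Pz = 0.5, P4 = 0.5)
  out <- w[channel_names]
  out[is.na(out)] <- 0.2
  unname(out)
}

# raised-cosine step from 1 to `target` starting at sample i0, ramp `nr`
# samples, holding until sample i1, then ramping back over `nr` samples
apply_envelope_dip <- function(env, i0, i1, nr, target) {
  n <- length(env)
  ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2   # 0 -> 1
  down <- 1 + (target - 1) * ramp
  up <- target + (1 - target) * ramp
  di <- i0:min(i0 + nr - 1L, n)
  env[di] <- env[di] * down[seq_along(di)]
  hi <- min(i0 + nr, n):min(i1, n)
  if (length(hi)) env[hi] <- env[hi] * target
  ui <- min(i1 + 1L, n):min(i1 + nr, n)
  if (i1 + 1L <= n) env[ui] <- env[ui] * up[seq_along(ui)]
  env
}

#' Simulate a full motor-imagery session
#'
#' Generates a continuous recording over the 17-channel montage with one
#' event marker per trial stage. Imagery-stage markers are labeled
#' `MotorImageryA`/`IdleStateA` (sit-to-stand) or `MotorImageryB`/
#' `IdleStateB` (stand-to-sit); the class sequence is a seeded pseudo-random
#' permutation. Motor-imagery trials carry an ERD (attenuation of the
#' central alpha/beta source) across the imagery window plus a beta rebound
#' (ERS) in its final second; idle trials do not.
#'
#' @param cfg A [sim_config()].
#' @param transition `"sit-to-stand"` (labels `...A`) or `"stand-to-sit"`
#'   (labels `...B`).
#' @return A [recording()].
#' @export
simulate_session <- function(cfg = sim_config(),
                             transition = c("sit-to-stand", "stand-to-sit")) {
  stopifnot(inherits(cfg, "sim_config"))
  transition <- match.arg(transition)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  fs <- cfg$fs
  tm <- cfg$timing
  trial_dur <- tm$fixation + tm$observation + tm$imagery + tm$rest
  n_trials <- 2L * cfg$n_trials_per_class
  n <- as.integer(round(n_trials * trial_dur * fs))
  mont <- standard_montage()
  n_ch <- length(mont$names)

  classes <- sample(rep(c(1L, -1L), cfg$n_trials_per_class))
  suffix <- if (transition == "sit-to-stand") "A" else "B"
  task_label <- ifelse(classes == 1L, paste0("MotorImagery", suffix),
                       paste0("IdleState", suffix))

  # shared sensorimotor sources
  alpha_src <- narrowband_noise(n, 8, 12, fs) * cfg$band_amplitudes[["alpha"]]
  beta_src <- narrowband_noise(n, 16, 24, fs) * cfg$band_amplitudes[["beta"]]

  env_alpha <- rep(1, n)
  env_beta <- rep(1, n)
  nr <- max(2L, as.integer(round(cfg$erd_ramp * fs)))
  t0s <- (seq_len(n_trials) - 1L) * trial_dur
  im_on <- t0s + tm$fixation + tm$observation
  for (k in seq_len(n_trials)) {
    if (classes[k] != 1L) next
    i0 <- as.integer(round((im_on[k] + cfg$erd_onset) * fs)) + 1L
    i1 <- as.integer(round((im_on[k] + tm$imagery) * fs))
    i0 <- max(i0, 1L)
    target <- 1 - cfg$erd_depth
    env_alpha <- apply_envelope_dip(env_alpha, i0, i1, nr, target)
    # beta: same ERD, but rebound above baseline in the final second
    i1b <- as.integer(round((im_on[k] + tm$imagery - 1) * fs))
    env_beta <- apply_envelope_dip(env_beta, i0, i1b, nr, target)
    if (cfg$ers_gain > 0) {
      e0 <- i1b + 1L
      env_beta <- apply_envelope_dip(env_beta, e0, i1, nr,
                                     1 + cfg$ers_gain)
    }
  }

  topo <- smr_topography(mont$names)
  src <- rbind(alpha_src * env_alpha, beta_src * env_beta)
  signals <- cbind(topo, topo) %*% src   # n_ch x n

  # spatially unstructured background rhythms + 1/f noise per channel
  for (ch in seq_len(n_ch)) {
    bg <- narrowband_noise(n, 8, 12, fs) + narrowband_noise(n, 16, 24, fs)
    signals[ch, ] <- signals[ch, ] +
      cfg$background_amplitude * bg / sqrt(2) +
      cfg$pink_noise_scale * pink_noise(n, fs)
  }

  onsets <- as.vector(rbind(t0s,
                            t0s + tm$fixation,
                            im_on,
                            im_on + tm$imagery))
  durs <- rep(c(tm$fixation, tm$observation, tm$imagery, tm$rest), n_trials)
  labs <- as.vector(rbind(rep("Fixation", n_trials),
                          rep("Observation", n_trials),
                          task_label,
                          rep("Rest", n_trials)))
  rec <- recording(signals, fs, mont$names,
                   event_table(onsets, durs, labs))

  if (any(cfg$artifact_rates > 0)) {
    rec <- inject_artifacts(rec, cfg)$recording
  }
  rec
}

#' Inject blink, clipping and EMG artifacts into a recording
#'
#' Artifact types:
#' * `blink`: a 300-600 uV low-frequency half-cosine deflection on the
#'   frontal channels (F3/Fz/F4, attenuated on FC1/FC2);
#' * `clipping`: a plateau at the amplifier rail amplitude on one channel;
#' * `emg`: a 20-40 Hz broadband burst spanning the epoching window of the
#'   trial, large enough to push the 20-40/4-40 power ratio above 0.7 on the
#'   affected channel.
#'
#' Artifacts are placed inside the `[-1, +1)` s epoching window around the
#' imagery onset of the affected trial so that downstream rejection criteria
#' can be validated against the returned log.
#'
#' @param rec A [recording()] with imagery-stage task markers.
#' @param cfg A [sim_config()]; only `artifact_rates` and `fs` are used.
#' @param seed Optional seed. The default `NULL` consumes the current RNG
#'   stream (so a seeded [simulate_session()] call and its artifacts form a
#'   single reproducible stream).
#' @return A list with elements `recording` (modified copy) and `log`
#'   (data.frame: `trial`, `channel`, `type`, `onset`).
#' @export
inject_artifacts <- function(rec, cfg, seed = NULL) {
  stopifnot(inherits(rec, "bci_recording"))
  if (!is.null(seed)) set.seed(seed)
  rates <- cfg$artifact_rates
  fs <- rec$fs
  tasks <- task_events(rec)
  log <- data.frame(trial = integer(), channel = character(),
                    type = character(), onset = numeric(),
                    stringsAsFactors = FALSE)
  if (all(rates == 0) || nrow(tasks) == 0)
    return(list(recording = rec, log = log))

  sig <- rec$signals
  ch_names <- rec$channel_names
  n <- ncol(sig)
  frontal <- intersect(c("F3", "Fz", "F4"), ch_names)
  frontal_w <- stats::setNames(rep(1, length(frontal)), frontal)
  near <- intersect(c("FC1", "FC2"), ch_names)
  if (length(near)) frontal_w <- c(frontal_w, stats::setNames(rep(0.5, length(near)), near))

  add <- function(trial, channel, type, onset) {
    log[nrow(log) + 1L, ] <<- list(trial, channel, type, onset)
  }

  for (k in seq_len(nrow(tasks))) {
    on <- tasks$onset[k]
    if (stats::runif(1) < rates[["blink"]]) {
      t_b <- on + stats::runif(1, -0.8, 0.5)
      amp <- stats::runif(1, 300, 600)
      len <- as.integer(round(0.15 * fs))
      i0 <- as.integer(round(t_b * fs)) + 1L
      idx <- i0:min(i0 + len - 1L, n)
      bump <- amp * (1 - cos(2 * pi * seq_along(idx) / len)) / 2
      for (chn in names(frontal_w))
        sig[match(chn, ch_names), idx] <-
          sig[match(chn, ch_names), idx] + frontal_w[[chn]] * bump
      add(k, "F3", "blink", t_b)
    }
    if (stats::runif(1) < rates[["clipping"]]) {
      chn <- sample(ch_names, 1)
      t_c <- on + stats::runif(1, -0.8, 0.6)
      len <- as.integer(round(0.3 * fs))
      i0 <- as.integer(round(t_c * fs)) + 1L
      idx <- i0:min(i0 + len - 1L, n)
      rail <- 1500 * sample(c(-1, 1), 1)
      sig[match(chn, ch_names), idx] <- rail
      add(k, chn, "clipping", t_c)
    }
    if (stats::runif(1) < rates[["emg"]]) {
      chn <- sample(intersect(c("C3", "C4", "FC5", "FC6", "CP5", "CP6"),
                              ch_names), 1)
      t_e <- on - 1
      len <- as.integer(round(2 * fs))
      i0 <- max(1L, as.integer(round(t_e * fs)) + 1L)
      idx <- i0:min(i0 + len - 1L, n)
      burst <- 40 * narrowband_noise(length(idx), 20, 40, fs)
      sig[match(chn, ch_names), idx] <- sig[match(chn, ch_names), idx] + burst
      add(k, chn, "emg", t_e)
    }
  }
  out <- rec
  out$signals <- sig
  list(recording = out, log = log)
}
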