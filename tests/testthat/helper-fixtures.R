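# Shared fixtures, built once per test run and memoized (session generation
# and banding are the expensive steps).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# full-size offline session under default study conditions
offline_session <- function() {
  fixture("offline", simulate_session(sim_config(seed = 42)))
}

offline_preprocessed <- function() {
  fixture("offline_pp", preprocess_session(offline_session()))
}

offline_banded <- function() {
  fixture("offline_banded", apply_filter_bank(offline_preprocessed()$epochs))
}

offline_csp <- function() {
  fixture("offline_csp", fit_csp_bank(offline_banded()))
}

offline_features <- function() {
  fixture("offline_feats", logvar_features(offline_banded(), offline_csp()))
}

offline_rlda <- function() {
  fixture("offline_rlda", fit_rlda(offline_features()))
}

# small session helper (not memoized; callers pick seeds)
small_session <- function(seed, n = 15, erd = 0.5, imagery = 4,
                          artifact_rates = c(blink = 0, clipping = 0, emg = 0)) {
  simulate_session(sim_config(seed = seed, n_trials_per_class = n,
                              erd_depth = erd,
                              timing = list(fixation = 4, observation = 3,
                                            imagery = imagery, rest = 4),
                              artifact_rates = artifact_rates))
}

# white-noise epoch set for geometry/degenerate-input tests
noise_epochs <- function(n_epochs = 10, n_ch = 4, n_samp = 500, fs = 250,
                         seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels))
    labels <- rep(c("MotorImageryA", "IdleStateA"), length.out = n_epochs)
  epoch_set(array(rnorm(n_epochs * n_ch * n_samp),
                  dim = c(n_epochs, n_ch, n_samp)),
            labels = labels, fs = fs, t0_offset = -1,
            channel_names = paste0("ch", seq_len(n_ch)))
}

# Welch-style band power of one channel segment (independent of package
# filtering code; used as an oracle for ERD checks)
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  mean(sp[f >= lo & f <= hi])
}
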