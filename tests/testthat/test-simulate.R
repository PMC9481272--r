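test_that("a default session has the full trial structure and class balance", {
  rec <- offline_session()
  expect_equal(rec$fs, 250)
  expect_length(rec$channel_names, 17)
  tasks <- rec$events[rec$events$label %in%
                        c("MotorImageryA", "IdleStateA"), ]
  expect_equal(nrow(tasks), 90)
  expect_equal(sum(tasks$label == "MotorImageryA"), 45)
  expect_equal(sum(tasks$label == "IdleStateA"), 45)
  # four stage markers per trial
  expect_equal(nrow(rec$events), 360)
  expect_equal(as.vector(table(rec$events$label)[c("Fixation", "Observation",
                                                   "Rest")]),
               c(90L, 90L, 90L))
})

test_that("the same seed reproduces a session bit for bit", {
  a <- small_session(seed = 11, n = 2)
  b <- small_session(seed = 11, n = 2)
  expect_identical(a$signals, b$signals)
  expect_identical(a$events, b$events)
})

test_that("stand-to-sit sessions carry B labels", {
  rec <- simulate_session(sim_config(seed = 2, n_trials_per_class = 2),
                          transition = "stand-to-sit")
  tasks <- rec$events[grepl("B$", rec$events$label), ]
  expect_equal(nrow(tasks), 4)
})

test_that("null sessions (erd_depth = 0) have indistinguishable imagery alpha power", {
  rec <- simulate_session(sim_config(seed = 21, erd_depth = 0, ers_gain = 0))
  tasks <- rec$events[rec$events$label %in%
                        c("MotorImageryA", "IdleStateA"), ]
  c3 <- match("C3", rec$channel_names)
  p <- vapply(seq_len(nrow(tasks)), function(k) {
    i0 <- round(tasks$onset[k] * rec$fs) + 1
    band_power(rec$signals[c3, i0:(i0 + rec$fs * 2)], rec$fs, 8, 12)
  }, 0)
  mi <- tasks$label == "MotorImageryA"
  expect_gt(t.test(p[mi], p[!mi])$p.value, 0.01)
})

test_that("increasing erd_depth strictly decreases imagery alpha power of MI trials", {
  depths <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(depths, function(d) {
    rec <- simulate_session(sim_config(seed = 33, erd_depth = d,
                                       n_trials_per_class = 15))
    tasks <- rec$events[rec$events$label == "MotorImageryA", ]
    chs <- match(c("C3", "Cz", "C4"), rec$channel_names)
    mean(vapply(seq_len(nrow(tasks)), function(k) {
      i0 <- round(tasks$onset[k] * rec$fs) + 1
      mean(vapply(chs, function(ch)
        band_power(rec$signals[ch, i0:(i0 + rec$fs * 2)], rec$fs, 8, 12), 0))
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("zero artifact rates leave the session untouched with an empty log", {
  cfg <- sim_config(seed = 4, n_trials_per_class = 2)
  rec <- simulate_session(cfg)
  out <- inject_artifacts(rec, cfg, seed = 9)
  expect_identical(out$recording$signals, rec$signals)
  expect_equal(nrow(out$log), 0)
})

test_that("injected artifacts trip the matching rejection criteria downstream", {
  cfg <- sim_config(seed = 8, n_trials_per_class = 6,
                    artifact_rates = c(blink = 0, clipping = 0, emg = 0))
  rec <- simulate_session(cfg)
  for (type in c("blink", "clipping", "emg")) {
    rates <- c(blink = 0, clipping = 0, emg = 0)
    rates[type] <- 0.5
    cfg2 <- sim_config(seed = 8, n_trials_per_class = 6,
                       artifact_rates = rates)
    out <- inject_artifacts(rec, cfg2, seed = 14)
    expect_gt(nrow(out$log), 0)
    pp <- preprocess_session(out$recording)
    crit <- switch(type, blink = "vpp", clipping = c("vpp", "sigma"),
                   emg = "pnorm")
    for (k in seq_len(nrow(out$log))) {
      hits <- pp$report[pp$report$epoch == out$log$trial[k], ]
      expect_gt(nrow(hits), 0)
      expect_true(any(hits$criterion %in% crit),
                  label = paste(type, "trial", out$log$trial[k],
                                "flagged under", paste(crit, collapse = "/")))
    }
    # EMG bursts must push the affected channel's power ratio above 0.7
    if (type == "emg") {
      e440 <- fir_bandpass(extract_epochs(out$recording), 4, 40)
      e2040 <- fir_bandpass(extract_epochs(out$recording), 20, 40)
      m <- artifact_metrics(e440, e2040)
      for (k in seq_len(nrow(out$log)))
        expect_gt(m$pnorm[out$log$trial[k], out$log$channel[k]], 0.7)
    }
  }
})

test_that("acquisition filter removes DC, keeps 10 Hz, and attenuates 80 Hz", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mk <- function(x) recording(matrix(x, 1), fs, "Cz")
  mid <- seq(round(length(t) * 0.45), round(length(t) * 0.55))
  # DC is driven toward zero (0.01 Hz high-pass has a ~16 s time constant,
  # so judge the middle of a long segment)
  ydc <- acquisition_filter(mk(rep(100, length(t))))$signals[1, ]
  expect_lt(max(abs(ydc[mid])), 10)
  y10 <- acquisition_filter(mk(sin(2 * pi * 10 * t)))$signals[1, ]
  gain10 <- 20 * log10(sd(y10[mid]) / sd(sin(2 * pi * 10 * t)[mid]))
  expect_lt(abs(gain10), 1)
  y80 <- acquisition_filter(mk(sin(2 * pi * 80 * t)))$signals[1, ]
  gain80 <- 20 * log10(sd(y80[mid]) / sd(sin(2 * pi * 80 * t)[mid]))
  expect_lt(gain80, -20)
  expect_error(acquisition_filter(recording(matrix(0, 1, 10), 100, "Cz")),
               "too low")
})

test_that("simulation config validates its parameters", {
  expect_error(sim_config(erd_depth = 1.5), "erd_depth")
  expect_error(sim_config(timing = list(fixation = 0, observation = 3,
                                        imagery = 4, rest = 4)),
               "durations")
  expect_error(sim_config(artifact_rates = c(blink = 2, clipping = 0,
                                             emg = 0)),
               "probabilities")
})
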