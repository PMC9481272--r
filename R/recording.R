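# Closed vocabulary of event labels. The four imagery-stage task labels name
# the class (MotorImagery vs IdleState) and the experiment (A = sit-to-stand,
# B = stand-to-sit); the remaining three mark the other trial stages.
TASK_LABELS <- c("MotorImageryA", "IdleStateA", "MotorImageryB", "IdleStateB")
STAGE_LABELS <- c("Fixation", "Observation", "Rest")
EVENT_LABELS <- c(TASK_LABELS, STAGE_LABELS)

#' Event label vocabulary
#'
#' The closed set of event labels a session may carry: the four imagery-stage
#' task labels (`MotorImageryA`, `IdleStateA`, `MotorImageryB`, `IdleStateB`)
#' plus the stage markers `Fixation`, `Observation` and `Rest`.
#'
#' @return Character vector of the seven admissible labels.
#' @export
event_vocabulary <- function() EVENT_LABELS

#' Standard 17-electrode motor-cortex montage
#'
#' Electrode layout used for sit-to-stand / stand-to-sit recordings:
#' 17 positions of the international 10-20 system around the primary motor
#' cortex, referenced to the right earlobe with ground at AFz.
#'
#' @return A list of class `bci_montage` with elements `names` (ordered
#'   electrode labels), `reference` and `ground`.
#' @export
standard_montage <- function() {
  structure(list(
    names = c("F3", "Fz", "F4", "FC5", "FC1", "FC2", "FC6",
              "C3", "Cz", "C4", "CP5", "CP1", "CP2", "CP6",
              "P3", "Pz", "P4"),
    reference = "A2",
    ground = "AFz"
  ), class = "bci_montage")
}

#' Check channel labels against the standard montage
#'
#' @param channel_names Character vector of channel labels.
#' @param montage A `bci_montage`, by default [standard_montage()].
#' @return Invisibly `TRUE`; errors naming the offending labels otherwise.
#' @export
validate_montage <- function(channel_names, montage = standard_montage()) {
  missing <- setdiff(montage$names, channel_names)
  extra <- setdiff(channel_names, montage$names)
  if (length(missing) || length(extra)) {
    stop("channel labels do not match the 17-electrode montage; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an event table
#'
#' @param onset Numeric vector, seconds from recording start.
#' @param duration Numeric vector, seconds.
#' @param label Character vector drawn from [event_vocabulary()].
#' @return A `data.frame` with columns `onset`, `duration`, `label`, sorted
#'   by onset (stable for ties).
#' @export
event_table <- function(onset = numeric(), duration = numeric(),
                        label = character()) {
  stopifnot(length(onset) == length(duration),
            length(onset) == length(label))
  bad <- setdiff(unique(label), EVENT_LABELS)
  if (length(bad)) {
    stop("unknown event label(s): [", paste(bad, collapse = ", "),
         "]; admissible labels are: [", paste(EVENT_LABELS, collapse = ", "),
         "]", call. = FALSE)
  }
  if (any(onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  if (any(duration < 0)) stop("event durations must be >= 0", call. = FALSE)
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  ev[order(ev$onset), , drop = FALSE]  # stable sort: order() is stable
}

#' Construct a continuous EEG recording
#'
#' The core container for a session: a channels x samples amplitude matrix in
#' microvolts, the sampling rate, ordered channel labels, and an event table.
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one label per signal row.
#' @param events Event `data.frame` as from [event_table()].
#' @return A list of class `bci_recording` with fields `signals`, `fs`,
#'   `channel_names`, `events`.
#' @export
recording <- function(signals, fs, channel_names,
                      events = event_table()) {
  signals <- as.matrix(signals)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (nrow(signals) != length(channel_names))
    stop("signals has ", nrow(signals), " rows but ", length(channel_names),
         " channel names were given", call. = FALSE)
  if (!is.data.frame(events) ||
      !all(c("onset", "duration", "label") %in% names(events)))
    stop("events must be a data.frame with onset/duration/label", call. = FALSE)
  events <- event_table(events$onset, events$duration, events$label)
  t_max <- ncol(signals) / fs
  if (nrow(events) && any(events$onset > t_max + 1e-9))
    stop("event onset beyond end of recording (", t_max, " s)", call. = FALSE)
  structure(list(signals = signals, fs = fs,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs, nrow(x$events)))
  invisible(x)
}

# imagery-stage (task) markers of a recording
task_events <- function(rec) {
  rec$events[rec$events$label %in% TASK_LABELS, , drop = FALSE]
}

# map a task label to its binary class: MotorImagery -> 1, IdleState -> -1
task_class <- function(label) {
  ifelse(grepl("^MotorImagery", label), 1L, -1L)
}
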