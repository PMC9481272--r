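# Minimal EDF (European Data Format) I/O.
#
# EDF is the de-facto interchange format for clinical/BCI EEG: a 256-byte
# ASCII header, one 256-byte ASCII header block per signal, then data records
# of little-endian 16-bit integers. Amplitudes are stored against a declared
# physical range; this package fixes it at +/-2000 microvolts, so the
# quantization step is 4000/65535 ~ 0.061 uV. Events travel in a sidecar
# tab-separated table (onset / duration / label) because EDF+ annotations are
# dialect-prone.

EDF_PHYS_MIN <- -2000
EDF_PHYS_MAX <- 2000
EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'",
                             call. = FALSE)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a recording to an EDF file plus a TSV event table
#'
#' Signals are quantized to 16 bits against a fixed physical range of
#' +/-2000 microvolts; amplitudes outside that range are an error rather
#' than being clipped silently. Events are written as a tab-separated table
#' with header `onset  duration  label`.
#'
#' @param rec A [recording()].
#' @param path Output EDF file path.
#' @param events_path Output TSV event file path.
#' @return Invisibly `NULL`.
#' @export
write_recording <- function(rec, path, events_path) {
  stopifnot(inherits(rec, "bci_recording"))
  x <- rec$signals
  if (any(!is.finite(x)))
    stop("signals contain non-finite values", call. = FALSE)
  if (any(x < EDF_PHYS_MIN | x > EDF_PHYS_MAX))
    stop("signal amplitudes exceed the declared physical range [",
         EDF_PHYS_MIN, ", ", EDF_PHYS_MAX, "] uV; refusing to clip",
         call. = FALSE)
  n_ch <- nrow(x); n_samp <- ncol(x); fs <- rec$fs

  # one-second records when the length allows, else a single record
  if (fs == round(fs) && n_samp %% fs == 0 && n_samp > 0) {
    n_rec <- n_samp %/% fs; spr <- as.integer(fs); dur <- 1
  } else {
    n_rec <- 1L; spr <- n_samp; dur <- n_samp / fs
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (n_ch + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(format(dur, digits = 7), 8),
    edf_field(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width)
    paste(vapply(vals, edf_field, "", width = width), collapse = "")
  writeChar(paste0(
    per_sig(rec$channel_names, 16),
    per_sig(rep("AgAgCl electrode", n_ch), 80),
    per_sig(rep("uV", n_ch), 8),
    per_sig(rep(EDF_PHYS_MIN, n_ch), 8),
    per_sig(rep(EDF_PHYS_MAX, n_ch), 8),
    per_sig(rep(EDF_DIG_MIN, n_ch), 8),
    per_sig(rep(EDF_DIG_MAX, n_ch), 8),
    per_sig(rep("", n_ch), 80),
    per_sig(rep(spr, n_ch), 8),
    per_sig(rep("", n_ch), 32)), con, eos = NULL)

  gain <- (EDF_PHYS_MAX - EDF_PHYS_MIN) / (EDF_DIG_MAX - EDF_DIG_MIN)
  dig <- round((x - EDF_PHYS_MIN) / gain) + EDF_DIG_MIN
  storage.mode(dig) <- "integer"
  if (n_rec > 0 && spr > 0) {
    for (r in seq_len(n_rec)) {
      idx <- ((r - 1L) * spr + 1L):(r * spr)
      # record = channel 1 samples, channel 2 samples, ...
      writeBin(as.vector(t(dig[, idx, drop = FALSE])), con,
               size = 2L, endian = "little")
    }
  }

  write_events_tsv(rec$events, events_path)
  invisible(NULL)
}

write_events_tsv <- function(events, path) {
  utils::write.table(events[, c("onset", "duration", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("event file is empty (no header): ", path,
                           call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("onset", "duration", "label")))
    stop("event file must have header 'onset\\tduration\\tlabel', got: '",
         lines[1], "'", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(event_table())
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  onset <- suppressWarnings(as.numeric(vapply(parts, function(p) p[1], "")))
  duration <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2], "")))
  bad <- which(n_fields != 3L | !is.finite(onset) | !is.finite(duration))
  if (length(bad))
    stop("malformed event row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  label <- vapply(parts, function(p) p[3], "")
  event_table(onset, duration, label)
}

#' Read a recording from an EDF file plus a TSV event table
#'
#' @param path EDF file path.
#' @param events_path TSV event file path (`onset`, `duration`, `label`
#'   header); pass `NULL` for a recording without events.
#' @param montage Optional `bci_montage` to validate channel labels against;
#'   `NULL` (default) skips the check.
#' @return A [recording()] with signals in microvolts and events sorted by
#'   onset.
#' @export
read_recording <- function(path, events_path = NULL, montage = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (implied by n_ch)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  rds <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  labels <- rds(16); rds(80); rds(8)
  pmin_ <- as.numeric(rds(8)); pmax_ <- as.numeric(rds(8))
  dmin_ <- as.numeric(rds(8)); dmax_ <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8)); rds(32)

  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported",
         call. = FALSE)
  spr1 <- spr[1]
  fs <- spr1 / dur
  sig <- matrix(0, n_ch, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr1, size = 2L,
                   endian = "little")
    if (length(raw) < n_ch * spr1)
      stop("truncated EDF data record ", r, call. = FALSE)
    idx <- ((r - 1L) * spr1 + 1L):(r * spr1)
    sig[, idx] <- t(matrix(raw, nrow = spr1))
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- sweep(sweep(sig, 1, dmin_), 1, gain, `*`)
  sig <- sweep(sig, 1, pmin_, `+`)

  events <- if (is.null(events_path)) event_table() else
    read_events_tsv(events_path)
  if (!is.null(montage)) validate_montage(labels, montage)
  recording(sig, fs, labels, events)
}
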