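# Minimal EDF (European Data Format) I/O for 16-bit continuous recordings.
# Covers the plain EDF subset this package needs: one continuous multichannel
# signal, identical sampling rate on every channel, no annotations.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Plain EDF, 16-bit samples, one data record per second (a trailing
#' sub-second remainder is dropped, as EDF records are fixed-length).
#' Physical scaling is chosen per channel from the data range.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(fs)                     # samples per 1 s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  ns <- nrow(rec$data)
  data <- rec$data[, seq_len(n_rec * spr), drop = FALSE]

  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste("session", rec$session), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(sprintf("%.8g", phys_min), 8)
  field(sprintf("%.8g", phys_max), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads plain continuous EDF files where every channel shares one sampling
#' rate (the format written by [write_recording_edf()]). Channel labels are
#' matched case-insensitively against the 16-lead montage; unmatched
#' channels are dropped with a warning.
#'
#' @param path EDF path.
#' @param subject_id,session Metadata overrides; defaults come from the file
#'   header where possible.
#' @return An `eeg_recording`.
#' @export
read_recording_edf <- function(path, subject_id = NULL, session = "pre") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not a plain EDF file (version field: ", version, ")")
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     signed = TRUE, endian = "little")
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        phys_min[ch] + (dig - dig_min[ch]) * gain
    }
  }
  matched <- match_montage_channels(labels)
  if (any(is.na(matched))) {
    warning("ignoring channels not in the 16-lead montage: ",
            paste(labels[is.na(matched)], collapse = ", "))
  }
  keep <- !is.na(matched)
  eeg_recording(data[keep, , drop = FALSE], fs, channels = matched[keep],
                subject_id = subject_id %||% patient, session = session)
}
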