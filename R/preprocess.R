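#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth applied forward and backward (zero phase). The
#' broadband default of 0.5-45 Hz stands in for a "0-45 Hz" setting: a true
#' DC passband would keep slow drift that corrupts entropy and moment
#' features downstream.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Passband edges in Hz; `0 <= low < high < fs/2`. A zero
#'   `low` gives a pure low-pass.
#' @param order Butterworth order (applied twice; default 4).
#' @return A filtered `eeg_recording` of the same shape.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 4) {
  fs <- rec$sampling_rate
  if (low < 0 || high <= low) stop("need 0 <= low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency ", fs / 2, " Hz")
  filt <- if (low == 0) {
    signal::butter(order, high / (fs / 2), type = "low")
  } else {
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  }
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(filt, x)))
  rownames(out$data) <- rec$channels
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping windows; a trailing remainder shorter than one epoch is
#' discarded. All epochs start out retained.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length Epoch length in seconds (default 1).
#' @return An `epoched_eeg`: list with `epochs` (epoch x channel x sample
#'   array), `retained` (logical per epoch), `sampling_rate`, `channels`,
#'   `epoch_length`, `subject_id`, `session`.
#' @export
segment_epochs <- function(rec, epoch_length = 1) {
  if (epoch_length <= 0) stop("epoch_length must be positive")
  nsamp <- round(epoch_length * rec$sampling_rate)
  n_ep <- ncol(rec$data) %/% nsamp
  if (n_ep < 1) stop("recording shorter than one epoch")
  arr <- array(0, dim = c(n_ep, nrow(rec$data), nsamp),
               dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rec$data[, ((e - 1) * nsamp + 1):(e * nsamp)]
  }
  structure(
    list(epochs = arr, retained = rep(TRUE, n_ep),
         sampling_rate = rec$sampling_rate, channels = rec$channels,
         epoch_length = epoch_length,
         subject_id = rec$subject_id, session = rec$session),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("<epoched_eeg> %d epochs (%d retained) x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[1], sum(x$retained), dim(x$epochs)[2],
              dim(x$epochs)[3], x$sampling_rate))
  invisible(x)
}

#' Flag high-amplitude epochs as artifacts
#'
#' Any epoch in which any channel exceeds the peak-amplitude threshold is
#' flagged not-retained; the data are left untouched. This amplitude screen
#' stands in for manual component-based artifact removal.
#'
#' @param ep An `epoched_eeg`.
#' @param amplitude_threshold_uv Peak absolute amplitude in uV (default 100).
#' @return The `epoched_eeg` with an updated `retained` mask.
#' @export
reject_artifacts <- function(ep, amplitude_threshold_uv = 100) {
  if (amplitude_threshold_uv <= 0) stop("amplitude threshold must be positive")
  peaks <- apply(abs(ep$epochs), 1, max)
  ep$retained <- ep$retained & (peaks <= amplitude_threshold_uv)
  ep
}

#' Concatenate the retained epochs of each channel
#'
#' @param ep An `epoched_eeg`.
#' @return A channels x samples matrix of the retained signal.
#' @export
clean_signal <- function(ep) {
  keep <- which(ep$retained)
  if (length(keep) == 0) stop("no retained epochs")
  nsamp <- dim(ep$epochs)[3]
  out <- matrix(0, nrow = dim(ep$epochs)[2], ncol = length(keep) * nsamp,
                dimnames = list(ep$channels, NULL))
  for (i in seq_along(keep)) {
    out[, ((i - 1) * nsamp + 1):(i * nsamp)] <- ep$epochs[keep[i], , ]
  }
  out
}

#' Band-limit the retained signal of an epoched recording
#'
#' The retained epochs are concatenated per channel, zero-phase band-pass
#' filtered to the requested band, and re-segmented on the same epoch grid.
#' Filtering the concatenated signal (rather than each 1-s epoch) avoids
#' severe edge effects in the slow bands, which hold only a few cycles per
#' epoch. Non-retained epochs keep their original (broadband) data and stay
#' masked.
#'
#' @param ep An `epoched_eeg`.
#' @param band One canonical band name, or a list/row with `low` and `high`.
#' @param order Butterworth order (default 4).
#' @return An `epoched_eeg` whose retained epochs hold band-limited data.
#' @export
band_decompose <- function(ep, band, order = 4) {
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% bands$band) stop("unknown band: ", band)
    band <- as.list(bands[bands$band == band, ])
  }
  fs <- ep$sampling_rate
  if (band$high >= fs / 2) stop("band upper edge must be below Nyquist")
  keep <- which(ep$retained)
  if (length(keep) == 0) stop("no retained epochs to decompose")
  sig <- clean_signal(ep)
  filt <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
  sig <- t(apply(sig, 1, function(x) signal::filtfilt(filt, x)))
  nsamp <- dim(ep$epochs)[3]
  out <- ep
  for (i in seq_along(keep)) {
    out$epochs[keep[i], , ] <- sig[, ((i - 1) * nsamp + 1):(i * nsamp)]
  }
  out
}

#' Standard preprocessing for one recording
#'
#' Broadband zero-phase filter, 1-s epoching, amplitude-threshold artifact
#' flagging.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Broadband filter edges in Hz.
#' @param epoch_length Epoch length in seconds.
#' @param amplitude_threshold_uv Artifact peak threshold in uV.
#' @return An `epoched_eeg`.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 45, epoch_length = 1,
                                 amplitude_threshold_uv = 100) {
  rec |>
    bandpass_filter(low = low, high = high) |>
    segment_epochs(epoch_length = epoch_length) |>
    reject_artifacts(amplitude_threshold_uv = amplitude_threshold_uv)
}
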