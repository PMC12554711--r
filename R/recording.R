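#' Construct an EEG recording object
#'
#' A light container for one subject/session multichannel resting EEG:
#' a channels x time matrix in microvolts plus montage metadata.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Character vector of channel labels (rows of `data`).
#' @param subject_id Subject label.
#' @param session `"pre"` or `"post"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channels = montage_channels(),
                          subject_id = "s1", session = c("pre", "post")) {
  session <- match.arg(session)
  data <- as.matrix(data)
  if (nrow(data) != length(channels)) {
    stop("data has ", nrow(data), " rows but ", length(channels),
         " channel labels were given")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  rownames(data) <- channels
  structure(
    list(subject_id = subject_id, session = session, channels = channels,
         sampling_rate = sampling_rate, data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session, nrow(x$data), ncol(x$data),
              x$sampling_rate, ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Scalar seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

#' Write a recording to CSV
#'
#' Plain numeric matrix, one column per channel (channel labels as header),
#' one row per sample. The sampling rate is stored in a `# sampling_rate:`
#' comment on the first line.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  writeLines(sprintf("# sampling_rate: %.10g", rec$sampling_rate), path)
  df <- tibble::as_tibble(t(rec$data))
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Accepts the format written by [write_recording_csv()]: an optional
#' `# sampling_rate:` comment line, then a header of channel labels and one
#' row per sample. Channel labels are matched case-insensitively against the
#' 16-lead montage; extra channels are dropped with a warning.
#'
#' @param path CSV path.
#' @param sampling_rate Sampling rate in Hz; overrides any value found in
#'   the file comment. Required if the file has no comment.
#' @param subject_id,session Metadata for the returned recording.
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, sampling_rate = NULL,
                               subject_id = "s1", session = "pre") {
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*sampling_rate:", first)) {
    fs_file <- as.numeric(sub("^#\\s*sampling_rate:\\s*", "", first))
    if (is.null(sampling_rate)) sampling_rate <- fs_file
  }
  if (is.null(sampling_rate)) stop("sampling_rate not given and not found in file")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  matched <- match_montage_channels(names(df))
  if (any(is.na(matched))) {
    warning("ignoring channels not in the 16-lead montage: ",
            paste(names(df)[is.na(matched)], collapse = ", "))
  }
  keep <- !is.na(matched)
  data <- t(as.matrix(df[keep]))
  eeg_recording(data, sampling_rate, channels = matched[keep],
                subject_id = subject_id, session = session)
}

# case-insensitive montage matching; returns canonical labels or NA
match_montage_channels <- function(labels) {
  canon <- montage_channels()
  canon[match(tolower(labels), tolower(canon))]
}
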