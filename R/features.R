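#' Feature-extraction parameters
#'
#' Houses every tunable of the per-channel feature set. The entropy
#' defaults (m = 2, tolerance 0.2 x SD, pattern order 3, delay 1) are the
#' conventional choices for short physiological series; the tolerance is
#' recomputed per band-limited channel signal because band amplitudes
#' differ by orders of magnitude.
#'
#' @param m Embedding dimension for ApEn/SampEn.
#' @param r Tolerance as a fraction of the signal SD for ApEn/SampEn.
#' @param pe_order,pe_delay Ordinal pattern length and delay for PE.
#' @param welch_window Welch segment length in seconds.
#' @param welch_overlap Welch fractional overlap.
#' @param broadband_low,broadband_high Broadband filter edges (Hz).
#' @param epoch_length Epoch length in seconds.
#' @param amplitude_threshold_uv Artifact peak threshold in uV.
#' @param entropy_max_samples ApEn/SampEn are evaluated on at most this
#'   many leading samples of the clean band-limited signal; template
#'   matching is quadratic in length and a few thousand points saturate
#'   the estimate at m = 2.
#' @param per_epoch If `TRUE`, entropies and moments are averaged over
#'   retained 1-s epochs instead of computed once on the concatenated
#'   signal (sensitivity-analysis mode).
#' @return A `feature_params` list.
#' @export
feature_params <- function(m = 2, r = 0.2, pe_order = 3, pe_delay = 1,
                           welch_window = 2, welch_overlap = 0.5,
                           broadband_low = 0.5, broadband_high = 45,
                           epoch_length = 1, amplitude_threshold_uv = 100,
                           entropy_max_samples = 2500, per_epoch = FALSE) {
  stopifnot(m >= 1, r > 0, pe_order >= 2, pe_delay >= 1,
            welch_overlap >= 0, welch_overlap < 1)
  structure(
    list(m = m, r = r, pe_order = pe_order, pe_delay = pe_delay,
         welch_window = welch_window, welch_overlap = welch_overlap,
         broadband_low = broadband_low, broadband_high = broadband_high,
         epoch_length = epoch_length,
         amplitude_threshold_uv = amplitude_threshold_uv,
         entropy_max_samples = entropy_max_samples, per_epoch = per_epoch),
    class = "feature_params"
  )
}

feature_names <- function() {
  c("ApEn", "SampEn", "PE", "PSD", "median", "mean", "skewness", "kurtosis")
}

# the eight features of one band-limited channel signal; band power comes in
# precomputed from the broadband Welch spectrum
channel_features <- function(x, band_pow, params) {
  xe <- x[seq_len(min(length(x), params$entropy_max_samples))]
  r_abs <- params$r * stats::sd(xe)
  apen <- sampen <- NA_real_
  if (is.finite(r_abs) && r_abs > 0 && length(xe) >= params$m + 2) {
    ent <- apen_sampen_cpp(xe, as.integer(params$m), r_abs)
    apen <- ent[1]; sampen <- ent[2]
  }
  pe <- permutation_entropy(x, params$pe_order, params$pe_delay)
  # population moments, inlined (this runs 160x per recording)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- kurt <- NA_real_
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  }
  vals <- c(ApEn = apen, SampEn = sampen, PE = pe, PSD = band_pow,
            median = stats::median(x), mean = mu,
            skewness = skew, kurtosis = kurt)
  vals[!is.finite(vals)] <- NA_real_
  vals
}

#' Extract the 8 x 5 x 16 feature grid for one recording
#'
#' Preprocesses the recording (broadband filter, 1-s epochs, amplitude
#' artifact screen), then computes, per canonical band and channel, the
#' eight features: approximate entropy, sample entropy, permutation
#' entropy, Welch band power, median, mean, skewness and kurtosis. Band
#' power integrates the broadband Welch spectrum over each band; the other
#' features are computed on the band-limited concatenated clean signal.
#'
#' @param rec An `eeg_recording`.
#' @param params A [feature_params()].
#' @return A tibble with columns `subject_id`, `session`, `feature`,
#'   `band`, `channel`, `value` (8 x 5 x 16 = 640 rows).
#' @export
extract_recording_features <- function(rec, params = feature_params()) {
  ep <- preprocess_recording(
    rec, low = params$broadband_low, high = params$broadband_high,
    epoch_length = params$epoch_length,
    amplitude_threshold_uv = params$amplitude_threshold_uv
  )
  extract_epoch_features(ep, params)
}

# feature grid from an already-preprocessed epoched recording
extract_epoch_features <- function(ep, params = feature_params()) {
  broad <- clean_signal(ep)
  fs <- ep$sampling_rate
  bands <- eeg_bands()
  channels <- ep$channels

  powers <- matrix(NA_real_, length(channels), nrow(bands),
                   dimnames = list(channels, bands$band))
  for (ch in seq_along(channels)) {
    spec <- welch_spectrum(broad[ch, ], fs, params$welch_window,
                           params$welch_overlap)
    for (b in seq_len(nrow(bands))) {
      powers[ch, b] <- band_power(spec, as.list(bands[b, ]))
    }
  }

  rows <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sigb <- clean_signal(band_decompose(ep, as.list(bands[b, ])))
    vals <- lapply(seq_along(channels), function(ch) {
      if (params$per_epoch) {
        nsamp <- dim(ep$epochs)[3]
        n_ep <- ncol(sigb) / nsamp
        per <- vapply(seq_len(n_ep), function(e) {
          channel_features(sigb[ch, ((e - 1) * nsamp + 1):(e * nsamp)],
                           powers[ch, b], params)
        }, numeric(8))
        rowMeans(per, na.rm = TRUE)
      } else {
        channel_features(sigb[ch, ], powers[ch, b], params)
      }
    })
    rows[[b]] <- tibble::tibble(
      feature = rep(feature_names(), times = length(channels)),
      band = bands$band[b],
      channel = rep(channels, each = length(feature_names())),
      value = unlist(vals, use.names = FALSE)
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(subject_id = ep$subject_id, session = ep$session,
                  .before = 1)
}

#' Extract the full feature table of a pre/post cohort
#'
#' Runs [extract_recording_features()] on every subject's pre and post
#' recording. Missing entropy values (undefined sample entropy) are kept as
#' `NA` and excluded pairwise downstream.
#'
#' @param cohort A list as returned by [generate_cohort()], or the bare
#'   `recordings` element of one (a named list of `list(pre = , post = )`
#'   recording pairs).
#' @param params A [feature_params()].
#' @return A long tibble `subject_id`, `session`, `feature`, `band`,
#'   `channel`, `value` with 640 rows per subject-session.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synthetic_config(n_subjects = 3, duration = 4,
#'                                            sampling_rate = 100, seed = 1))
#' ft <- extract_features(cohort)
#' }
extract_features <- function(cohort, params = feature_params()) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  out <- purrr::imap(recs, function(pair, sid) {
    if (is.null(pair$pre) || is.null(pair$post)) {
      stop("cohort integrity error: subject ", sid,
           " is missing a pre or post session")
    }
    dplyr::bind_rows(
      extract_recording_features(pair$pre, params),
      extract_recording_features(pair$post, params)
    )
  })
  res <- dplyr::bind_rows(out)
  n_missing <- sum(is.na(res$value))
  if (n_missing > 0) {
    message(n_missing, " feature value(s) undefined; kept as NA ",
            "(excluded pairwise downstream)")
  }
  res
}

#' Write / read a feature table as long-format TSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path TSV path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    value = readr::col_double(),
                    .default = readr::col_character()
                  ))
}
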