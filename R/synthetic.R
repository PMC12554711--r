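#' Configuration for the synthetic resting-EEG cohort generator
#'
#' Describes a cohort of awake, eyes-closed resting recordings: per-band
#' sinusoidal oscillations (carrier frequency drawn uniformly inside each
#' band, per channel, fixed per subject across sessions) over 1/f^alpha
#' background noise, with a planted post-treatment amplitude change at one
#' (band, channel) whose size is proportional to the subject's sleep-scale
#' score change.
#'
#' @param n_subjects Number of subjects (>= 3 for a cohort).
#' @param sampling_rate Sampling rate in Hz (>= 100).
#' @param duration Recording length in seconds.
#' @param band_amplitudes Named numeric vector of per-band oscillation
#'   amplitudes in uV; names must be the five canonical bands.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param noise_scale Background noise standard deviation in uV.
#' @param effect_channel Channel carrying the planted effect.
#' @param effect_band Band carrying the planted effect.
#' @param effect_size Fractional post-vs-pre amplitude change per unit of
#'   score change (0 disables the effect).
#' @param effect_scale Which instrument's change drives the effect
#'   (`"isi"` or `"psqi"`).
#' @param score_change_mean,score_change_sd Normal distribution of the
#'   planted (after - before) score changes; defaults mirror the magnitude
#'   of one week of treatment in the packaged study table (improvement is
#'   negative).
#' @param seed Integer RNG seed; all generated output is a deterministic
#'   function of (seed, subject, session).
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_subjects = 4, duration = 5, seed = 1)
synthetic_config <- function(n_subjects = 15,
                             sampling_rate = 250,
                             duration = 300,
                             band_amplitudes = c(delta = 20, theta = 10,
                                                 alpha = 20, beta = 5,
                                                 gamma = 2),
                             noise_exponent = 1,
                             noise_scale = 10,
                             effect_channel = "P3",
                             effect_band = "alpha",
                             effect_size = 0,
                             effect_scale = c("isi", "psqi"),
                             score_change_mean = -4.4,
                             score_change_sd = 4,
                             seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  if (sampling_rate < 100) stop("sampling_rate must be >= 100 Hz")
  if (duration <= 0) stop("duration must be positive")
  if (!setequal(names(band_amplitudes), band_names())) {
    stop("band_amplitudes must be named with the five canonical bands")
  }
  if (!effect_channel %in% montage_channels()) {
    stop("effect_channel not in the 16-lead montage: ", effect_channel)
  }
  if (!effect_band %in% band_names()) {
    stop("effect_band must be one of the five canonical bands")
  }
  structure(
    list(n_subjects = n_subjects, sampling_rate = sampling_rate,
         duration = duration,
         band_amplitudes = band_amplitudes[band_names()],
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         effect_channel = effect_channel, effect_band = effect_band,
         effect_size = effect_size, effect_scale = effect_scale,
         score_change_mean = score_change_mean,
         score_change_sd = score_change_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# deterministic per-(subject, session) seed stream, independent of call order
derive_seed <- function(seed, subject_id, session = "") {
  key <- utf8ToInt(paste0(subject_id, "/", session))
  h <- as.numeric(seed) %% 2147483647
  for (k in key) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian 1/f^alpha noise via spectral shaping, unit variance before scaling
powerlaw_noise <- function(n, alpha) {
  white <- stats::rnorm(n)
  if (alpha == 0) return(white)
  f <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))                 # avoid dividing DC by 0
  freq <- pmin(freq, n - freq + 1)             # symmetric (aliased) frequencies
  shaped <- f / freq^(alpha / 2)
  shaped[1] <- 0
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic resting-EEG recording
#'
#' Each channel is a sum over the five bands of a fixed-amplitude sinusoid
#' at a carrier frequency drawn uniformly inside the band (per channel,
#' fixed per subject so pre and post sessions share carriers) plus
#' 1/f^alpha background noise. Deterministic given (config seed, subject,
#' session).
#'
#' @param config A [synthetic_config()].
#' @param subject_id Subject label.
#' @param session `"pre"` or `"post"`.
#' @param band_amplitude_overrides Optional named list/vector: per-band
#'   amplitude multipliers for this recording, either a scalar per band or
#'   a named per-channel vector (used to plant effects).
#' @return An `eeg_recording`.
#' @export
#' @examples
#' rec <- generate_recording(synthetic_config(duration = 2, seed = 7), "s1", "pre")
generate_recording <- function(config, subject_id, session = c("pre", "post"),
                               band_amplitude_overrides = NULL) {
  session <- match.arg(session)
  if (!is.null(band_amplitude_overrides)) {
    bad <- setdiff(names(band_amplitude_overrides), band_names())
    if (length(bad) > 0) stop("unknown band in overrides: ", paste(bad, collapse = ", "))
  }
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  channels <- montage_channels()
  bands <- eeg_bands()
  tt <- seq_len(n) / fs

  # subject-level stream: carrier frequencies, fixed across sessions
  subj <- with_local_seed(derive_seed(config$seed, subject_id), {
    list(
      freq = matrix(stats::runif(length(channels) * nrow(bands),
                                 rep(bands$low, each = length(channels)),
                                 rep(pmin(bands$high, 44.9), each = length(channels))),
                    nrow = length(channels),
                    dimnames = list(channels, bands$band)),
      phase = matrix(stats::runif(length(channels) * nrow(bands), 0, 2 * pi),
                     nrow = length(channels),
                     dimnames = list(channels, bands$band))
    )
  })

  data <- with_local_seed(derive_seed(config$seed, subject_id, session), {
    out <- matrix(0, nrow = length(channels), ncol = n,
                  dimnames = list(channels, NULL))
    for (ch in seq_along(channels)) {
      x <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        amp <- config$band_amplitudes[[bands$band[b]]]
        ov <- band_amplitude_overrides[[bands$band[b]]]
        if (!is.null(ov)) {
          mult <- if (is.null(names(ov))) {
            ov[[1]]
          } else if (channels[ch] %in% names(ov)) {
            ov[[channels[ch]]]
          } else 1
          amp <- amp * mult
        }
        x <- x + amp * sin(2 * pi * subj$freq[ch, b] * tt + subj$phase[ch, b])
      }
      if (config$noise_scale > 0) {
        x <- x + config$noise_scale * powerlaw_noise(n, config$noise_exponent)
      }
      out[ch, ] <- x
    }
    out
  })
  eeg_recording(data, fs, channels = channels,
                subject_id = as.character(subject_id), session = session)
}

#' Generate a pre/post synthetic cohort with a planted, score-linked effect
#'
#' For every subject a score change (after - before) is drawn from the
#' configured normal distribution, rounded to an integer and clipped to the
#' instrument range; the post-session amplitude of `effect_band` at
#' `effect_channel` is set to pre x (1 + effect_size x score change) for the
#' instrument named by `effect_scale`. With `effect_size = 0` the cohort is
#' a null cohort: pre and post differ only in the noise realization.
#'
#' @param config A [synthetic_config()] with `n_subjects >= 3`.
#' @return A list with `recordings` (list of per-subject lists with `pre`
#'   and `post` `eeg_recording`s) and `scores` (a scale tibble).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 3, duration = 2, seed = 1))
generate_cohort <- function(config) {
  if (config$n_subjects < 3) stop("a cohort needs n_subjects >= 3")
  n <- config$n_subjects
  ids <- as.character(seq_len(n))

  scores <- with_local_seed(derive_seed(config$seed, "cohort-scores"), {
    draw_change <- function() {
      round(stats::rnorm(n, config$score_change_mean, config$score_change_sd))
    }
    psqi_before <- pmin(pmax(round(stats::rnorm(n, 15.3, 2.8)), 5), 21)
    isi_before <- pmin(pmax(round(stats::rnorm(n, 19, 6.3)), 8), 28)
    d_psqi <- draw_change()
    d_isi <- draw_change()
    tibble::tibble(
      subject_id = ids,
      age = pmin(pmax(round(stats::rnorm(n, 42, 11)), 18), 80),
      psqi_before = psqi_before,
      isi_before = isi_before,
      psqi_after = pmin(pmax(psqi_before + d_psqi, 0), 21),
      isi_after = pmin(pmax(isi_before + d_isi, 0), 28)
    )
  })

  delta <- if (config$effect_scale == "psqi") {
    scores$psqi_after - scores$psqi_before
  } else {
    scores$isi_after - scores$isi_before
  }

  recordings <- purrr::map(seq_len(n), function(i) {
    mult <- 1 + config$effect_size * delta[i]
    if (mult <= 0) {
      stop("planted effect makes the post amplitude nonpositive for subject ",
           ids[i], " (multiplier ", signif(mult, 3), "); reduce effect_size")
    }
    ov <- stats::setNames(1, config$effect_channel)
    overrides <- stats::setNames(list(ov * mult), config$effect_band)
    list(
      pre = generate_recording(config, ids[i], "pre"),
      post = generate_recording(config, ids[i], "post",
                                band_amplitude_overrides = overrides)
    )
  })
  names(recordings) <- ids
  list(recordings = recordings, scores = scores)
}
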