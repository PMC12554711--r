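#' Welch averaged-periodogram power spectral density
#'
#' Modified periodograms (Hann taper, per-segment mean removal) averaged
#' over overlapping segments; one-sided density scaled so that the
#' integrated density approximates the signal variance (Parseval).
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments in \[0, 1) (default 0.5).
#' @return An `eeg_spectrum`: tibble with columns `frequency` (Hz) and
#'   `density` (uV^2/Hz), with attributes `sampling_rate` and `n_segments`.
#' @export
#' @examples
#' s <- welch_spectrum(sin(2 * pi * 10 * seq(0, 10, by = 1 / 250)), 250)
#' band_power(s, "alpha")
welch_spectrum <- function(x, sampling_rate, window = 2, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  nper <- round(window * sampling_rate)
  n <- length(x)
  if (nper > n) stop("window longer than the signal")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)  # periodic Hann
  u <- sum(w^2)
  n_freq <- nper %/% 2 + 1
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    pw <- Mod(stats::fft(seg))^2 / (sampling_rate * u)
    pw <- pw[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nper %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + pw * dbl
  }
  out <- tibble::tibble(
    frequency = (seq_len(n_freq) - 1) * sampling_rate / nper,
    density = acc / length(starts)
  )
  structure(out, sampling_rate = sampling_rate, n_segments = length(starts),
            class = c("eeg_spectrum", class(out)))
}

#' Integrated band power of a spectrum
#'
#' Trapezoidal integral of the spectral density over a frequency band,
#' with linear interpolation at the band edges.
#'
#' @param spectrum An `eeg_spectrum` (see [welch_spectrum()]).
#' @param band A canonical band name or a list/row with `low` and `high` Hz.
#' @return Band power in uV^2 (non-negative scalar).
#' @export
band_power <- function(spectrum, band) {
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% bands$band) stop("unknown band: ", band)
    band <- as.list(bands[bands$band == band, ])
  }
  f <- spectrum$frequency
  d <- spectrum$density
  if (band$low >= max(f) || band$high <= min(f)) return(0)
  lo <- max(band$low, min(f))
  hi <- min(band$high, max(f))
  if (hi <= lo) return(0)
  inner <- f > lo & f < hi
  fg <- c(lo, f[inner], hi)
  dg <- c(stats::approx(f, d, xout = lo)$y, d[inner],
          stats::approx(f, d, xout = hi)$y)
  sum(diff(fg) * (utils::head(dg, -1) + utils::tail(dg, -1)) / 2)
}

#' Distribution moments of a signal
#'
#' Sample median, arithmetic mean, population (biased) Fisher-Pearson
#' skewness g1, and excess kurtosis g2 (a normal distribution gives 0).
#'
#' @param x Numeric vector (length >= 4).
#' @return A one-row tibble with `median`, `mean`, `skewness`, `kurtosis`;
#'   skewness/kurtosis are `NA` for zero-variance input.
#' @export
#' @examples
#' moment_features(c(1, 2, 3, 4))
moment_features <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples")
  degenerate <- stats::sd(x) == 0
  tibble::tibble(
    median = stats::median(x),
    mean = mean(x),
    skewness = if (degenerate) NA_real_ else e1071::skewness(x, type = 1),
    kurtosis = if (degenerate) NA_real_ else e1071::kurtosis(x, type = 1)
  )
}
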