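tone_recording <- function(freq, fs = 250, dur = 10, amp = 1, offset = 0) {
  tt <- seq_len(fs * dur) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * tt) + offset, each = 16),
                 nrow = 16, byrow = FALSE)
  data <- t(vapply(1:16, function(i) amp * sin(2 * pi * freq * tt) + offset,
                   numeric(length(tt))))
  eeg_recording(data, fs)
}

test_that("broadband filter passes in-band tones and rejects out-of-band power", {
  rec10 <- tone_recording(10)
  out <- bandpass_filter(rec10, 0.5, 45)
  trim <- 500:2000  # avoid start-up transients
  expect_lt(abs(max(abs(out$data[1, trim])) - 1), 0.05)

  rec60 <- tone_recording(60)
  out60 <- bandpass_filter(rec60, 0.5, 45)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out60$data[1, trim]) / rms(rec60$data[1, trim]), 0.10)
})

test_that("the filter removes DC offset", {
  rec <- tone_recording(10, amp = 0, offset = 100)  # constant 100 uV
  out <- bandpass_filter(rec, 0.5, 45)
  expect_lt(mean(abs(out$data[1, 500:2000])), 1)
})

test_that("filter preconditions are enforced", {
  rec <- tone_recording(10, fs = 100, dur = 2)
  expect_error(bandpass_filter(rec, 0.5, 50), "Nyquist")
  expect_error(bandpass_filter(rec, 10, 5), "low < high")
})

test_that("epoch segmentation counts and remainder handling are exact", {
  rec <- eeg_recording(matrix(rnorm(16 * 300 * 250), nrow = 16), 250)
  ep <- segment_epochs(rec, 1)
  expect_equal(dim(ep$epochs), c(300, 16, 250))
  expect_true(all(ep$retained))

  rec2 <- eeg_recording(matrix(rnorm(16 * round(10.7 * 250)), nrow = 16), 250)
  expect_equal(dim(segment_epochs(rec2, 1)$epochs)[1], 10)

  short <- eeg_recording(matrix(rnorm(16 * 125), nrow = 16), 250)
  expect_error(segment_epochs(short, 1), "shorter than one epoch")
  expect_error(segment_epochs(rec, 0), "positive")
})

test_that("amplitude screening flags exactly the spiked epoch", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(16 * 10 * 100, sd = 10), nrow = 16), 100)
  rec$data[abs(rec$data) > 50] <- 50  # clamp everything within +-50 uV
  ep <- reject_artifacts(segment_epochs(rec, 1), 100)
  expect_true(all(ep$retained))

  rec$data[5, 350] <- 500  # spike inside epoch 4
  ep2 <- reject_artifacts(segment_epochs(rec, 1), 100)
  expect_equal(which(!ep2$retained), 4)

  expect_error(reject_artifacts(ep, 0), "positive")
})

test_that("band decomposition isolates band-limited content", {
  rec <- tone_recording(10, fs = 250, dur = 10)
  ep <- segment_epochs(rec, 1)
  v_in <- var(clean_signal(ep)[1, ])

  alpha <- clean_signal(band_decompose(ep, "alpha"))
  expect_lt(abs(var(alpha[1, ]) - v_in) / v_in, 0.10)

  delta <- clean_signal(band_decompose(ep, "delta"))
  expect_lt(var(delta[1, ]) / v_in, 0.05)
})

test_that("two-tone mixtures separate into their bands with little cross-talk", {
  fs <- 250; tt <- seq_len(fs * 10) / fs
  x <- sin(2 * pi * 2 * tt) + sin(2 * pi * 20 * tt)
  rec <- eeg_recording(matrix(rep(x, 16), nrow = 16, byrow = TRUE), fs)
  ep <- segment_epochs(rec, 1)
  rms <- function(z) sqrt(mean(z^2))
  d <- clean_signal(band_decompose(ep, "delta"))[1, ]
  b <- clean_signal(band_decompose(ep, "beta"))[1, ]
  ref <- rms(sin(2 * pi * 2 * tt))
  expect_lt(abs(rms(d) - ref) / ref, 0.10)
  expect_lt(abs(rms(b) - ref) / ref, 0.10)
  # cross-talk: the 2 Hz tone leaking into beta (and vice versa) stays small
  expect_lt(rms(d - sin(2 * pi * 2 * tt)[seq_along(d)]) / ref, 0.15)
})

test_that("band energies add up to the broadband energy", {
  set.seed(8)
  fs <- 250
  rec <- eeg_recording(matrix(rnorm(16 * fs * 20, sd = 10), nrow = 16), fs)
  broad <- bandpass_filter(rec, 1, 45)
  ep <- segment_epochs(broad, 1)
  v_broad <- var(clean_signal(ep)[1, ])
  v_bands <- sum(vapply(eeg_bands()$band, function(b) {
    var(clean_signal(band_decompose(ep, b))[1, ])
  }, numeric(1)))
  expect_lt(abs(v_bands - v_broad) / v_broad, 0.15)
})

test_that("band filtering is nearly idempotent", {
  rec <- tone_recording(10, fs = 250, dur = 10)
  ep <- segment_epochs(rec, 1)
  once <- band_decompose(ep, "alpha")
  twice <- band_decompose(once, "alpha")
  rms <- function(z) sqrt(mean(z^2))
  r1 <- rms(clean_signal(once)[1, ])
  r2 <- rms(clean_signal(twice)[1, ])
  expect_lt(abs(r2 - r1) / r1, 0.02)
})

test_that("concatenating retained epochs reproduces the retained signal exactly", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(16 * 1000), nrow = 16), 100)
  ep <- segment_epochs(rec, 1)
  ep$retained[c(2, 7)] <- FALSE
  sig <- clean_signal(ep)
  kept <- setdiff(1:10, c(2, 7))
  manual <- do.call(cbind, lapply(kept, function(e) {
    rec$data[, ((e - 1) * 100 + 1):(e * 100)]
  }))
  expect_identical(sig, {rownames(manual) <- rec$channels; manual})
  expect_error(clean_signal({ep$retained[] <- FALSE; ep}), "no retained")
})
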