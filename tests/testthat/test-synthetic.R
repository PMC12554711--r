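test_that("generation is deterministic given seed, subject and session", {
  cfg <- test_synth_config()
  a <- generate_recording(cfg, "s1", "pre")
  b <- generate_recording(cfg, "s1", "pre")
  expect_identical(a$data, b$data)
  # different session or subject gives a different realization
  expect_false(identical(generate_recording(cfg, "s1", "post")$data, a$data))
  expect_false(identical(generate_recording(cfg, "s2", "pre")$data, a$data))
})

test_that("a noise-free single-band recording is a pure sinusoid", {
  cfg <- synthetic_config(
    sampling_rate = 250, duration = 10, noise_scale = 0,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 3, beta = 0, gamma = 0),
    seed = 5
  )
  rec <- generate_recording(cfg, "s1", "pre")
  # variance of A sin() over many cycles ~ A^2 / 2 on every channel
  v <- apply(rec$data, 1, var)
  expect_true(all(abs(v - 9 / 2) < 0.05))
})

test_that("carrier frequencies sit inside their bands and persist across sessions", {
  cfg <- synthetic_config(
    sampling_rate = 250, duration = 20, noise_scale = 0,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 2, beta = 0, gamma = 0),
    seed = 9
  )
  pre <- generate_recording(cfg, "s3", "pre")
  post <- generate_recording(cfg, "s3", "post")
  # noise-free and amplitude-identical: pre and post share carrier and phase
  expect_equal(pre$data, post$data, tolerance = 1e-12)
  sp <- welch_spectrum(pre$data["P3", ], 250, window = 4)
  peak <- sp$frequency[which.max(sp$density)]
  expect_gte(peak, 8); expect_lt(peak, 13)
})

test_that("1/f background noise has the configured spectral slope", {
  cfg <- synthetic_config(
    sampling_rate = 250, duration = 60, noise_exponent = 1, noise_scale = 5,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
    seed = 31
  )
  rec <- generate_recording(cfg, "s1", "pre")
  sp <- welch_spectrum(rec$data[1, ], 250, window = 8)
  sel <- sp$frequency >= 1 & sp$frequency <= 40
  fit <- lm(log(density) ~ log(frequency), data = sp[sel, ])
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.3)
})

test_that("cohort generation yields complete, deterministic pre/post pairs", {
  cfg <- test_synth_config(n_subjects = 4)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$recordings, 4)
  expect_equal(nrow(cohort$scores), 4)
  expect_true(all(vapply(cohort$recordings, function(p) {
    inherits(p$pre, "eeg_recording") && inherits(p$post, "eeg_recording")
  }, logical(1))))
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$scores, cohort2$scores)
  expect_identical(cohort$recordings[["2"]]$post$data,
                   cohort2$recordings[["2"]]$post$data)
  # scores respect instrument ranges
  expect_true(all(cohort$scores$psqi_after >= 0 & cohort$scores$psqi_after <= 21))
  expect_true(all(cohort$scores$isi_after >= 0 & cohort$scores$isi_after <= 28))
})

test_that("configuration and override validation catches bad input", {
  expect_error(synthetic_config(sampling_rate = 50), ">= 100")
  expect_error(synthetic_config(duration = 0), "positive")
  expect_error(synthetic_config(effect_channel = "Cz"), "montage")
  expect_error(synthetic_config(effect_band = "mu"), "canonical")
  cfg <- test_synth_config()
  expect_error(generate_recording(cfg, "s1", "pre",
                                  band_amplitude_overrides = list(mu = 2)),
               "unknown band")
  # a planted effect that would drive the amplitude negative is an error
  strong <- test_synth_config(n_subjects = 4, effect_size = 10)
  expect_error(generate_cohort(strong), "nonpositive")
})

test_that("planted alpha effect at P3 scales band power with the score change", {
  # direct band-power readout at the planted channel over a 3-point
  # effect-size grid; |r| with the score change grows with the effect size
  mean_abs_r <- vapply(c(0, 0.02, 0.04), function(es) {
    rs <- vapply(1:20, function(k) {
      cfg <- synthetic_config(n_subjects = 8, sampling_rate = 100,
                              duration = 5, effect_size = es,
                              effect_scale = "psqi", seed = 1000 + k)
      cohort <- generate_cohort(cfg)
      dpow <- vapply(cohort$recordings, function(pair) {
        f <- function(rec) band_power(welch_spectrum(rec$data["P3", ], 100), "alpha")
        f(pair$post) - f(pair$pre)
      }, numeric(1))
      dscore <- cohort$scores$psqi_after - cohort$scores$psqi_before
      if (sd(dpow) == 0 || sd(dscore) == 0) 0 else cor(dpow, dscore)
    }, numeric(1))
    mean(abs(rs))
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) > 0))
  # no planted effect: correlations hover near zero
  expect_lt(mean_abs_r[1], 0.45)
  # strong effect: strong association
  expect_gt(mean_abs_r[3], 0.7)
})
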