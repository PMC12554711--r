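test_that("the indicator grid test covers all 640 cells and matches t.test", {
  ft <- null_cohort_features()
  tt <- ttest_all_indicators(ft)
  expect_equal(nrow(tt), 640)
  expect_true(all(tt$p >= 0 & tt$p <= 1, na.rm = TRUE))
  expect_true(all(tt$n_effective <= 10))

  # spot-check three cells against a direct paired t.test
  wide <- tidyr::pivot_wider(ft, names_from = "session", values_from = "value")
  for (i in c(1, 320, 640)) {
    cell <- tt[i, ]
    sub <- wide[wide$feature == cell$feature & wide$band == cell$band &
                  wide$channel == cell$channel, ]
    ok <- is.finite(sub$pre) & is.finite(sub$post)
    ref <- t.test(sub$post[ok], sub$pre[ok], paired = TRUE)
    expect_equal(cell$statistic, unname(ref$statistic))
    expect_equal(cell$p, ref$p.value)
  }
})

test_that("missing values are excluded pairwise with n_effective recorded", {
  ft <- small_features()
  ft$value[ft$subject_id == "1" & ft$feature == "ApEn" &
             ft$band == "delta" & ft$channel == "C3" &
             ft$session == "pre"] <- NA
  tt <- ttest_all_indicators(ft)
  cell <- tt[tt$feature == "ApEn" & tt$band == "delta" & tt$channel == "C3", ]
  expect_equal(cell$n_effective, 2)
  expect_true(cell$untestable)  # only 2 complete pairs remain of 3 subjects
})

test_that("feature differences follow the after-minus-before convention", {
  ft <- small_features()
  d <- feature_differences(ft)
  expect_equal(nrow(d), 3 * 640)
  one <- ft[ft$subject_id == "1" & ft$feature == "PSD" &
              ft$band == "alpha" & ft$channel == "P3", ]
  expect_equal(
    d$delta[d$subject_id == "1" & d$feature == "PSD" &
              d$band == "alpha" & d$channel == "P3"],
    one$value[one$session == "post"] - one$value[one$session == "pre"]
  )
})

test_that("outcome correlation reproduces the Pearson formula", {
  # identity: feature change equal to the score change gives r = 1
  diffs <- tibble::tibble(
    subject_id = as.character(1:3), feature = "PSD", band = "alpha",
    channel = "P3", delta = c(-4, -1, 2)
  )
  sd_tab <- tibble::tibble(subject_id = as.character(1:3),
                           delta_psqi = c(-4, -1, 2), delta_isi = c(3, 5, 8))
  res <- correlate_with_outcome(diffs, sd_tab, "psqi")
  expect_equal(res$statistic, 1)

  # hand-computed example: x = (1,2,3), y = (3,5,8) -> r ~ 0.9934
  diffs$delta <- 1:3
  res2 <- correlate_with_outcome(diffs, sd_tab, "isi")
  expect_equal(res2$statistic, pearson_oracle(1:3, c(3, 5, 8)))
  expect_equal(round(res2$statistic, 4), 0.9934)

  # degenerate: zero variance flagged, not crashed
  diffs$delta <- c(1, 1, 1)
  res3 <- correlate_with_outcome(diffs, sd_tab, "isi")
  expect_true(res3$untestable)
})

test_that("Pearson r is symmetric, scale-invariant and bounded", {
  set.seed(60)
  for (i in 1:25) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x))
    r <- pearson_oracle(x, y)
    expect_lte(abs(r), 1)
    expect_equal(cor(x, y), r)
    expect_equal(cor(y, x), r)
    expect_equal(cor(2 + 3 * x, y), r)
  }
})

test_that("significance selection honors alpha and the chosen correction", {
  rec <- tibble::tibble(feature = c("a", "b", "c"), p = c(0.5, 0.5, 0.5))
  expect_equal(nrow(select_significant(rec)), 0)

  rec$p <- c(0.01, 0.04, 0.2)
  expect_equal(nrow(select_significant(rec, 0.05, "none")), 2)

  # Benjamini-Hochberg step-up by hand: adjusted p = (0.03, 0.06, 0.2)
  sel_bh <- select_significant(rec, 0.05, "BH")
  expect_equal(nrow(sel_bh), 1)
  expect_equal(sel_bh$p_adjusted, 0.03)
  expect_equal(sort(p.adjust(rec$p, "BH")), c(0.03, 0.06, 0.2))

  # untestable (NA p) records are never selected
  rec$p[1] <- NA
  expect_equal(nrow(select_significant(rec, 0.05, "none")), 1)
})
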