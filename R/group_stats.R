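#' Per-subject feature changes (post - pre)
#'
#' @param features Long feature tibble from [extract_features()].
#' @return A tibble `subject_id`, `feature`, `band`, `channel`, `delta`.
#' @export
feature_differences <- function(features) {
  features |>
    tidyr::pivot_wider(names_from = "session", values_from = "value") |>
    dplyr::mutate(delta = .data$post - .data$pre) |>
    dplyr::select("subject_id", "feature", "band", "channel", "delta")
}

#' Paired pre/post t-tests over the whole indicator grid
#'
#' One paired t-test per (feature, band, channel) cell — 8 features x 5
#' bands x 16 channels = 640 tests. Subjects with a missing value in a cell
#' are excluded pairwise; the subject count actually used is reported as
#' `n_effective`. Cells with fewer than 3 complete pairs, or zero-variance
#' differences, are flagged untestable (`NA` statistic and p).
#'
#' @param features Long feature tibble from [extract_features()].
#' @return A tibble `feature`, `band`, `channel`, `statistic`, `df`, `p`,
#'   `n_effective`, `untestable`.
#' @export
ttest_all_indicators <- function(features) {
  sessions <- unique(features$session)
  if (!all(c("pre", "post") %in% sessions)) {
    stop("both pre and post sessions are required")
  }
  wide <- tidyr::pivot_wider(features, names_from = "session",
                             values_from = "value")
  wide |>
    dplyr::group_by(.data$feature, .data$band, .data$channel) |>
    dplyr::summarise(cell_ttest(.data$pre, .data$post), .groups = "drop")
}

cell_ttest <- function(pre, post) {
  ok <- is.finite(pre) & is.finite(post)
  n <- sum(ok)
  d <- post[ok] - pre[ok]
  if (n < 3 || stats::sd(d) == 0) {
    return(tibble::tibble(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          n_effective = n, untestable = TRUE))
  }
  tt <- stats::t.test(post[ok], pre[ok], paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n_effective = n, untestable = FALSE)
}

#' Correlate feature changes with a sleep-scale change
#'
#' Pearson correlation (two-tailed p) between each indicator-channel's
#' post - pre change and the chosen instrument's score change, across
#' subjects. Missing feature values are excluded pairwise.
#'
#' @param diffs Feature-difference tibble from [feature_differences()].
#' @param score_diffs Scale-difference tibble from [scale_differences()].
#' @param scale `"psqi"` or `"isi"`.
#' @return A tibble `scale`, `feature`, `band`, `channel`, `statistic`
#'   (Pearson r), `p`, `n_effective`, `untestable`.
#' @export
correlate_with_outcome <- function(diffs, score_diffs, scale = c("psqi", "isi")) {
  scale <- match.arg(scale)
  y_tab <- tibble::tibble(
    subject_id = score_diffs$subject_id,
    y = score_diffs[[paste0("delta_", scale)]]
  )
  diffs |>
    dplyr::inner_join(y_tab, by = "subject_id") |>
    dplyr::group_by(.data$feature, .data$band, .data$channel) |>
    dplyr::summarise(cell_correlation(.data$delta, .data$y), .groups = "drop") |>
    dplyr::mutate(scale = scale, .before = 1)
}

cell_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                          n_effective = n, untestable = TRUE))
  }
  ct <- stats::cor.test(x[ok], y[ok])
  tibble::tibble(statistic = unname(ct$estimate), p = ct$p.value,
                 n_effective = n, untestable = FALSE)
}

#' Select significant indicator-channel records
#'
#' Filters a statistics tibble at a significance level, optionally after
#' multiple-testing adjustment. The default (no correction) mirrors common
#' exploratory practice in small pre/post cohorts and is deliberately
#' permissive; Benjamini-Hochberg is one flag away.
#'
#' @param records Tibble with a `p` column (from [ttest_all_indicators()]
#'   or [correlate_with_outcome()]).
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default), `"BH"`, `"bonferroni"`, or any
#'   method accepted by [stats::p.adjust()].
#' @return The selected rows, with a `p_adjusted` column, ordered by it.
#' @export
select_significant <- function(records, alpha = 0.05, correction = "none") {
  testable <- records[!is.na(records$p), , drop = FALSE]
  testable$p_adjusted <- stats::p.adjust(testable$p, method = correction)
  out <- testable[testable$p_adjusted < alpha, , drop = FALSE]
  out[order(out$p_adjusted), , drop = FALSE]
}

#' Write a statistics table as TSV
#'
#' @param records Statistics tibble.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_stat_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
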