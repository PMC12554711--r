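#' Load the packaged study sleep-scale table
#'
#' Reads the per-subject scale table shipped with the package: 15 insomnia
#' patients with age and PSQI/ISI total scores before and after one week of
#' low-frequency TMS. PSQI totals range 0-21, ISI totals 0-28; higher is
#' worse on both instruments.
#'
#' @return A tibble with columns `subject_id`, `age`, `psqi_before`,
#'   `isi_before`, `psqi_after`, `isi_after`, one row per subject.
#' @export
#' @examples
#' scores <- load_study_scores()
#' mean(scores$psqi_before)
load_study_scores <- function() {
  path <- system.file("extdata", "study_scores.csv", package = "eegprognosr",
                      mustWork = TRUE)
  scores <- read_scale_table(path)
  validate_scale_table(scores, n_expected = 15L)
  scores
}

#' Read a sleep-scale table from CSV
#'
#' @param path CSV file with columns `subject_id`, `age`, `psqi_before`,
#'   `isi_before`, `psqi_after`, `isi_after`.
#' @return A tibble.
#' @export
read_scale_table <- function(path) {
  scores <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              subject_id = readr::col_character(),
                              .default = readr::col_double()
                            ))
  needed <- c("subject_id", "age", "psqi_before", "isi_before",
              "psqi_after", "isi_after")
  missing <- setdiff(needed, names(scores))
  if (length(missing) > 0) {
    stop("scale table is missing columns: ", paste(missing, collapse = ", "))
  }
  scores[needed]
}

#' Write a sleep-scale table to CSV
#'
#' @param scores A scale tibble as returned by [load_study_scores()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scale_table <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}

validate_scale_table <- function(scores, n_expected = NULL) {
  if (!is.null(n_expected) && nrow(scores) != n_expected) {
    stop("scale table integrity error: expected ", n_expected,
         " rows, found ", nrow(scores))
  }
  if (anyNA(scores)) stop("scale table integrity error: missing values")
  in_range <- function(x, lo, hi) all(x >= lo & x <= hi)
  ok <- in_range(scores$psqi_before, 0, 21) && in_range(scores$psqi_after, 0, 21) &&
    in_range(scores$isi_before, 0, 28) && in_range(scores$isi_after, 0, 28) &&
    all(scores$age > 0)
  if (!ok) stop("scale table integrity error: scores outside instrument range")
  if (anyDuplicated(scores$subject_id)) {
    stop("scale table integrity error: duplicated subject ids")
  }
  invisible(scores)
}

#' Paired t-test on before/after values
#'
#' Classical paired Student t-test on the per-subject differences
#' (after - before), two-tailed, with n - 1 degrees of freedom.
#'
#' @param before,after Numeric vectors of equal length (>= 3).
#' @return A one-row tibble with `statistic` (t), `df`, `p`, `n`,
#'   `mean_diff` (after - before).
#' @export
#' @examples
#' paired_ttest(c(1, 2, 4), c(2, 2, 5))
paired_ttest <- function(before, after) {
  if (length(before) != length(after)) stop("before/after lengths differ")
  if (length(before) < 3) stop("need at least 3 pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    stop("degenerate input: zero-variance differences")
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    n = length(d),
    mean_diff = mean(d)
  )
}

#' Paired t-tests on the PSQI and ISI total scores
#'
#' Tests whether each instrument's total score changed between the pre- and
#' post-treatment assessments.
#'
#' @param scores A scale tibble (see [load_study_scores()]).
#' @return A tibble with one row per scale: `scale`, `mean_before`,
#'   `mean_after`, `statistic`, `df`, `p`, `n`.
#' @export
#' @examples
#' scale_ttests(load_study_scores())
scale_ttests <- function(scores) {
  purrr::map_dfr(c("psqi", "isi"), function(sc) {
    before <- scores[[paste0(sc, "_before")]]
    after <- scores[[paste0(sc, "_after")]]
    res <- paired_ttest(before, after)
    tibble::tibble(
      scale = sc,
      mean_before = mean(before),
      mean_after = mean(after),
      statistic = res$statistic, df = res$df, p = res$p, n = res$n
    )
  })
}

#' Treatment responder rate under a fractional-reduction rule
#'
#' A subject is a responder when their score fell by at least `threshold`
#' of the baseline value: (before - after) / before >= threshold.
#'
#' @param scores A scale tibble.
#' @param scale `"psqi"` or `"isi"`.
#' @param threshold Fractional reduction counted as response (default 0.25).
#' @return Fraction of responders (scalar in \[0, 1\]).
#' @export
#' @examples
#' responder_rate(load_study_scores(), "psqi")
responder_rate <- function(scores, scale = c("psqi", "isi"), threshold = 0.25) {
  scale <- match.arg(scale)
  before <- scores[[paste0(scale, "_before")]]
  after <- scores[[paste0(scale, "_after")]]
  if (any(before <= 0)) stop("responder rate undefined: nonpositive baseline score")
  mean((before - after) / before >= threshold)
}

#' Per-subject scale-score changes
#'
#' Computes after - before changes for both instruments; improvement is a
#' negative change under this convention.
#'
#' @param scores A scale tibble.
#' @return A tibble with `subject_id`, `delta_psqi`, `delta_isi`.
#' @export
scale_differences <- function(scores) {
  tibble::tibble(
    subject_id = scores$subject_id,
    delta_psqi = scores$psqi_after - scores$psqi_before,
    delta_isi = scores$isi_after - scores$isi_before
  )
}
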