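#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a permutation-validated prognosis result
#'
#' @param x An `eeg_permutation` from [permutation_test()] or
#'   [run_prognosis()].
#' @param ... Unused.
#' @return A tibble with one row per subject: `observed` (true score
#'   change) and `predicted` (leave-one-out SVR prediction).
#' @export
tidy.eeg_permutation <- function(x, ...) {
  tibble::tibble(
    subject = seq_along(x$y),
    observed = x$y,
    predicted = x$loo_predictions
  )
}

#' Summarize a permutation-validated prognosis result in one row
#'
#' @inheritParams tidy.eeg_permutation
#' @return A one-row tibble: `observed_r`, `p`, `n_permutations`,
#'   `n_selected`, `n_subjects`, `seed`.
#' @export
glance.eeg_permutation <- function(x, ...) {
  tibble::tibble(
    observed_r = x$observed_r,
    p = x$p,
    n_permutations = x$n_permutations,
    n_selected = x$n_selected,
    n_subjects = length(x$y),
    seed = x$seed
  )
}

#' Plot the permutation null distribution with the observed correlation
#'
#' @param object An `eeg_permutation`.
#' @param ... Unused.
#' @return A ggplot: histogram of the permutation null correlations with a
#'   vertical line at the observed leave-one-out correlation.
#' @export
autoplot.eeg_permutation <- function(object, ...) {
  if (isTRUE(object$empty)) stop("empty prognosis result: nothing to plot")
  df <- tibble::tibble(r = object$null_rs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed_r, color = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "null correlation (rows permuted)",
      y = "count",
      title = sprintf("Observed r = %.3f, permutation p = %.4f",
                      object$observed_r, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Paired before/after scale-score plot
#'
#' One line per subject from the pre- to the post-treatment total score,
#' with group means overlaid.
#'
#' @param scores A scale tibble.
#' @param scale `"psqi"` or `"isi"`.
#' @return A ggplot.
#' @export
plot_scale_change <- function(scores, scale = c("psqi", "isi")) {
  scale <- match.arg(scale)
  long <- tibble::tibble(
    subject_id = rep(scores$subject_id, 2),
    session = rep(c("before", "after"), each = nrow(scores)),
    score = c(scores[[paste0(scale, "_before")]],
              scores[[paste0(scale, "_after")]])
  ) |>
    dplyr::mutate(session = factor(.data$session, c("before", "after")))
  means <- long |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$session, y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       color = "grey60", alpha = 0.7) +
    ggplot2::geom_point(color = "grey40") +
    ggplot2::geom_point(data = means, size = 4, color = "firebrick") +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = NULL, y = paste(toupper(scale), "total score")) +
    ggplot2::theme_minimal()
}
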