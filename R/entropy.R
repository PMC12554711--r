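#' Approximate entropy (ApEn)
#'
#' Regularity statistic over embedded templates: ApEn(m, r) =
#' Phi_m - Phi_(m+1), with self-matches included, Chebyshev distance and
#' natural logarithms. Lower values indicate a more regular series.
#'
#' @param x Numeric series (length >= m + 2).
#' @param m Embedding dimension (default 2).
#' @param r_abs Absolute match tolerance (same units as `x`); callers
#'   typically pass 0.2 times the signal SD.
#' @return Scalar; non-negative for generic signals (strictly periodic
#'   series can give small negative values, a known quirk of the
#'   self-match convention).
#' @export
#' @examples
#' approximate_entropy(sin(seq(0, 20, by = 0.1)), m = 2, r_abs = 0.2)
approximate_entropy <- function(x, m = 2, r_abs) {
  if (length(x) < m + 2) stop("series too short for embedding dimension ", m)
  if (!is.finite(r_abs) || r_abs <= 0) {
    stop("tolerance r_abs must be positive and finite (zero-variance input?)")
  }
  apen_cpp(as.numeric(x), as.integer(m), r_abs)
}

#' Sample entropy (SampEn)
#'
#' Richman-Moorman sample entropy: -log(A/B) where B counts template pairs
#' of length `m` within tolerance (Chebyshev distance, self-matches
#' excluded) and A the subset still matching at length m + 1.
#'
#' @inheritParams approximate_entropy
#' @return Non-negative scalar; `NA` when no template pairs match at length
#'   `m` (entropy undefined), `Inf` when matches exist at `m` but none
#'   extend to m + 1.
#' @export
#' @examples
#' sample_entropy(rnorm(200), m = 2, r_abs = 0.2)
sample_entropy <- function(x, m = 2, r_abs) {
  if (length(x) < m + 2) stop("series too short for embedding dimension ", m)
  if (!is.finite(r_abs) || r_abs <= 0) {
    stop("tolerance r_abs must be positive and finite (zero-variance input?)")
  }
  sampen_cpp(as.numeric(x), as.integer(m), r_abs)
}

#' Permutation entropy of ordinal patterns
#'
#' Shannon entropy (natural log) of the relative frequencies of ordinal
#' patterns of `order` consecutive (delayed) samples, optionally normalized
#' by log(order!) so the result lies in \[0, 1\]. Ties are broken by order
#' of appearance (stable ranking).
#'
#' @param x Numeric series.
#' @param order Ordinal pattern length (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @param normalized Divide by log(order!)? Default `TRUE`.
#' @return Scalar entropy; in \[0, 1\] when normalized.
#' @export
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), order = 2)
permutation_entropy <- function(x, order = 3, delay = 1, normalized = TRUE) {
  n <- length(x)
  n_pat <- n - (order - 1) * delay
  if (order < 2) stop("order must be >= 2")
  if (n_pat < 2) stop("series too short for order ", order, " and delay ", delay)
  # embed: rows = patterns, cols = order
  idx <- outer(seq_len(n_pat), (seq_len(order) - 1) * delay, `+`)
  emb <- matrix(x[idx], nrow = n_pat)
  # stable within-pattern ranks (ties broken by order of appearance),
  # computed by vectorized pairwise comparison and packed into one code
  ranks <- matrix(1L, nrow = n_pat, ncol = order)
  for (j in seq_len(order)) {
    for (k in seq_len(order)) {
      if (k == j) next
      lt <- emb[, k] < emb[, j] | (emb[, k] == emb[, j] & k < j)
      ranks[, j] <- ranks[, j] + lt
    }
  }
  codes <- as.vector(ranks %*% (order + 1)^(seq_len(order) - 1))
  p <- as.numeric(table(codes)) / n_pat
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(order)) else h
}
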