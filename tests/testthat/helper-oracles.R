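# Independent brute-force oracles, written straight from the definitions.
# They share no code with the package's Rcpp implementations.

# ApEn: Phi_m - Phi_{m+1}, self-matches included, Chebyshev, natural log
apen_oracle <- function(x, m, r) {
  phi <- function(m) {
    n <- length(x)
    nt <- n - m + 1
    templates <- lapply(seq_len(nt), function(i) x[i:(i + m - 1)])
    counts <- vapply(seq_len(nt), function(i) {
      sum(vapply(seq_len(nt), function(j) {
        max(abs(templates[[i]] - templates[[j]])) <= r
      }, logical(1)))
    }, numeric(1))
    mean(log(counts / nt))
  }
  phi(m) - phi(m + 1)
}

# SampEn: -log(A/B), self-matches excluded, n - m templates at both lengths
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  count_pairs <- function(len) {
    total <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          total <- total + 1
        }
      }
    }
    total / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# closed-form paired t statistic and two-tailed p
paired_t_oracle <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(abs(t), df = n - 1, lower.tail = FALSE))
}

# Pearson r from the definition
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
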