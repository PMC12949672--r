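# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles and never
# call the code paths they verify.

# Step-up FDR adjustment, literal definition: sort ascending,
# adj_(i) = min over j >= i of p_(j) * n / j, capped at 1, original order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n / (i:n) * ps[i:n]))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Pairwise Pearson correlation from the raw sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Welch two-sided p from the textbook t and Welch-Satterthwaite df.
welch_oracle <- function(a, b) {
  v1 <- var(a) / length(a)
  v2 <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  2 * stats::pt(-abs(t_stat), df)
}

# ARI by explicit pair counting over all unordered node pairs.
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)   # both partitions trivially identical in pair terms
  2 * (n11 * n00 - n10 * n01) / den
}

# Poisson upper tail P(X >= x) by partial pmf summation.
poisson_tail_oracle <- function(x, lambda) {
  if (x <= 0) return(1)
  1 - sum(exp(-lambda) * lambda^(0:(x - 1)) / factorial(0:(x - 1)))
}

# All set partitions of n elements as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recur <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1L)) {
      recur(c(labels, v), max(next_max, v))
    }
  }
  recur(integer(0), 0L)
  out
}
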