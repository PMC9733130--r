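# Independent oracles kept deliberately naive: they never share code with
# the implementation they check.

# O(N^2) direct-summation DFT under the negative-exponent convention.
dft_oracle <- function(values) {
  n <- length(values)
  vapply(0:(n - 1L), function(k) {
    sum(values * exp(-2i * pi * k * (0:(n - 1L)) / n))
  }, complex(1))
}

# Folded power at an arbitrary frequency index straight from the oracle DFT.
power_oracle <- function(values, k) {
  n <- length(values)
  co <- dft_oracle(values)
  if (k == 0L || k == n %/% 2L) {
    Mod(co[k + 1L])^2 / n^2
  } else {
    (Mod(co[k + 1L])^2 + Mod(co[n - k + 1L])^2) / n^2
  }
}

# Exhaustive permutation p-value at small N: enumerates all N! orderings.
exhaustive_perm_p <- function(values, dt, stat = function(v) NULL) {
  n <- length(values)
  perms <- gtools_permutations(n)
  k <- n * dt / 24
  p24 <- function(v) {
    w <- exp(-2i * pi * k * (0:(n - 1L)) / n)
    fold <- if (k == n / 2) 1 else 2
    fold * Mod(sum(v * w))^2 / n^2
  }
  obs <- p24(values)
  null <- apply(perms, 1, function(idx) p24(values[idx]))
  mean(null >= obs - 1e-12 * obs)
}

# All permutations of 1..n as a matrix (n! rows), recursive and dependency
# free.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Brute-force two-sample KS statistic: max ECDF gap over observed points.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Upper-tail hypergeometric probability from the combinatorial sum.
hyper_tail_oracle <- function(k, K, M, n) {
  if (k <= 0L) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# Step-up BH by hand: q_i = min_{j: p_j >= p_i} p_j * m / rank_j, capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(ranked, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Standard 12-point / 48-hour design used throughout the tests.
t12 <- seq(0, 44, by = 4)

random_profile <- function(n = 12L, min = 0, max = 10) {
  stats::runif(n, min, max)
}
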