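# Permutation null for the 24-h power: each draw permutes the observed
# values uniformly at random across time points and records P(24).
# Because permutation leaves the total variance fixed, ranking against this
# null is identical whether the statistic is P(24), RP24 or F24.

#' Null distribution of the 24-hour power under time-point shuffling
#'
#' @inheritParams f24
#' @return Numeric vector of `n_perm` P(24) values from permuted profiles.
#' @export
null_p24 <- function(values, dt, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  k <- k24_index(n, dt)
  w <- exp(-2i * pi * k * (0:(n - 1L)) / n)
  fold <- if (k == n %/% 2L) 1 else 2
  perm <- matrix(0, nrow = n_perm, ncol = n)
  for (i in seq_len(n_perm)) perm[i, ] <- sample(values)
  fold * Mod(perm %*% w)^2 / n^2
}

#' Permutation p-value for 24-hour rhythmicity
#'
#' Compares the observed RP24 of a profile with the RP24 distribution
#' obtained by randomly shuffling its time points. Since shuffling holds
#' the variance fixed, the rank of RP24 equals the rank of the raw 24-h
#' power P(24), which is what is actually permuted. Uses the add-one
#' estimator \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})}, so the
#' smallest attainable p is 1/(n_perm + 1); ties count against the
#' observed statistic (conservative).
#'
#' @inheritParams f24
#' @param n_perm Number of random permutations (>= 100).
#' @return p-value in (0, 1]; constant profiles return exactly 1.
#' @export
permutation_pvalue <- function(values, dt, n_perm = 10000L, seed = NULL) {
  validate_profile(values)
  if (n_perm < 100L) abort("`n_perm` must be at least 100 for a usable p resolution.")
  if (max(values) == min(values)) return(1)
  obs <- p24_power(values, dt)
  null <- null_p24(values, dt, n_perm = n_perm, seed = seed)
  .perm_p(obs, null)
}

# Shared tail count with a relative tolerance so permutations that
# reproduce the observed arrangement count as ties.
.perm_p <- function(obs, null) {
  tol <- 1e-9 * max(obs, max(null), 1e-300)
  (1 + sum(null >= obs - tol)) / (1 + length(null))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`): q_i = min over j with p_j >= p_i of
#' p_j * m / rank(p_j), capped at 1. Order-preserving in ranks and never
#' below the raw p-value.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
    abort("p-values must lie in (0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' Compares two sets of rhythmicity scores (e.g. RP24 in young versus old)
#' with the two-sample KS test. Infinite scores (noise-free sinusoids) are
#' legitimate and rank above all finite scores; they are mapped to a finite
#' value above both samples' maxima before calling the test, which leaves
#' the ECDF gap unchanged.
#'
#' @param scores_a,scores_b Numeric vectors (may contain `Inf`; `NA`
#'   dropped).
#' @return A tibble with columns `statistic` (D) and `p_value` (asymptotic).
#' @export
ks_compare <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    abort("both score vectors must be non-empty.")
  }
  finite_max <- suppressWarnings(max(c(scores_a, scores_b)[is.finite(c(scores_a, scores_b))], -Inf))
  cap <- if (is.finite(finite_max)) finite_max + 1 else 1
  scores_a[is.infinite(scores_a)] <- cap
  scores_b[is.infinite(scores_b)] <- cap
  res <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}
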