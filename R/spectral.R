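#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort
NULL

# Relative tolerance used when deciding whether sample times are equally
# spaced and whether folded powers are exactly zero.
.rhythm_tol <- 1e-9

#' Validate an expression time series
#'
#' Checks the sampling-design invariants required by the discrete Fourier
#' machinery: finite values, an even number of time points (needed for the
#' Nyquist branch of the power-spectrum fold) and, when `times` is given,
#' a strictly increasing, equally spaced grid.
#'
#' @param values Numeric vector of expression values, one per time point.
#' @param times Optional numeric vector of sample times in hours.
#' @param require_nonneg If `TRUE`, negative values are rejected (FPKM
#'   input); simulated profiles may legitimately dip below zero and are
#'   validated with `FALSE`.
#' @return `values`, invisibly.
#' @keywords internal
validate_profile <- function(values, times = NULL, require_nonneg = FALSE) {
  if (!is.numeric(values) || length(values) < 4L) {
    abort("`values` must be a numeric vector with at least 4 time points.")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort("expression values must all be finite (no NA/NaN/Inf).")
  }
  if (require_nonneg && any(values < 0)) {
    abort("expression values must be non-negative.")
  }
  if (length(values) %% 2L != 0L) {
    abort("the number of time points must be even (Nyquist fold requires it).")
  }
  if (!is.null(times)) {
    if (length(times) != length(values)) {
      abort("`times` and `values` must have the same length.")
    }
    d <- diff(times)
    if (any(d <= 0) || diff(range(d)) > .rhythm_tol * max(abs(d))) {
      abort("sample times must be strictly increasing and equally spaced.")
    }
  }
  invisible(values)
}

#' Discrete Fourier transform of an expression profile
#'
#' Computes all N complex Fourier coefficients of a regularly sampled
#' expression series under the negative-exponent convention,
#' \eqn{\hat{E}_k = \sum_{n=0}^{N-1} E_n e^{-2\pi i k n / N}}, so the DC
#' term equals the sum of the values and coefficients of a real series
#' satisfy the conjugate symmetry \eqn{\hat{E}_{N-k} = \overline{\hat{E}_k}}.
#'
#' @inheritParams validate_profile
#' @return Complex vector of length `length(values)`, indexed k = 0..N-1.
#' @examples
#' dft(cos(2 * pi * seq(0, 44, by = 4) / 24))
#' @export
dft <- function(values, times = NULL) {
  validate_profile(values, times)
  stats::fft(values)
}

#' Nyquist frequency index of a sampling design
#'
#' Half the number of time points: the highest frequency index resolvable
#' from the design (6 for 12 samples over 48 h).
#'
#' @param n_points Number of equally spaced samples (even).
#' @return Integer index N/2.
#' @export
nyquist_index <- function(n_points) {
  if (n_points %% 2L != 0L) abort("`n_points` must be even.")
  as.integer(n_points / 2L)
}

#' Valid Fourier periods of a sampling design
#'
#' The discrete Fourier grid of N samples spanning `duration` hours resolves
#' periods T/k for frequencies k = 1 up to the Nyquist index N/2. For
#' 12 points over 48 h these are 48, 24, 16, 12, 9.6 and 8 hours.
#'
#' @param n_points Number of equally spaced samples (even).
#' @param duration Total span T of the series in hours (`n_points * dt`).
#' @return A tibble with columns `k` (frequency index) and `period` (hours).
#' @export
period_grid <- function(n_points, duration) {
  half <- nyquist_index(n_points)
  k <- seq_len(half)
  tibble(k = k, period = duration / k)
}

#' Folded discrete Fourier power spectrum
#'
#' Folds the two-sided coefficient magnitudes into one power per
#' non-negative frequency: \eqn{P(T_k) = |\hat{E}_k|^2 / N^2} at k = 0 and
#' k = N/2, and \eqn{(|\hat{E}_k|^2 + |\hat{E}_{N-k}|^2)/N^2} for
#' 0 < k < N/2. The powers satisfy Parseval's identity: they sum to the
#' mean of the squared expression values, the DC power is the squared mean,
#' and the non-DC powers sum to the population variance.
#'
#' @param coeffs Complex DFT coefficients from [dft()] (real-valued input).
#' @param duration Total span T of the series in hours.
#' @return A tibble with columns `k` (0..N/2), `period` (hours; `Inf` for
#'   the DC term) and `power`.
#' @export
power_spectrum <- function(coeffs, duration) {
  n <- length(coeffs)
  if (n %% 2L != 0L) abort("power spectrum fold requires an even number of points.")
  half <- n %/% 2L
  mod2 <- Mod(coeffs)^2
  power <- numeric(half + 1L)
  power[1L] <- mod2[1L] / n^2
  power[half + 1L] <- mod2[half + 1L] / n^2
  if (half >= 2L) {
    kk <- seq_len(half - 1L)
    power[kk + 1L] <- (mod2[kk + 1L] + mod2[n - kk + 1L]) / n^2
  }
  tibble(
    k = 0:half,
    period = c(Inf, duration / seq_len(half)),
    power = power
  )
}

# Frequency index of the 24-h period for an N-point series sampled every
# dt hours; errors when 24 h is not on the Fourier grid.
k24_index <- function(n_points, dt) {
  k <- n_points * dt / 24
  if (abs(k - round(k)) > .rhythm_tol || round(k) < 1 ||
      round(k) > n_points / 2) {
    abort(paste0(
      "no 24-hour period on the Fourier grid for N = ", n_points,
      ", dt = ", dt, " h; periods available: ",
      paste(signif(n_points * dt / seq_len(n_points %/% 2), 4), collapse = ", ")
    ))
  }
  as.integer(round(k))
}

#' Relative spectral power of one Fourier period
#'
#' The power at the signal frequency `k_signal` divided by the summed power
#' of every other non-DC frequency, i.e. a signal-to-noise ratio on the
#' Fourier grid. Returns `Inf` for a noise-free signal (zero denominator,
#' positive numerator) and `NA` for a constant profile (0/0).
#'
#' @param spectrum Power-spectrum tibble from [power_spectrum()].
#' @param k_signal Frequency index treated as the signal (1..N/2).
#' @return Non-negative scalar, `Inf`, or `NA_real_`.
#' @export
rp_score <- function(spectrum, k_signal) {
  k_max <- max(spectrum$k)
  if (k_signal < 1L || k_signal > k_max) {
    abort(paste0("`k_signal` must lie in [1, ", k_max, "] (Nyquist index)."))
  }
  p_sig <- spectrum$power[spectrum$k == k_signal]
  denom <- sum(spectrum$power[spectrum$k != 0L & spectrum$k != k_signal])
  # denominators that are pure floating-point dust relative to the signal
  # (noise-free sinusoids) count as zero
  if (denom <= .rhythm_tol^2 * p_sig) {
    if (p_sig > 0) Inf else NA_real_
  } else {
    p_sig / denom
  }
}

#' Relative power of the 24-hour period (RP24)
#'
#' RP24 is the power of the 24-hour Fourier component divided by the summed
#' power of all other non-DC components. It quantifies the strength of the
#' diurnal signal relative to everything else in the profile. For the
#' standard design (12 samples over 48 h) the 24-h component is frequency
#' index 2.
#'
#' @inheritParams rp_score
#' @return Non-negative scalar; `Inf` for a noise-free 24-h sinusoid; `NA`
#'   for a constant profile.
#' @export
rp24 <- function(spectrum) {
  hit <- which(is.finite(spectrum$period) &
                 abs(spectrum$period - 24) < .rhythm_tol * 24)
  if (length(hit) != 1L) {
    abort("the spectrum has no 24-hour period; check N and dt.")
  }
  rp_score(spectrum, spectrum$k[hit])
}

# Power of the 24-h component straight from the values (fast path used by
# the permutation machinery). Computes only the k24 coefficient.
p24_power <- function(values, dt) {
  n <- length(values)
  k <- k24_index(n, dt)
  w <- exp(-2i * pi * k * (0:(n - 1L)) / n)
  fold <- if (k == n %/% 2L) 1 else 2
  fold * Mod(sum(values * w))^2 / n^2
}

#' Peak-time (phase) of the 24-hour component
#'
#' Writing the 24-h component as \eqn{A\cos(2\pi t/24 + \varphi)}, the phase
#' in Zeitgeber hours is the time of peak expression,
#' \eqn{-12\varphi/\pi} reduced modulo 24 into [0, 24). \eqn{\varphi} is the
#' argument of the 24-h Fourier coefficient under the negative-exponent
#' convention of [dft()].
#'
#' @param values Numeric expression values on a regular grid.
#' @param dt Sampling interval in hours.
#' @return Phase in hours in [0, 24); `NA` for a constant profile.
#' @export
phase24 <- function(values, dt) {
  validate_profile(values)
  if (max(values) == min(values)) return(NA_real_)
  n <- length(values)
  k <- k24_index(n, dt)
  coeff <- sum(values * exp(-2i * pi * k * (0:(n - 1L)) / n))
  if (Mod(coeff) == 0) return(NA_real_)
  (-12 * Arg(coeff) / pi) %% 24
}

#' Permutation-normalised 24-hour power (F24)
#'
#' The observed power of the 24-h component divided by its mean over
#' uniformly random permutations of the values across time points. A score
#' of 1 means the 24-h power is no larger than expected for a random
#' arrangement of the same values.
#'
#' @inheritParams phase24
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Integer seed making the permutation draw reproducible.
#' @return Non-negative scalar; `NA` for a constant profile.
#' @export
f24 <- function(values, dt, n_perm = 1000L, seed = NULL) {
  validate_profile(values)
  if (n_perm < 1L) abort("`n_perm` must be at least 1.")
  if (max(values) == min(values)) return(NA_real_)
  obs <- p24_power(values, dt)
  null <- null_p24(values, dt, n_perm = n_perm, seed = seed)
  obs / mean(null)
}
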