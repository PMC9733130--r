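# Spike ("staccato") screening and two-condition rhythm classification.
#
# A staccato profile is baseline expression plus a burst at one time point
# per 24-h cycle (indices phi and phi + N/2). Its DFT is
# E_k = 2*dE*exp(-2*pi*i*k*phi/N) for even k != 0 and exactly 0 for odd k,
# so spike profiles concentrate power on even frequencies with coordinated
# arguments — the two facts the SP and PVEC scores exploit.

#' Spectral parity (even/odd power bias)
#'
#' Natural log of the ratio of summed folded power at even non-DC
#' frequencies to that at odd frequencies. Spike-per-cycle profiles put all
#' power on even frequencies, giving `Inf`; smooth noisy profiles give
#' values near 0.
#'
#' @param spectrum Power-spectrum tibble from [power_spectrum()].
#' @return Scalar; `Inf` when odd power is exactly zero and even power is
#'   positive; `NA` when both are zero (constant profile).
#' @export
spectral_parity <- function(spectrum) {
  k <- spectrum$k
  even <- sum(spectrum$power[k != 0L & k %% 2L == 0L])
  odd <- sum(spectrum$power[k %% 2L == 1L])
  if (even == 0 && odd == 0) return(NA_real_)
  if (odd <= .rhythm_tol^2 * even) return(Inf)  # dust-level odd power
  log(even / odd)
}

#' Phase variance of even Fourier coefficients (PVEC)
#'
#' Dispersion of the arguments of the even-indexed Fourier coefficients
#' (k = 2, 4, ..., N/2). For an ideal spike profile the arguments are
#' arg(E_k) = -2*pi*k*phi/N: after re-aligning each coefficient by the
#' estimated spike index (multiplying by exp(+2*pi*i*k*phi_hat/N)) they are
#' all equal, so PVEC = 0 exactly. Dispersion is measured circularly as
#' 1 minus the mean resultant length of the aligned arguments, avoiding
#' the wrap-around discontinuity of a linear variance.
#'
#' @param coeffs Complex DFT coefficients from [dft()].
#' @param values Optional raw values used to estimate the spike index
#'   (position of the maximum); when omitted the index is taken as 0 (no
#'   re-alignment).
#' @return Scalar in [0, 1]; `NA` when fewer than two even coefficients
#'   have non-zero magnitude.
#' @export
pvec <- function(coeffs, values = NULL) {
  n <- length(coeffs)
  half <- n %/% 2L
  k_even <- seq(2L, half, by = 2L)
  mags <- Mod(coeffs[k_even + 1L])
  tol <- .rhythm_tol * max(Mod(coeffs), 1e-300)
  usable <- mags > tol
  if (sum(usable) < 2L) return(NA_real_)
  phi_hat <- if (is.null(values)) 0L else (which.max(values) - 1L) %% half
  k_use <- k_even[usable]
  aligned <- coeffs[k_use + 1L] * exp(+2i * pi * k_use * phi_hat / n)
  r <- Mod(mean(exp(1i * Arg(aligned))))
  max(0, 1 - r)
}

#' Fraction of profile variance explained by a two-spike model
#'
#' Fits the idealised spike model (baseline plus a burst at the estimated
#' spike index and its 24-h repeat) by averaging inside and outside the
#' spike positions, and reports the R-squared of that fit. Near 1 for true
#' spike profiles, well below 1 for smooth rhythms.
#'
#' @param values Numeric expression values on a regular grid (even length).
#' @return Scalar in [0, 1]; `NA` for a constant profile.
#' @export
spike_variance_fraction <- function(values) {
  n <- length(values)
  half <- n %/% 2L
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot == 0) return(NA_real_)
  phi_hat <- (which.max(values) - 1L) %% half
  idx <- c(phi_hat, phi_hat + half) + 1L
  e0 <- mean(values[-idx])
  fitted <- rep(e0, n)
  fitted[idx] <- mean(values[idx])
  max(0, 1 - sum((values - fitted)^2) / ss_tot)
}

#' Max/min fold change of a profile
#'
#' @inheritParams spike_variance_fraction
#' @return `max(values)/min(values)`; `Inf` when the minimum is 0 and the
#'   maximum positive; 1 for a non-zero constant profile; `NA` for an
#'   all-zero profile.
#' @export
max_min_fold <- function(values) {
  mx <- max(values)
  mn <- min(values)
  if (mx == 0 && mn == 0) return(NA_real_)
  if (mn == 0) return(Inf)
  mx / mn
}

#' Classification thresholds
#'
#' Bundles every cutoff used by detectability filtering, the spike screen
#' and two-condition classification. Defaults follow the standard analysis:
#' rhythmic at q <= 0.05, arrhythmic at q >= 0.075 (the open band between
#' is indeterminate), detectable at >= 1.5 max/min fold change and median
#' expression >= 1 FPKM, with the fold requirement relaxed to 1.4 in the
#' non-anchor age for robust cyclers. The spike-screen cutoffs (`sp_min`,
#' `pvec_max`, `spike_var_min`) were calibrated once on simulated smooth
#' and spike profiles and then frozen.
#'
#' @param q_rhythmic q-value at or below which a transcript is rhythmic.
#' @param q_arrhythmic q-value at or above which it is arrhythmic.
#' @param fold_detectable Max/min fold change required for detectability.
#' @param fold_relaxed Relaxed fold change for the non-anchor age of a
#'   robust cycler.
#' @param median_fpkm_min Minimum median expression (FPKM).
#' @param sp_min Minimum spectral parity for the spike screen.
#' @param pvec_max Maximum PVEC for the spike screen.
#' @param spike_var_min Minimum spike-model variance fraction for the
#'   spike screen.
#' @return A list with class `"rhythm_thresholds"`.
#' @export
rhythm_thresholds <- function(q_rhythmic = 0.05,
                              q_arrhythmic = 0.075,
                              fold_detectable = 1.5,
                              fold_relaxed = 1.4,
                              median_fpkm_min = 1,
                              sp_min = 2,
                              pvec_max = 0.15,
                              spike_var_min = 0.75) {
  if (!(q_rhythmic < q_arrhythmic)) {
    abort("`q_rhythmic` must be strictly below `q_arrhythmic`.")
  }
  if (!(fold_relaxed < fold_detectable)) {
    abort("`fold_relaxed` must be strictly below `fold_detectable`.")
  }
  structure(
    list(
      q_rhythmic = q_rhythmic, q_arrhythmic = q_arrhythmic,
      fold_detectable = fold_detectable, fold_relaxed = fold_relaxed,
      median_fpkm_min = median_fpkm_min,
      sp_min = sp_min, pvec_max = pvec_max, spike_var_min = spike_var_min
    ),
    class = "rhythm_thresholds"
  )
}

#' Detectability of a profile
#'
#' A transcript is detectable when its max/min fold change meets the fold
#' threshold and its median expression is at least the FPKM floor.
#'
#' @param fold Max/min fold change (from [max_min_fold()]).
#' @param median_expr Median expression of the profile.
#' @param thresholds A [rhythm_thresholds()] object.
#' @param fold_key Either `"fold_detectable"` (1.5) or `"fold_relaxed"`
#'   (1.4).
#' @return Logical scalar (`NA` fold fails).
#' @export
is_detectable <- function(fold, median_expr, thresholds = rhythm_thresholds(),
                          fold_key = c("fold_detectable", "fold_relaxed")) {
  fold_key <- match.arg(fold_key)
  !is.na(fold) && fold >= thresholds[[fold_key]] &&
    median_expr >= thresholds$median_fpkm_min
}

# Spike screen on one profile's scores; NA components fail the screen
# (a pure sinusoid has SP = Inf but undefined PVEC, so it is never flagged).
is_staccato <- function(sp, pv, spike_frac, thresholds) {
  isTRUE(sp >= thresholds$sp_min) &&
    isTRUE(pv <= thresholds$pvec_max) &&
    isTRUE(spike_frac >= thresholds$spike_var_min)
}

#' Classify one transcript across two conditions
#'
#' Assigns one of the six labels: `staccato_filtered` when either
#' condition's profile is flagged by the spike screen; `indeterminate` when
#' either q-value falls strictly inside the open band between the rhythmic
#' and arrhythmic cutoffs; `ELC` (early life cycler: rhythmic and
#' detectable in the first condition, arrhythmic in the second); `LLC`
#' (late life cycler: the mirror image); `RLC` (robust life cycler:
#' rhythmic in both, detectable at the full fold threshold in at least one
#' condition with the other passing the relaxed fold and the median floor);
#' otherwise `NR`.
#'
#' Constant or otherwise score-less profiles carry q = 1 and therefore
#' count as arrhythmic; they can never be classified rhythmic.
#'
#' @param q_a,q_b q-values in conditions A (e.g. young) and B (e.g. old).
#' @param fold_a,fold_b Max/min fold changes.
#' @param median_a,median_b Median expression levels.
#' @param staccato_a,staccato_b Logical spike-screen flags.
#' @param thresholds A [rhythm_thresholds()] object.
#' @return Character scalar label.
#' @export
classify_pair <- function(q_a, q_b, fold_a, fold_b, median_a, median_b,
                          staccato_a = FALSE, staccato_b = FALSE,
                          thresholds = rhythm_thresholds()) {
  if (anyNA(c(q_a, q_b))) abort("both conditions must have a q-value (use q = 1 for undefined scores).")
  if (isTRUE(staccato_a) || isTRUE(staccato_b)) return("staccato_filtered")
  th <- thresholds
  in_band <- function(q) q > th$q_rhythmic && q < th$q_arrhythmic
  if (in_band(q_a) || in_band(q_b)) return("indeterminate")
  det <- function(fold, med, key) is_detectable(fold, med, th, key)
  rhythmic_a <- q_a <= th$q_rhythmic
  rhythmic_b <- q_b <= th$q_rhythmic
  if (rhythmic_a && rhythmic_b) {
    full_a <- det(fold_a, median_a, "fold_detectable")
    full_b <- det(fold_b, median_b, "fold_detectable")
    relax_a <- det(fold_a, median_a, "fold_relaxed")
    relax_b <- det(fold_b, median_b, "fold_relaxed")
    if ((full_a && relax_b) || (full_b && relax_a)) return("RLC")
    return("NR")
  }
  if (rhythmic_a && q_b >= th$q_arrhythmic &&
      det(fold_a, median_a, "fold_detectable")) return("ELC")
  if (rhythmic_b && q_a >= th$q_arrhythmic &&
      det(fold_b, median_b, "fold_detectable")) return("LLC")
  "NR"
}

#' Classify all transcripts in a score table
#'
#' Takes the long per-condition score table from [score_rhythmicity()] and
#' returns one label per transcript, comparing `condition_a` (the "young"
#' role in ELC/LLC naming) against `condition_b`.
#'
#' @param scores Score tibble with columns `transcript_id`, `condition`,
#'   `q_value`, `max_min_fold`, `median_expr`, `staccato`.
#' @param thresholds A [rhythm_thresholds()] object.
#' @param condition_a,condition_b The two condition labels to compare.
#' @return A tibble with columns `transcript_id` and `class`.
#' @export
classify_transcripts <- function(scores,
                                 thresholds = rhythm_thresholds(),
                                 condition_a = "young",
                                 condition_b = "old") {
  need <- c("transcript_id", "condition", "q_value", "max_min_fold",
            "median_expr", "staccato")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0L) {
    abort(paste0("`scores` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  a <- scores[scores$condition == condition_a, ]
  b <- scores[scores$condition == condition_b, ]
  ids <- union(a$transcript_id, b$transcript_id)
  lost <- c(setdiff(ids, a$transcript_id), setdiff(ids, b$transcript_id))
  if (length(lost) > 0L) {
    abort(paste0("transcripts missing one condition: ",
                 paste(utils::head(unique(lost), 10), collapse = ", ")))
  }
  a <- a[match(ids, a$transcript_id), ]
  b <- b[match(ids, b$transcript_id), ]
  cls <- vapply(seq_along(ids), function(i) {
    classify_pair(
      q_a = a$q_value[i], q_b = b$q_value[i],
      fold_a = a$max_min_fold[i], fold_b = b$max_min_fold[i],
      median_a = a$median_expr[i], median_b = b$median_expr[i],
      staccato_a = a$staccato[i], staccato_b = b$staccato[i],
      thresholds = thresholds
    )
  }, character(1))
  tibble(transcript_id = ids, class = cls)
}

#' Rhythmic-overlap summary between two conditions
#'
#' Counts transcripts rhythmic (q at or below the rhythmic cutoff and
#' detectable at the full fold threshold) only in condition A, only in B,
#' or in both — the Euler-diagram summary of an ageing comparison.
#'
#' @inheritParams classify_transcripts
#' @return A one-row tibble with columns `only_a`, `only_b`, `both`.
#' @export
rhythmic_overlap_summary <- function(scores,
                                     thresholds = rhythm_thresholds(),
                                     condition_a = "young",
                                     condition_b = "old") {
  rhythmic <- function(cond) {
    s <- scores[scores$condition == cond, ]
    ok <- s$q_value <= thresholds$q_rhythmic & !s$staccato &
      vapply(seq_len(nrow(s)), function(i) {
        is_detectable(s$max_min_fold[i], s$median_expr[i], thresholds,
                      "fold_detectable")
      }, logical(1))
    s$transcript_id[ok & !is.na(ok)]
  }
  ra <- rhythmic(condition_a)
  rb <- rhythmic(condition_b)
  tibble(
    only_a = length(setdiff(ra, rb)),
    only_b = length(setdiff(rb, ra)),
    both = length(intersect(ra, rb))
  )
}
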