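#' @importFrom dplyr group_by summarise arrange mutate ungroup filter n
#' @importFrom dplyr left_join select distinct bind_rows
NULL

#' Score rhythmicity of every transcript in a long expression table
#'
#' The main scoring verb. For each (transcript, condition) profile it
#' computes the folded Fourier power spectrum and derives: RP24 (24-h power
#' over all other non-DC power), F24 (24-h power over its mean under
#' time-point permutation), the peak phase in Zeitgeber hours, a
#' permutation p-value, the Benjamini-Hochberg q-value (within condition),
#' the max/min fold change, the median expression, the spike-screen scores
#' (spectral parity, PVEC, spike-model variance fraction) and the
#' resulting spike flag.
#'
#' The p-value and F24 share one seeded permutation set per profile:
#' permutation leaves the profile's variance fixed, so the permutation rank
#' of RP24, F24 and the raw 24-h power are identical.
#'
#' Constant profiles have no defined RP24/F24/phase; they are reported with
#' `NA` scores and p = q = 1, so they can never be called rhythmic.
#'
#' @param expr Long tibble with columns `transcript_id`, `condition`,
#'   `time` (hours) and `value`; optionally `replicate` (collapsed first).
#' @param n_perm Number of permutations per profile.
#' @param seed Integer master seed; per-profile seeds are derived from it
#'   so results do not depend on row order.
#' @param collapse How to collapse replicate measurements at the same time
#'   point: `"mean"` (default) or `"median"`.
#' @param log2_transform If `TRUE`, score `log2(value + 1)` instead of raw
#'   values (fold change and median are still reported on the raw scale).
#' @param thresholds [rhythm_thresholds()] used only for the spike flag.
#' @return A tibble of class `rhythm_scores` with one row per transcript
#'   per condition and columns `transcript_id`, `condition`, `rp24`, `f24`,
#'   `phase`, `p_value`, `q_value`, `max_min_fold`, `median_expr`, `sp`,
#'   `pvec`, `spike_frac`, `staccato`.
#' @examples
#' expr <- simulate_dataset(n_elc = 3, n_rlc = 3, n_llc = 0, n_nr = 3,
#'                          n_staccato = 0, seed = 1)$expression
#' score_rhythmicity(expr, n_perm = 200, seed = 1)
#' @export
score_rhythmicity <- function(expr,
                              n_perm = 1000L,
                              seed = 1L,
                              collapse = c("mean", "median"),
                              log2_transform = FALSE,
                              thresholds = rhythm_thresholds()) {
  collapse <- match.arg(collapse)
  need <- c("transcript_id", "condition", "time", "value")
  missing_cols <- setdiff(need, names(expr))
  if (length(missing_cols) > 0L) {
    abort(paste0("`expr` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  fun <- if (collapse == "mean") mean else stats::median
  expr <- expr |>
    group_by(.data$transcript_id, .data$condition, .data$time) |>
    summarise(value = fun(.data$value), .groups = "drop") |>
    arrange(.data$condition, .data$transcript_id, .data$time)

  profiles <- split(expr, interaction(expr$condition, expr$transcript_id, drop = TRUE))
  # stable deterministic order independent of input row order
  keys <- vapply(profiles, function(p) paste(p$condition[1], p$transcript_id[1]), character(1))
  profiles <- profiles[order(keys)]

  set.seed(seed)
  profile_seeds <- sample.int(.Machine$integer.max, length(profiles))

  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    score_profile(p$value, p$time,
                  transcript_id = p$transcript_id[1],
                  condition = p$condition[1],
                  n_perm = n_perm, seed = profile_seeds[i],
                  log2_transform = log2_transform,
                  thresholds = thresholds)
  })
  out <- bind_rows(rows)
  out <- out |>
    group_by(.data$condition) |>
    mutate(q_value = bh_qvalues(.data$p_value)) |>
    ungroup() |>
    arrange(.data$condition, .data$transcript_id) |>
    select(
      "transcript_id", "condition", "rp24", "f24", "phase", "p_value",
      "q_value", "max_min_fold", "median_expr", "sp", "pvec",
      "spike_frac", "staccato"
    )
  structure(out,
            class = c("rhythm_scores", class(out)),
            n_perm = n_perm, seed = seed)
}

# Score one profile: all per-profile statistics except the q-value.
score_profile <- function(values, times, transcript_id, condition,
                          n_perm, seed, log2_transform, thresholds) {
  validate_profile(values, times)
  dt <- times[2] - times[1]
  duration <- length(values) * dt
  raw <- values
  if (log2_transform) values <- log2(values + 1)

  coeffs <- dft(values)
  spec <- power_spectrum(coeffs, duration)
  constant <- max(values) == min(values)

  if (constant) {
    rp <- NA_real_; f <- NA_real_; ph <- NA_real_; p <- 1
  } else {
    rp <- rp24(spec)
    obs <- p24_power(values, dt)
    null <- null_p24(values, dt, n_perm = n_perm, seed = seed)
    f <- obs / mean(null)
    p <- .perm_p(obs, null)
    ph <- phase24(values, dt)
  }

  sp <- spectral_parity(spec)
  pv <- pvec(coeffs, values)
  frac <- spike_variance_fraction(values)

  tibble(
    transcript_id = transcript_id,
    condition = condition,
    rp24 = rp, f24 = f, phase = ph,
    p_value = p,
    max_min_fold = max_min_fold(raw),
    median_expr = stats::median(raw),
    sp = sp, pvec = pv, spike_frac = frac,
    staccato = is_staccato(sp, pv, frac, thresholds)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rhythm score table
#'
#' Returns the underlying tibble stripped of the `rhythm_scores` class.
#'
#' @param x A `rhythm_scores` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy rhythm_scores
#' @export
tidy.rhythm_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rhythm_scores")
  attr(out, "n_perm") <- NULL
  attr(out, "seed") <- NULL
  as_tibble(out)
}

#' One-row summary of a rhythm score table
#'
#' @param x A `rhythm_scores` object.
#' @param ... Unused.
#' @return A one-row tibble with transcript/condition counts, the
#'   permutation settings and the attainable p-value resolution.
#' @method glance rhythm_scores
#' @export
glance.rhythm_scores <- function(x, ...) {
  tibble(
    n_transcripts = length(unique(x$transcript_id)),
    n_conditions = length(unique(x$condition)),
    n_perm = attr(x, "n_perm"),
    seed = attr(x, "seed"),
    p_resolution = 1 / (attr(x, "n_perm") + 1),
    n_staccato_flagged = sum(x$staccato, na.rm = TRUE)
  )
}
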