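# Phase geometry: the 24-h clock face used by circular histograms and
# dot-and-arrow plots. ZT0 (lights-on) sits at the top of the clock, ZT6
# at 3 o'clock, ZT12 (lights-off) at the bottom; angles run clockwise.

#' Logistic scaling of a rhythmicity score
#'
#' Maps RP24 from [0, Inf] onto [0, 1] via `rp / (1 + rp)`, the base-2
#' logistic of `S = log2(rp)`. Strictly increasing, with 0 -> 0, 1 -> 0.5
#' and Inf -> 1, so noise-free sinusoids sit on the unit circle.
#'
#' @param rp Numeric vector of non-negative scores (may contain `Inf`).
#' @return Numeric vector in [0, 1].
#' @export
logistic_scale <- function(rp) {
  if (anyNA(rp)) abort("undefined scores cannot be placed on the clock; drop NA first.")
  if (any(rp < 0)) abort("scores must be non-negative.")
  ifelse(is.infinite(rp), 1, rp / (1 + rp))
}

#' Polar clock-face state of (RP24, phase) pairs
#'
#' Converts each transcript's rhythmicity state to a point on the unit
#' disc: radius `rp/(1+rp)` and angle `theta = pi/2 - phase * pi/12`, i.e.
#' ZT0 up, clockwise clock. The point is `z = radius * exp(i * theta)`.
#'
#' @param df Data frame with columns named by `rp_col` and `phase_col`.
#' @param rp_col,phase_col Column names for the score and the phase
#'   (hours in [0, 24)).
#' @return The input with columns `radius`, `theta`, `x`, `y` appended.
#' @export
polar_state <- function(df, rp_col = "rp24", phase_col = "phase") {
  rp <- df[[rp_col]]
  phase <- df[[phase_col]]
  if (is.null(rp) || is.null(phase)) {
    abort(paste0("`df` must have columns `", rp_col, "` and `", phase_col, "`."))
  }
  radius <- logistic_scale(rp)
  theta <- pi / 2 - phase * pi / 12
  dplyr::mutate(as_tibble(df),
                radius = radius, theta = theta,
                x = radius * cos(theta), y = radius * sin(theta))
}

#' Signed circular difference between two phases
#'
#' Shortest signed arc from `from` to `to` on the 24-h circle, in
#' (-12, +12] hours. Positive values are phase delays (peak moves later),
#' negative values are advances; an exact 12-h change is reported as a
#' delay (+12).
#'
#' @param from,to Phases in hours.
#' @return Signed difference in hours.
#' @export
circular_phase_diff <- function(from, to) {
  d <- (to - from) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Circular histogram of peak phases
#'
#' Bins phases into equal half-open intervals around the 24-h clock
#' (default 30-minute bins, 48 in total). Counts sum to the number of
#' phases supplied.
#'
#' @param phases Numeric vector of phases in [0, 24) hours.
#' @param bin_minutes Bin width in minutes; must divide 24 h evenly.
#' @return A tibble of class `rhythm_phase_hist` with columns `bin_start`,
#'   `bin_mid` (hours) and `count`.
#' @export
circular_histogram <- function(phases, bin_minutes = 30) {
  if ((24 * 60) %% bin_minutes != 0) {
    abort("`bin_minutes` must divide 24 hours evenly.")
  }
  if (any(phases < 0 | phases >= 24)) {
    abort("phases must lie in [0, 24).")
  }
  width <- bin_minutes / 60
  n_bins <- as.integer(24 / width)
  idx <- pmin(floor(phases / width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  out <- tibble(
    bin_start = (seq_len(n_bins) - 1L) * width,
    bin_mid = (seq_len(n_bins) - 0.5) * width,
    count = counts
  )
  structure(out, class = c("rhythm_phase_hist", class(out)))
}

#' Circular median of phases on the 24-h clock
#'
#' The data point minimising the summed absolute circular distance to all
#' other points; ties broken by the smaller clock time.
#'
#' @param phases Numeric vector of phases in hours.
#' @return Scalar phase in [0, 24).
#' @export
circular_median <- function(phases) {
  if (length(phases) == 0L) abort("`phases` must be non-empty.")
  phases <- phases %% 24
  cost <- vapply(phases, function(p) {
    sum(abs(circular_phase_diff(p, phases)))
  }, numeric(1))
  sort(phases[cost == min(cost)])[1]
}

#' Dot-and-arrow coordinate table for a two-condition comparison
#'
#' Builds the geometry behind the clock-face "dot and arrow" plot: each
#' transcript is drawn as a dot at its (RP24, phase) state in the first
#' condition and an arrow pointing to its state in the second. Also
#' reports the signed circular phase change and its direction
#' (`"advance"`, `"delay"` or `"none"`).
#'
#' @param scores A [score_rhythmicity()] table (long, per condition).
#' @param condition_from,condition_to Condition labels for dot and arrow
#'   tip.
#' @param ids Optional transcript subset; defaults to all transcripts with
#'   defined phases in both conditions. Transcripts requested but missing
#'   a defined state in either condition are an error.
#' @return A tibble of class `rhythm_arrows` with columns `transcript_id`,
#'   `x_from`, `y_from`, `x_to`, `y_to`, `delta_phase_hours`, `direction`.
#' @export
dot_and_arrow <- function(scores, condition_from = "young",
                          condition_to = "old", ids = NULL) {
  pick <- function(cond) {
    s <- scores[scores$condition == cond &
                  !is.na(scores$rp24) & !is.na(scores$phase), ]
    s[, c("transcript_id", "rp24", "phase")]
  }
  a <- pick(condition_from)
  b <- pick(condition_to)
  if (is.null(ids)) {
    ids <- intersect(a$transcript_id, b$transcript_id)
  } else {
    lost <- c(setdiff(ids, a$transcript_id), setdiff(ids, b$transcript_id))
    if (length(lost) > 0L) {
      abort(paste0("no defined rhythm state in both conditions for: ",
                   paste(unique(lost), collapse = ", ")))
    }
  }
  a <- polar_state(a[match(ids, a$transcript_id), ])
  b <- polar_state(b[match(ids, b$transcript_id), ])
  delta <- circular_phase_diff(a$phase, b$phase)
  out <- tibble(
    transcript_id = ids,
    x_from = a$x, y_from = a$y,
    x_to = b$x, y_to = b$y,
    delta_phase_hours = delta,
    direction = dplyr::case_when(
      delta > 0 ~ "delay",
      delta < 0 ~ "advance",
      TRUE ~ "none"
    )
  )
  structure(out, class = c("rhythm_arrows", class(out)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Unit circle with ZT tick marks shared by the clock-face plots.
clock_face_layers <- function() {
  circ <- tibble(
    t = seq(0, 2 * pi, length.out = 241),
    x = cos(t), y = sin(t)
  )
  ticks <- polar_state(tibble(rp24 = Inf, phase = c(0, 6, 12, 18)))
  list(
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey70"),
    ggplot2::geom_text(
      data = ticks,
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                   label = paste0("ZT", .data$phase)),
      size = 3, colour = "grey30"
    ),
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)),
    ggplot2::theme_void()
  )
}

#' Plot a dot-and-arrow clock face
#'
#' @param object A `rhythm_arrows` table from [dot_and_arrow()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhythm_arrows
#' @export
autoplot.rhythm_arrows <- function(object, ...) {
  ggplot2::ggplot(object) +
    clock_face_layers() +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x_from, y = .data$y_from,
                   xend = .data$x_to, yend = .data$y_to,
                   colour = .data$direction),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$x_from, y = .data$y_from,
                   colour = .data$direction),
      size = 1
    ) +
    ggplot2::scale_colour_manual(
      values = c(advance = "#d95f02", delay = "#1b9e77", none = "grey50")
    )
}

#' Plot a circular phase histogram on the 24-h clock
#'
#' @param object A `rhythm_phase_hist` table from [circular_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhythm_phase_hist
#' @export
autoplot.rhythm_phase_hist <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_start[2] - object$bin_start[1],
                      fill = "#1b9e77", colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = c(0, 6, 12, 18),
                                labels = paste0("ZT", c(0, 6, 12, 18))) +
    ggplot2::labs(x = NULL, y = "transcripts") +
    ggplot2::theme_minimal()
}
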