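# Tabular IO. Expression matrices are TSV with transcript ids in the
# first column and one column per sample named <condition>_ZT<time>[_r<rep>],
# e.g. young_ZT0_r1. Scores and coordinate tables are written back as TSV.

#' Read a wide expression matrix into a long profile table
#'
#' Parses sample columns named `<condition>_ZT<time>` or
#' `<condition>_ZT<time>_r<replicate>`, collapses replicates at the same
#' time point, and checks that every condition has a complete, equally
#' spaced time grid.
#'
#' @param path Path to a tab-separated file; first column is the
#'   transcript id.
#' @param collapse Replicate collapse rule: `"mean"` (default) or
#'   `"median"`.
#' @return A long tibble with columns `transcript_id`, `condition`,
#'   `time`, `value`.
#' @export
read_expression_matrix <- function(path, collapse = c("mean", "median")) {
  collapse <- match.arg(collapse)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ))
  if (ncol(raw) < 2L) abort("expression matrix needs an id column plus sample columns.")
  id_col <- names(raw)[1]
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate transcript ids: ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  sample_cols <- names(raw)[-1]
  m <- stringr::str_match(sample_cols,
                          "^(.+)_ZT(\\d+(?:\\.\\d+)?)(?:_r(\\d+))?$")
  bad <- sample_cols[is.na(m[, 1])]
  if (length(bad) > 0L) {
    abort(paste0("sample columns not matching <condition>_ZT<time>[_r<rep>]: ",
                 paste(bad, collapse = ", ")))
  }
  # numeric check with coordinates
  for (j in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad_rows <- which(is.na(v) & !is.na(raw[[j]]))
    if (anyNA(raw[[j]]) || length(bad_rows) > 0L) {
      row1 <- if (length(bad_rows) > 0L) bad_rows[1] else which(is.na(raw[[j]]))[1]
      abort(paste0("non-numeric or missing value in column `", j,
                   "`, row ", row1, " (", ids[row1], ")."))
    }
    raw[[j]] <- v
  }
  long <- raw |>
    tidyr::pivot_longer(-dplyr::all_of(id_col),
                        names_to = "sample", values_to = "value") |>
    dplyr::rename(transcript_id = dplyr::all_of(id_col))
  meta <- tibble(
    sample = sample_cols,
    condition = m[, 2],
    time = as.numeric(m[, 3]),
    replicate = ifelse(is.na(m[, 4]), 1L, as.integer(m[, 4]))
  )
  long <- left_join(long, meta, by = "sample")
  if (any(long$value < 0)) abort("expression values must be non-negative.")

  fun <- if (collapse == "mean") mean else stats::median
  long <- long |>
    group_by(.data$transcript_id, .data$condition, .data$time) |>
    summarise(value = fun(.data$value), .groups = "drop")

  # each condition must present a complete, equally spaced grid
  for (cond in unique(long$condition)) {
    tt <- sort(unique(long$time[long$condition == cond]))
    if (length(tt) < 4L) {
      abort(paste0("condition `", cond, "` has fewer than 4 time points."))
    }
    d <- diff(tt)
    if (diff(range(d)) > 1e-9 * max(d)) {
      gap_at <- tt[which.max(d)]
      abort(paste0("condition `", cond,
                   "` has an uneven time grid: gap after ZT", gap_at, "."))
    }
  }
  arrange(long, .data$condition, .data$transcript_id, .data$time)
}

#' Write a long profile table as a wide expression matrix
#'
#' Inverse of [read_expression_matrix()]; useful for writing simulated
#' fixtures in the dialect the scorer reads.
#'
#' @param expr Long tibble with `transcript_id`, `condition`, `time`,
#'   `value`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  wide <- expr |>
    mutate(sample = sprintf("%s_ZT%g", .data$condition, .data$time)) |>
    select("transcript_id", "sample", "value") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a score or coordinate table as TSV
#'
#' @param x A tibble (e.g. from [score_rhythmicity()] or
#'   [dot_and_arrow()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every tunable of a scoring/classification run into one
#' serialisable object: permutation settings, q-value bands, detectability
#' thresholds, spike-screen cutoffs and the expected time grid. Written
#' next to each run's outputs so results are reproducible from the file
#' alone.
#'
#' @param n_perm Permutations per profile.
#' @param seed Master seed.
#' @param thresholds A [rhythm_thresholds()] object.
#' @param n_points,dt Expected time grid.
#' @param collapse Replicate collapse rule.
#' @param log2_transform Score log2(FPKM + 1) instead of raw FPKM.
#' @return A list of class `rhythm_config`.
#' @export
rhythm_config <- function(n_perm = 10000L, seed = 1L,
                          thresholds = rhythm_thresholds(),
                          n_points = 12L, dt = 4,
                          collapse = "mean", log2_transform = FALSE) {
  structure(
    list(n_perm = n_perm, seed = seed, thresholds = unclass(thresholds),
         n_points = n_points, dt = dt, collapse = collapse,
         log2_transform = log2_transform),
    class = "rhythm_config"
  )
}

#' Write a run configuration as JSON
#' @param config A [rhythm_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path Path written by [write_config()].
#' @return A `rhythm_config` object (thresholds re-validated).
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(rhythm_thresholds, x$thresholds)
  rhythm_config(
    n_perm = x$n_perm, seed = x$seed, thresholds = th,
    n_points = x$n_points, dt = x$dt, collapse = x$collapse,
    log2_transform = x$log2_transform
  )
}
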