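# Quiescent-bout calling and summaries from displacement series.

#' Detect quiescent bouts in a displacement series
#'
#' A frame is "still" when its inter-frame pixel displacement is at or below
#' `zero_threshold` (default 0, matching displacement data that are already
#' binarized upstream). A quiescent bout is a maximal run of still frames at
#' least `min_run` frames long -- the default of 9 frames is 27 s at the
#' standard 3 s frame interval. Runs shorter than `min_run` count as
#' movement. `NA` displacements (dropped frames) break runs: a gap never
#' fabricates stillness.
#'
#' @param series Either a numeric displacement vector for one animal, or a
#'   tidy data frame with columns `animal_id`, `frame_index`, `displacement`
#'   (and optionally `group`), as produced by [simulate_displacement()].
#' @param zero_threshold Displacements `<=` this value are still (>= 0).
#' @param min_run Minimum run length, in frames, for a bout (>= 1).
#' @param dt Seconds per frame; for data-frame input the `dt` attribute is
#'   used when present.
#' @param animal_id Identifier used for vector input.
#' @return A tibble of class `bout_set`: one row per bout with columns
#'   `animal_id`, `start_frame`, `end_frame`, `n_frames`, `seconds`.
#'   Intervals are half-open `[start_frame, end_frame)` over 0-based frame
#'   indices, so `seconds = (end_frame - start_frame) * dt`. Attributes:
#'   `dt`, `min_run`, `zero_threshold`, and `series_length` (named per
#'   animal).
#' @export
#' @examples
#' detect_bouts(c(1, rep(0, 9), 2))   # one 9-frame (27 s) bout
#' detect_bouts(c(1, rep(0, 8), 2))   # 8 frames: below threshold, no bout
detect_bouts <- function(series, zero_threshold = 0, min_run = 9L,
                         dt = 3, animal_id = "animal") {
  check_number(zero_threshold, "zero_threshold", lower = 0)
  check_number(min_run, "min_run", lower = 1)
  check_number(dt, "dt", lower = 1e-12)

  if (is.data.frame(series)) {
    check_columns(series, c("animal_id", "frame_index", "displacement"),
                  "displacement table")
    if (!is.null(attr(series, "dt"))) dt <- attr(series, "dt")
    ids <- unique(series$animal_id)
    parts <- lapply(ids, function(id) {
      sub <- series[series$animal_id == id, ]
      sub <- sub[order(sub$frame_index), ]
      detect_bouts(sub$displacement, zero_threshold, min_run, dt, id)
    })
    out <- dplyr::bind_rows(parts)
    attr(out, "dt") <- dt
    attr(out, "min_run") <- as.integer(min_run)
    attr(out, "zero_threshold") <- zero_threshold
    attr(out, "series_length") <- unlist(lapply(parts, attr, "series_length"))
    class(out) <- c("bout_set", class(tibble::tibble()))
    return(out)
  }

  if (!is.numeric(series) || length(series) == 0L) {
    stop_wormsleep("`series` must be a non-empty numeric vector")
  }
  if (any(series < 0, na.rm = TRUE)) {
    stop_wormsleep("displacement values must be >= 0")
  }
  still <- !is.na(series) & series <= zero_threshold
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  out <- tibble::tibble(
    animal_id = rep(animal_id, sum(keep)),
    start_frame = starts[keep] - 1L,          # 0-based, half-open
    end_frame = ends[keep],
    n_frames = r$lengths[keep],
    seconds = r$lengths[keep] * dt
  )
  attr(out, "dt") <- dt
  attr(out, "min_run") <- as.integer(min_run)
  attr(out, "zero_threshold") <- zero_threshold
  attr(out, "series_length") <- setNames(length(series), animal_id)
  class(out) <- c("bout_set", class(out))
  out
}

#' Total quiescence per hour bin
#'
#' Tiles the recording into half-open bins of `bin_width` seconds anchored
#' at the start of the series (the end of training) and sums quiescent-bout
#' time in each bin, in minutes. Bouts straddling a boundary are split at
#' the boundary by frame counting: frame `i` (0-based) belongs to bin
#' `floor(i * dt / bin_width)`.
#'
#' @param bouts A `bout_set` from [detect_bouts()].
#' @param series The displacement input the bouts were derived from (vector
#'   or data frame, as in [detect_bouts()]); supplies series length and the
#'   animal/group labels.
#' @param bin_width Bin width in seconds (default 3600).
#' @return Tibble `animal_id` (, `group`), `hour_bin` (0 = first bin after
#'   training), `minutes`. Every bin covered by the recording appears, with
#'   0 for bins without quiescence.
#' @export
quiescence_by_hour <- function(bouts, series, bin_width = 3600) {
  stopifnot(inherits(bouts, "bout_set"))
  check_number(bin_width, "bin_width", lower = 1e-9)
  dt <- attr(bouts, "dt")

  if (is.data.frame(series)) {
    check_columns(series, c("animal_id", "frame_index"), "displacement table")
    lens <- tapply(series$frame_index, series$animal_id, function(f) {
      max(f) + 1L
    })
    ids <- unique(series$animal_id)
    groups <- if ("group" %in% names(series)) {
      vapply(ids, function(id) {
        as.character(series$group[series$animal_id == id][1])
      }, character(1))
    } else NULL
  } else {
    ids <- names(attr(bouts, "series_length"))
    lens <- attr(bouts, "series_length")
    groups <- NULL
  }
  if (!all(unique(bouts$animal_id) %in% ids)) {
    stop_wormsleep("bouts contain animal_id values absent from `series`")
  }

  parts <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    n <- as.integer(lens[[id]])
    n_bins <- max(1L, ceiling(n * dt / bin_width))
    mins <- numeric(n_bins)
    b <- bouts[bouts$animal_id == id, ]
    if (nrow(b)) {
      frames <- unlist(mapply(seq, b$start_frame, b$end_frame - 1L,
                              SIMPLIFY = FALSE))
      tab <- table(floor(frames * dt / bin_width))
      mins[as.integer(names(tab)) + 1L] <- as.numeric(tab) * dt / 60
    }
    res <- tibble::tibble(animal_id = id, hour_bin = seq_len(n_bins) - 1L,
                          minutes = mins)
    if (!is.null(groups)) res$group <- groups[k]
    res
  })
  out <- dplyr::bind_rows(parts)
  if ("group" %in% names(out)) {
    out <- out[, c("animal_id", "group", "hour_bin", "minutes")]
  }
  out
}

#' Group-level quiescence summary
#'
#' Mean, SEM, median and n of per-animal (or per-trial-mean) hourly
#' quiescence, by group and hour bin. With a single animal in a cell the
#' SEM is reported as `NA`.
#'
#' @param hourly Output of [quiescence_by_hour()]; must contain a `group`
#'   column (join one on if absent).
#' @param mode `"animal"` summarizes animals directly; `"trial"` first
#'   averages animals within each trial (requires a `trial_id` column) and
#'   then summarizes trial means.
#' @return Tibble `group`, `hour_bin`, `mean`, `sem`, `n`, `median`. Empty
#'   groups are omitted with a warning.
#' @export
group_summary <- function(hourly, mode = c("animal", "trial")) {
  mode <- match.arg(mode)
  check_columns(hourly, c("group", "hour_bin", "minutes"), "hourly table")
  if (mode == "trial") {
    check_columns(hourly, "trial_id", "hourly table (mode = 'trial')")
    hourly <- hourly |>
      dplyr::group_by(.data$group, .data$trial_id, .data$hour_bin) |>
      dplyr::summarise(minutes = mean(.data$minutes), .groups = "drop")
  }
  empty <- setdiff(unique(as.character(hourly$group)),
                   unique(as.character(hourly$group[!is.na(hourly$minutes)])))
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  }
  hourly |>
    dplyr::filter(!is.na(.data$minutes)) |>
    dplyr::group_by(.data$group, .data$hour_bin) |>
    dplyr::summarise(
      mean = mean(.data$minutes),
      sem = if (dplyr::n() > 1) sd(.data$minutes) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      median = median(.data$minutes),
      .groups = "drop"
    )
}

#' Quiescence raster
#'
#' Binary animal-by-frame matrix: 1 where the frame belongs to a called
#' quiescent bout, 0 otherwise. Row order follows the order of first
#' appearance in the input. Also builds the conventional raster plot
#' (quiescence in blue on a yellow activity background).
#'
#' @param series Displacement data frame (see [detect_bouts()]); all
#'   animals must share one frame interval.
#' @param ... Passed to [detect_bouts()] (e.g. `zero_threshold`, `min_run`).
#' @return List of class `quiescence_raster`: `matrix` (rows = animals),
#'   `bouts` (the `bout_set`), `plot` (a ggplot, `NULL` for empty input).
#' @export
quiescence_raster <- function(series, ...) {
  if (nrow(series) == 0L) {
    return(structure(list(matrix = matrix(0, 0, 0), bouts = NULL,
                          plot = NULL),
                     class = "quiescence_raster"))
  }
  check_columns(series, c("animal_id", "frame_index", "displacement"),
                "displacement table")
  n_per <- tapply(series$frame_index, series$animal_id, length)
  if (length(unique(n_per)) != 1L) {
    stop_wormsleep("all animals must have the same number of frames")
  }
  bouts <- detect_bouts(series, ...)
  ids <- unique(series$animal_id)
  n_frames <- as.integer(n_per[[1]])
  mat <- matrix(0L, nrow = length(ids), ncol = n_frames,
                dimnames = list(ids, NULL))
  for (i in seq_len(nrow(bouts))) {
    mat[bouts$animal_id[i],
        (bouts$start_frame[i] + 1L):bouts$end_frame[i]] <- 1L
  }
  df <- tibble::tibble(
    animal = factor(rep(ids, each = n_frames), levels = rev(ids)),
    frame = rep(seq_len(n_frames) - 1L, times = length(ids)),
    quiescent = as.vector(t(mat))
  )
  dt <- attr(bouts, "dt")
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame * dt / 60,
                                          y = .data$animal,
                                          fill = factor(.data$quiescent))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "#F6D55C", `1` = "#20639B"),
                               labels = c("active", "quiescent"),
                               name = NULL) +
    ggplot2::labs(x = "minutes after training", y = NULL) +
    ggplot2::theme_minimal()
  structure(list(matrix = mat, bouts = bouts, plot = plt),
            class = "quiescence_raster")
}

#' @export
print.quiescence_raster <- function(x, ...) {
  cat(sprintf("<quiescence_raster> %d animals x %d frames, %.1f%% quiescent\n",
              nrow(x$matrix), ncol(x$matrix),
              if (length(x$matrix)) 100 * mean(x$matrix) else 0))
  invisible(x)
}

#' Pharyngeal pumping and feeding-quiescence metrics
#'
#' Pumps are counted over 15 s and multiplied by 4 to give pumps/min per
#' animal; the paused fraction is the proportion of animals observed to
#' stop pumping for at least 4 s during one minute of observation, with the
#' standard error of a proportion `sqrt(p * (1 - p) / n)`.
#'
#' @param records Data frame with columns `animal_id`, `group`, `pumps_15s`
#'   (nonnegative integer), `paused_ge4s` (logical).
#' @return Tibble per group: `pumps_per_min_mean`, `pumps_per_min_sem`,
#'   `paused_fraction`, `paused_se`, `n`.
#' @export
feeding_metrics <- function(records) {
  check_columns(records, c("animal_id", "group", "pumps_15s", "paused_ge4s"),
                "feeding table")
  if (nrow(records) == 0L) stop_wormsleep("no feeding records")
  if (any(records$pumps_15s < 0)) stop_wormsleep("pumps_15s must be >= 0")
  records |>
    dplyr::mutate(pumps_per_min = .data$pumps_15s * 4) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      pumps_per_min_mean = mean(.data$pumps_per_min),
      pumps_per_min_sem = if (dplyr::n() > 1) {
        sd(.data$pumps_per_min) / sqrt(dplyr::n())
      } else NA_real_,
      paused_fraction = mean(.data$paused_ge4s),
      paused_se = sqrt(mean(.data$paused_ge4s) *
                         (1 - mean(.data$paused_ge4s)) / dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
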