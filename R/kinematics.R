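# Posture and locomotion metrics from 17-point midline skeletons.
# Tidy skeleton tables have columns animal_id, frame_index, point_index
# (1-17, head = 1, midpoint = 9, tail = 17), x, y.

validate_skeleton <- function(skel) {
  check_columns(skel, c("frame_index", "point_index", "x", "y"),
                "skeleton table")
  counts <- table(skel$frame_index)
  if (any(counts != 17L)) {
    stop_wormsleep("every frame must have exactly 17 skeleton points")
  }
  invisible(skel)
}

# Interior angles (degrees) of triangles a-b-c, vectorized over rows of
# n x 2 matrices. Returns angles at a, at c, and the direct angle at b.
triangle_angles <- function(a, b, c) {
  ang <- function(v1, v2) {
    dot <- rowSums(v1 * v2)
    nn <- sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2))
    acos(pmin(pmax(dot / nn, -1), 1)) * 180 / pi
  }
  list(
    at_a = ang(b - a, c - a),
    at_c = ang(a - c, b - c),
    at_b = ang(a - b, c - b)
  )
}

#' Midpoint bending angle of a skeleton
#'
#' Treats the head (point 1), midpoint (point 9) and tail (point 17) as a
#' triangle and computes the midpoint bending angle as
#' `theta_m = 180 - (theta1 + theta2)`, where `theta1` and `theta2` are the
#' triangle's interior angles at the head and tail. By the angle-sum
#' identity this equals the interior angle at point 9: a straight animal
#' scores 180 degrees and tighter bends score lower. All angles are in
#' degrees; the measure is invariant under translation, rotation, uniform
#' scaling and reflection of the coordinates.
#'
#' @param skel Tidy skeleton table (one or more frames); see
#'   [simulate_skeleton()] for the layout.
#' @return Tibble with one row per (animal, frame): `animal_id`,
#'   `frame_index`, `theta1`, `theta2`, `theta_m`.
#' @export
#' @examples
#' bending_angle(simulate_skeleton("straight"))$theta_m   # 180
bending_angle <- function(skel) {
  validate_skeleton(skel)
  if (!"animal_id" %in% names(skel)) skel$animal_id <- "animal"
  key <- skel[skel$point_index %in% c(1L, 9L, 17L), ]
  key <- key[order(key$animal_id, key$frame_index, key$point_index), ]
  n <- nrow(key) / 3L
  idx <- function(k) seq(k, by = 3L, length.out = n)
  p1 <- cbind(key$x[idx(1L)], key$y[idx(1L)])
  p9 <- cbind(key$x[idx(2L)], key$y[idx(2L)])
  p17 <- cbind(key$x[idx(3L)], key$y[idx(3L)])

  d <- cbind(rowSums((p1 - p9)^2), rowSums((p9 - p17)^2),
             rowSums((p1 - p17)^2))
  if (any(d[, 1:2] == 0)) {
    bad <- which(d[, 1] == 0 | d[, 2] == 0)[1]
    stop_wormsleep(sprintf(
      "degenerate geometry in frame %d: point 9 coincides with point %s",
      key$frame_index[idx(2L)][bad], if (d[bad, 1] == 0) "1" else "17"))
  }
  collinear <- d[, 3] == 0   # head on tail: p1-p9-p17 folded; angles at
  # p1/p17 are undefined, but a fold means theta_m is the angle at p9.
  angs <- triangle_angles(p1, p9, p17)
  theta1 <- ifelse(collinear, NA_real_, angs$at_a)
  theta2 <- ifelse(collinear, NA_real_, angs$at_c)
  theta_m <- ifelse(collinear, angs$at_b, 180 - (theta1 + theta2))
  tibble::tibble(
    animal_id = key$animal_id[idx(1L)],
    frame_index = key$frame_index[idx(1L)],
    theta1 = theta1, theta2 = theta2, theta_m = theta_m
  )
}

#' Track metrics from a skeleton sequence
#'
#' Uses the 9th skeleton point as the center of the worm. Per-step speed is
#' the midpoint displacement divided by `dt`; track length is the summed
#' midpoint path; the moving-average speed smooths the speed series over
#' `ma_window` steps (window start-aligned). Each step is also projected on
#' the local body axis (tail-to-head chord, so positive = toward the head)
#' and split into forward and backward components of peristaltic movement.
#'
#' @param skel Tidy skeleton table for one animal, >= 2 frames.
#' @param dt Seconds per frame (> 0).
#' @param ma_window Moving-average window in steps (default 10, i.e. 30 s
#'   at 3 s/frame).
#' @return List of class `track_summary`: `per_step` tibble (`frame_index`
#'   of the step start, `speed`, `ma_speed`, `axial_disp`), `track_length`,
#'   `net_displacement`, `forward_dist`, `backward_dist`, `dt`.
#' @export
track_metrics <- function(skel, dt = 3, ma_window = 10L) {
  validate_skeleton(skel)
  check_number(dt, "dt", lower = 1e-12)
  frames <- sort(unique(skel$frame_index))
  if (length(frames) < 2L) stop_wormsleep("need at least 2 frames")
  get_pt <- function(i) {
    sub <- skel[skel$point_index == i, ]
    sub <- sub[order(sub$frame_index), ]
    cbind(sub$x, sub$y)
  }
  p9 <- get_pt(9L)
  p1 <- get_pt(1L)
  p17 <- get_pt(17L)
  step <- diff(p9)
  step_len <- sqrt(rowSums(step^2))
  speed <- step_len / dt
  # body axis at the step's starting frame, tail -> head
  axis <- p1 - p17
  axis <- axis[-nrow(axis), , drop = FALSE]
  axis <- axis / sqrt(rowSums(axis^2))
  axial <- rowSums(step * axis)
  nstep <- length(speed)
  w <- min(as.integer(ma_window), nstep)
  cs <- c(0, cumsum(speed))
  ma <- c((cs[(w + 1):(nstep + 1)] - cs[1:(nstep - w + 1)]) / w,
          rep(NA_real_, w - 1L))
  structure(list(
    per_step = tibble::tibble(frame_index = frames[-length(frames)],
                              speed = speed, ma_speed = ma,
                              axial_disp = axial),
    track_length = sum(step_len),
    net_displacement = sqrt(sum((p9[nrow(p9), ] - p9[1, ])^2)),
    forward_dist = sum(pmax(axial, 0)),
    backward_dist = -sum(pmin(axial, 0)),
    dt = dt
  ), class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  cat(sprintf(
    "<track_summary> %d steps | track %.3g | net %.3g | mean speed %.3g/s\n",
    nrow(x$per_step), x$track_length, x$net_displacement,
    mean(x$per_step$speed)))
  invisible(x)
}

#' Stillest window of a speed series
#'
#' Finds the first window of `window` consecutive frames minimizing the
#' mean of the (moving-average) speed series -- the period used to capture
#' and overlay sleep posture. Ties are broken by the earliest start.
#'
#' @param ma_speed Numeric speed series (NAs, e.g. the moving-average tail,
#'   are excluded from candidate windows).
#' @param window Window length in frames (default 10).
#' @return Named integer vector `c(start, end)`, 1-based inclusive indices
#'   into `ma_speed`.
#' @export
stillest_window <- function(ma_speed, window = 10L) {
  window <- as.integer(window)
  check_number(window, "window", lower = 1)
  # trailing NAs (the start-aligned moving-average tail) are not candidates
  last <- if (any(!is.na(ma_speed))) max(which(!is.na(ma_speed))) else 0L
  x <- ma_speed[seq_len(last)]
  if (length(x) < window) stop_wormsleep("series shorter than the window")
  if (anyNA(x)) stop_wormsleep("internal NA in speed series")
  cs <- c(0, cumsum(x))
  means <- (cs[(window + 1):(length(x) + 1)] -
              cs[1:(length(x) - window + 1)]) / window
  start <- which.min(means)          # which.min returns the first minimum
  c(start = start, end = start + window - 1L)
}

#' Align skeletons to their midpoints
#'
#' Translates each frame's skeleton so that point 9 sits at the origin; no
#' rotation or scaling is applied, so overlaying the aligned frames shows
#' posture variation around the body center. An isometry per frame:
#' inter-point distances are unchanged.
#'
#' @param skel Tidy skeleton table (one or more frames).
#' @return The same table with `x`, `y` re-centered per frame.
#' @export
align_overlay <- function(skel) {
  validate_skeleton(skel)
  if (!"animal_id" %in% names(skel)) skel$animal_id <- "animal"
  skel |>
    dplyr::group_by(.data$animal_id, .data$frame_index) |>
    dplyr::mutate(x = .data$x - .data$x[.data$point_index == 9L],
                  y = .data$y - .data$y[.data$point_index == 9L]) |>
    dplyr::ungroup()
}
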