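# Independent oracles and fixture builders used across the suite.

# Brute-force maximal-run scan: walk the series frame by frame, close a run
# when stillness ends, keep runs >= min_run. Independent of the rle-based
# implementation in the package.
brute_force_bouts <- function(values, zero_threshold = 0, min_run = 9L) {
  still <- !is.na(values) & values <= zero_threshold
  starts <- integer(0)
  ends <- integer(0)
  run_start <- NA_integer_
  for (i in seq_along(still)) {
    if (still[i] && is.na(run_start)) run_start <- i
    if (!still[i] && !is.na(run_start)) {
      if (i - run_start >= min_run) {
        starts <- c(starts, run_start - 1L)
        ends <- c(ends, i - 1L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && length(still) - run_start + 1L >= min_run) {
    starts <- c(starts, run_start - 1L)
    ends <- c(ends, length(still))
  }
  data.frame(start_frame = starts, end_frame = ends)
}

# Exhaustive stillest-window search.
brute_force_window <- function(x, window) {
  means <- vapply(seq_len(length(x) - window + 1L), function(s) {
    mean(x[s:(s + window - 1L)])
  }, numeric(1))
  s <- which(means == min(means))[1]
  c(start = s, end = s + window - 1L)
}

# A random non-degenerate triangle as a 17-point skeleton table: points
# 1, 9, 17 at the triangle vertices, the rest interpolated along the legs
# (interior points only need to be non-coincident).
random_triangle_skeleton <- function() {
  repeat {
    v <- matrix(stats::rnorm(6, sd = 5), 3, 2)
    a <- sqrt(sum((v[1, ] - v[2, ])^2))
    b <- sqrt(sum((v[2, ] - v[3, ])^2))
    cross <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1])
    if (a > 0.1 && b > 0.1 && abs(cross) > 0.05) break
  }
  leg1 <- cbind(seq(v[1, 1], v[2, 1], length.out = 9),
                seq(v[1, 2], v[2, 2], length.out = 9))
  leg2 <- cbind(seq(v[2, 1], v[3, 1], length.out = 9),
                seq(v[2, 2], v[3, 2], length.out = 9))
  pts <- rbind(leg1, leg2[-1, ])
  tibble::tibble(animal_id = "t", frame_index = 0L, point_index = 1:17,
                 x = pts[, 1], y = pts[, 2])
}

# Interior angle at b of triangle (a, b, c), degrees, computed directly.
direct_angle_at <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

expect_bouts_equal <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
}
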