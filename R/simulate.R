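# Synthetic-data generators: seeded, reproducible inputs with the
# statistical structure the downstream analyses assume.

#' Simulate displacement series from a two-state Markov chain
#'
#' Each animal alternates between an active state, which emits a positive
#' half-normal inter-frame pixel displacement, and a quiescent state, which
#' emits exactly 0. Transitions follow per-frame probabilities
#' (`enter` = active to quiescent, `exit` = quiescent to active) that may
#' vary by hour bin. Animals start active (they are moving when loaded into
#' wells immediately after training).
#'
#' @param config A [sim_config()].
#' @param group Group label; must be a name of `config$groups`.
#' @return A tibble with columns `animal_id`, `group`, `frame_index`
#'   (0-based), `displacement`, plus attributes `dt` (seconds/frame) and
#'   `t0` (seconds since end of training, 0).
#' @export
#' @examples
#' d <- simulate_displacement(sim_config(seed = 1, n_animals = 2), "butanone")
#' head(d)
simulate_displacement <- function(config, group) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% names(config$groups)) {
    stop_wormsleep(sprintf("unknown group label '%s' (have: %s)", group,
                           paste(names(config$groups), collapse = ", ")))
  }
  dt <- config$frame_interval
  n_frames <- as.integer(round(config$duration_h * 3600 / dt))
  pars <- config$groups[[group]]
  n_hours <- max(1L, ceiling(config$duration_h))
  enter <- rep_len(pars$enter, n_hours)
  exit <- rep_len(pars$exit, n_hours)
  hour_of <- pmin(floor((seq_len(n_frames) - 1) * dt / 3600), n_hours - 1) + 1

  out <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    out[[a]] <- with_substream(config$seed, c("displacement", group, a), {
      u <- runif(n_frames)
      state <- logical(n_frames)    # TRUE = quiescent
      prev <- FALSE
      for (i in seq_len(n_frames)) {
        h <- hour_of[i]
        state[i] <- if (prev) u[i] >= exit[h] else u[i] < enter[h]
        prev <- state[i]
      }
      disp <- abs(rnorm(n_frames, 0, config$active_scale))
      disp[state] <- 0
      tibble::tibble(
        animal_id = sprintf("%s_%03d", group, a),
        group = group,
        frame_index = seq_len(n_frames) - 1L,
        displacement = disp
      )
    })
  }
  res <- dplyr::bind_rows(out)
  attr(res, "dt") <- dt
  attr(res, "t0") <- 0
  res
}

#' Simulate one chemotaxis plate count
#'
#' Draws `n_worms` placements from a single multinomial over the four plate
#' regions (odor arena, diluent arena, origin, elsewhere) configured for
#' `condition`.
#'
#' @param config A [sim_config()].
#' @param condition Condition label; must be a name of `config$plate_probs`.
#' @param n_worms Number of worms on the plate (>= 1).
#' @param trial_id Trial identifier recorded in the output.
#' @param timepoint_h Assay timepoint (hours post-training) recorded in the
#'   output.
#' @return One-row tibble with columns `trial_id`, `condition`,
#'   `timepoint_h`, `n_odor`, `n_diluent`, `n_origin`, `n_total`.
#' @export
simulate_plate_counts <- function(config, condition, n_worms,
                                  trial_id = "t1", timepoint_h = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% names(config$plate_probs)) {
    stop_wormsleep(sprintf("no plate probabilities for condition '%s'",
                           condition))
  }
  check_number(n_worms, "n_worms", lower = 1)
  p <- config$plate_probs[[condition]]
  counts <- with_substream(config$seed,
                           c("plate", condition, trial_id, timepoint_h),
                           as.vector(rmultinom(1, n_worms, p)))
  tibble::tibble(
    trial_id = trial_id, condition = condition, timepoint_h = timepoint_h,
    n_odor = counts[1], n_diluent = counts[2], n_origin = counts[3],
    n_total = as.integer(n_worms)
  )
}

#' Simulate a synaptic-intensity time course
#'
#' Per-animal punctal intensities whose square roots follow a continuous
#' piecewise-linear mean with a knot: for an animal sampled at `t` hours
#' post-training, `sqrt(intensity) = a + b1 * min(t, knot) +
#' b2 * max(0, t - knot) + N(0, sigma)`. Negative intensities cannot occur
#' physically, so sqrt-scale draws below zero are truncated at intensity 0
#' and counted in the `n_truncated` attribute.
#'
#' @param config A [sim_config()].
#' @param condition Condition label; must be a name of
#'   `config$synapse_params`.
#' @param sleep_status Sleep status recorded in the output records.
#' @return A tibble of synapse records (`worm_id`, `marker`, `condition`,
#'   `sleep_status`, `timepoint_h`, `assay_day`, `raw_intensity`) with
#'   attribute `n_truncated`. Animals are spread round-robin over four
#'   assay days so day-wise normalization is exercised.
#' @export
simulate_synapse_timecourse <- function(config, condition,
                                        sleep_status = "slept") {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$synapse_params[[condition]]
  if (is.null(sp)) {
    stop_wormsleep(sprintf("no synapse parameters for condition '%s'",
                           condition))
  }
  if (sp$sigma <= 0) stop_wormsleep("sigma must be > 0")
  n_days <- 4L
  rows <- vector("list", length(config$timepoints_h))
  n_trunc <- 0L
  for (k in seq_along(config$timepoints_h)) {
    t <- config$timepoints_h[k]
    mu <- sp$a + sp$b1 * min(t, sp$knot_h) + sp$b2 * max(0, t - sp$knot_h)
    draws <- with_substream(config$seed, c("synapse", condition,
                                           sleep_status, t), {
      rnorm(config$n_per_timepoint, mu, sp$sigma)
    })
    n_trunc <- n_trunc + sum(draws < 0)
    draws <- pmax(draws, 0)
    n <- config$n_per_timepoint
    rows[[k]] <- tibble::tibble(
      worm_id = sprintf("%s_%s_t%g_%03d", condition, sleep_status, t,
                        seq_len(n)),
      marker = "AWC-AIY",
      condition = condition,
      sleep_status = sleep_status,
      timepoint_h = t,
      assay_day = sprintf("day%d", ((seq_len(n) - 1L) %% n_days) + 1L),
      raw_intensity = draws^2
    )
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "n_truncated") <- n_trunc
  res
}

#' Simulate correlated sleep--memory trial pairs
#'
#' Draws `(quiescence_min, li_16h)` pairs from a bivariate normal with
#' population correlation `config$rho` and the configured marginals, then
#' clips quiescence to \[0, 60\] minutes and LI to \[-2, 2\]. Clipping after
#' the correlation-inducing draw biases the sample correlation toward zero,
#' so the fraction of clipped values is recorded in the `clip_fraction`
#' attribute and a `clipped` attribute flags when it exceeds 1%.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `trial_id`, `quiescence_min`, `li_16h`;
#'   attributes `clip_fraction` and `clipped`.
#' @export
simulate_sleep_memory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_trials < 3) stop_wormsleep("n_trials must be >= 3")
  if (abs(config$rho) > 1) stop_wormsleep("|rho| must be <= 1")
  n <- config$n_trials
  rho <- config$rho
  draws <- with_substream(config$seed, "sleep_memory", {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    list(z1 = z1, z2 = z2)
  })
  q_raw <- config$sleep_mean + config$sleep_sd * draws$z1
  li_raw <- config$li_mean + config$li_sd * draws$z2
  q <- pmin(pmax(q_raw, 0), 60)
  li <- pmin(pmax(li_raw, -2), 2)
  clip_frac <- mean(q != q_raw | li != li_raw)
  res <- tibble::tibble(
    trial_id = sprintf("trial_%03d", seq_len(n)),
    quiescence_min = q,
    li_16h = li
  )
  attr(res, "clip_fraction") <- clip_frac
  attr(res, "clipped") <- clip_frac > 0.01
  res
}

#' Simulate 17-point worm skeletons
#'
#' Generates skeleton coordinate sequences of four stereotyped shapes, with
#' the 17 midline points spaced uniformly in arc length (to within 1%):
#'
#' * `straight` -- a straight midline.
#' * `sinusoid` -- a sinusoidal midline `y = amplitude * sin(2*pi*periods*
#'   s / length)` parameterized by arc length.
#' * `crook` -- the posterior 75% of the body straight and the anterior 25%
#'   (head end, points near 1) bent on a circular arc: the stereotyped
#'   sleep posture.
#' * `v_bend` -- two straight limbs meeting at point 9 with interior angle
#'   `angle_deg`.
#'
#' Frames after the first are rigid translations by `translate` per frame,
#' giving a known ground-truth track for the midpoint.
#'
#' @param shape One of `"straight"`, `"sinusoid"`, `"crook"`, `"v_bend"`.
#' @param params Named list: `length` (body length, default 1), `amplitude`
#'   and `periods` (sinusoid, defaults 0.15 and 1), `angle_deg` (v_bend,
#'   default 90), `crook_turn_deg` (total heading change over the curved
#'   anterior quarter, default 120), `n_frames` (default 1), `translate`
#'   (length-2 displacement per frame, default c(0, 0)),
#'   `animal_id` (default `"sim"`).
#' @return Tidy tibble `animal_id`, `frame_index` (0-based), `point_index`
#'   (1--17, head = 1, midpoint = 9, tail = 17), `x`, `y`.
#' @export
#' @examples
#' sk <- simulate_skeleton("v_bend", list(angle_deg = 90))
#' bending_angle(sk)
simulate_skeleton <- function(shape, params = list()) {
  shapes <- c("straight", "sinusoid", "crook", "v_bend")
  if (!shape %in% shapes) {
    stop_wormsleep(sprintf("unknown shape '%s' (have: %s)", shape,
                           paste(shapes, collapse = ", ")))
  }
  p <- utils::modifyList(
    list(length = 1, amplitude = 0.15, periods = 1, angle_deg = 90,
         crook_turn_deg = 120, n_frames = 1L, translate = c(0, 0),
         animal_id = "sim"),
    params
  )
  pts <- switch(
    shape,
    straight = cbind(seq(0, p$length, length.out = 17), rep(0, 17)),
    sinusoid = arc_length_resample(function(u) {
      x <- u * p$length
      cbind(x, p$amplitude * sin(2 * pi * p$periods * x / p$length))
    }),
    crook = skeleton_crook(p$length, p$crook_turn_deg),
    v_bend = skeleton_v_bend(p$length, p$angle_deg)
  )
  frames <- lapply(seq_len(p$n_frames) - 1L, function(f) {
    tibble::tibble(
      animal_id = p$animal_id,
      frame_index = f,
      point_index = 1:17,
      x = pts[, 1] + f * p$translate[1],
      y = pts[, 2] + f * p$translate[2]
    )
  })
  dplyr::bind_rows(frames)
}

# Resample a curve u in [0,1] -> (x, y) at 17 points uniform in arc length.
arc_length_resample <- function(curve, n_fine = 4096L) {
  fine <- curve(seq(0, 1, length.out = n_fine))
  seg <- sqrt(diff(fine[, 1])^2 + diff(fine[, 2])^2)
  s <- c(0, cumsum(seg))
  targets <- seq(0, s[length(s)], length.out = 17)
  x <- stats::approx(s, fine[, 1], xout = targets, ties = "ordered")$y
  y <- stats::approx(s, fine[, 2], xout = targets, ties = "ordered")$y
  cbind(x, y)
}

# Posterior 75% straight, anterior 25% on a circular arc. Points are laid
# tail (17) to head (1): straight run along +x, then an arc turning through
# `turn_deg` degrees. Built on a fine arc-length grid, so spacing is uniform.
skeleton_crook <- function(len, turn_deg) {
  curve <- function(u) {
    s <- u * len                      # arc length from the tail
    s_straight <- 0.75 * len
    r <- 0.25 * len / (turn_deg * pi / 180)   # arc radius
    x <- ifelse(s <= s_straight, s,
                s_straight + r * sin((s - s_straight) / r))
    y <- ifelse(s <= s_straight, 0, r * (1 - cos((s - s_straight) / r)))
    cbind(x, y)
  }
  pts <- arc_length_resample(curve)
  pts[17:1, , drop = FALSE]           # reorder so point 1 is the head
}

# Two straight 8-interval limbs joined at point 9 with the given interior
# angle; uniform spacing is exact by construction.
skeleton_v_bend <- function(len, angle_deg) {
  half <- len / 2
  ang <- angle_deg * pi / 180
  u1 <- c(cos(ang / 2), sin(ang / 2))      # toward the head
  u2 <- c(cos(ang / 2), -sin(ang / 2))     # toward the tail
  d <- seq(half, 0, length.out = 9)
  head_pts <- cbind(d * u1[1], d * u1[2])
  tail_pts <- cbind(d * u2[1], d * u2[2])[8:0 + 1, , drop = FALSE]
  rbind(head_pts, tail_pts[-1, , drop = FALSE])
}
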