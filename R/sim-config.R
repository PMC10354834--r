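#' Simulation configuration
#'
#' Builds and validates the configuration object used by all `simulate_*()`
#' generators. The defaults describe the study conditions the analyses
#' assume: movement sampled at 1 frame per 3 s, hour-scale recordings,
#' training groups whose two-state (active/quiescent) Markov rates give
#' roughly 15 / 5 / 1 min of quiescence per hour for butanone-trained,
#' buffer-trained and naive animals, chemotaxis plates scored as multinomial
#' draws over (odor arena, diluent arena, origin, elsewhere), a
#' square-root-scale piecewise-linear synaptic intensity mean with its knot
#' at 2 h post-training, and 47 sleep--memory trial pairs with population
#' correlation 0.61.
#'
#' @param seed Integer root seed. Every generator derives independent
#'   sub-streams from it (keyed by stage name and animal/trial index), so
#'   adding animals never perturbs already-generated series.
#' @param frame_interval Seconds between frames (default 3).
#' @param duration_h Recording duration in hours.
#' @param n_animals Animals per group.
#' @param groups Named list; each element a list with `enter` and `exit`,
#'   the per-frame probabilities of entering/leaving quiescence. Scalars
#'   apply to every hour; a vector gives one value per hour bin.
#' @param active_scale Scale of the half-normal displacement emitted on
#'   active frames (pixels/frame). Any positive emission law would do for
#'   bout calling, which only distinguishes zero from nonzero; the
#'   half-normal is a convenient concrete choice.
#' @param plate_probs Named list of length-4 probability vectors
#'   `(odor, diluent, origin, elsewhere)` per condition; each must sum to 1.
#' @param synapse_params Named list per condition with elements `a`
#'   (sqrt-intensity intercept at t = 0), `b1` (slope 0 to knot, sqrt
#'   units/h), `b2` (slope after the knot), `knot_h` (default 2) and
#'   `sigma` (> 0, residual SD on the sqrt scale).
#' @param timepoints_h Sampling times (hours post-training) for the synapse
#'   generator.
#' @param n_per_timepoint Animals per condition per timepoint.
#' @param rho Target population correlation between per-trial quiescence and
#'   16-h learning index.
#' @param n_trials Number of sleep--memory trial pairs.
#' @param sleep_mean,sleep_sd,li_mean,li_sd Marginal means/SDs of the
#'   sleep--memory pairs (minutes of hour-1 quiescence; learning-index
#'   units) before clipping to their plausible ranges.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$groups$butanone
sim_config <- function(seed = 1L,
                       frame_interval = 3,
                       duration_h = 1,
                       n_animals = 20L,
                       groups = list(
                         naive    = list(enter = 0.002, exit = 0.10),
                         buffer   = list(enter = 0.010, exit = 0.08),
                         butanone = list(enter = 0.030, exit = 0.07)
                       ),
                       active_scale = 4,
                       plate_probs = list(
                         buffer   = c(odor = 0.80, diluent = 0.05,
                                      origin = 0.10, elsewhere = 0.05),
                         butanone = c(odor = 0.35, diluent = 0.30,
                                      origin = 0.10, elsewhere = 0.25)
                       ),
                       synapse_params = list(
                         buffer   = list(a = 10, b1 = -2.0, b2 = -0.10,
                                         knot_h = 2, sigma = 0.5),
                         butanone = list(a = 10, b1 = -2.0, b2 = -0.17,
                                         knot_h = 2, sigma = 0.5)
                       ),
                       timepoints_h = c(0, 2, 16),
                       n_per_timepoint = 80L,
                       rho = 0.61,
                       n_trials = 47L,
                       sleep_mean = 15, sleep_sd = 5,
                       li_mean = 0.8, li_sd = 0.25) {
  check_number(seed, "seed")
  check_number(frame_interval, "frame_interval", lower = 1e-9)
  check_number(duration_h, "duration_h", lower = 1e-9)
  check_number(n_animals, "n_animals", lower = 1)
  check_number(active_scale, "active_scale", lower = 1e-12)
  check_number(rho, "rho", lower = -1, upper = 1)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(sleep_sd, "sleep_sd", lower = 0)
  check_number(li_sd, "li_sd", lower = 0)

  for (g in names(groups)) {
    for (field in c("enter", "exit")) {
      p <- groups[[g]][[field]]
      if (is.null(p) || !is.numeric(p) || any(is.na(p)) ||
          any(p < 0) || any(p > 1)) {
        stop_wormsleep(sprintf(
          "group '%s': `%s` must be probabilities in [0, 1]", g, field))
      }
    }
  }
  for (cond in names(plate_probs)) {
    p <- plate_probs[[cond]]
    if (length(p) != 4L || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-12) {
      stop_wormsleep(sprintf(
        "plate_probs['%s'] must be 4 probabilities summing to 1", cond))
    }
  }
  for (cond in names(synapse_params)) {
    sp <- synapse_params[[cond]]
    for (field in c("a", "b1", "b2", "knot_h", "sigma")) {
      if (is.null(sp[[field]])) {
        stop_wormsleep(sprintf(
          "synapse_params['%s'] is missing `%s`", cond, field))
      }
    }
    if (sp$sigma <= 0) {
      stop_wormsleep(sprintf("synapse_params['%s']: sigma must be > 0", cond))
    }
    if (sp$knot_h <= 0) {
      stop_wormsleep(sprintf("synapse_params['%s']: knot_h must be > 0", cond))
    }
  }

  structure(
    list(seed = as.integer(seed), frame_interval = frame_interval,
         duration_h = duration_h, n_animals = as.integer(n_animals),
         groups = groups, active_scale = active_scale,
         plate_probs = plate_probs, synapse_params = synapse_params,
         timepoints_h = timepoints_h,
         n_per_timepoint = as.integer(n_per_timepoint),
         rho = rho, n_trials = as.integer(n_trials),
         sleep_mean = sleep_mean, sleep_sd = sleep_sd,
         li_mean = li_mean, li_sd = li_sd),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed: %d | %g s/frame | %g h | %d animals/group\n",
              x$seed, x$frame_interval, x$duration_h, x$n_animals))
  cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  cat("  plate conditions:", paste(names(x$plate_probs), collapse = ", "), "\n")
  cat(sprintf("  sleep-memory: %d trials, rho = %g\n", x$n_trials, x$rho))
  invisible(x)
}
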