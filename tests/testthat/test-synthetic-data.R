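# The generators: determinism, configured statistical structure, and the
# documented edge behaviors.

test_that("identical seeds give identical outputs and seeds are per-stream", {
  cfg <- sim_config(seed = 42, n_animals = 3, duration_h = 0.1)
  expect_identical(simulate_displacement(cfg, "buffer"),
                   simulate_displacement(cfg, "buffer"))
  expect_identical(simulate_sleep_memory(cfg), simulate_sleep_memory(cfg))
  expect_identical(simulate_plate_counts(cfg, "buffer", 100),
                   simulate_plate_counts(cfg, "buffer", 100))
  # adding animals must not perturb existing series
  cfg5 <- sim_config(seed = 42, n_animals = 5, duration_h = 0.1)
  d3 <- simulate_displacement(cfg, "buffer")
  d5 <- simulate_displacement(cfg5, "buffer")
  expect_identical(d3$displacement,
                   d5$displacement[d5$animal_id %in% unique(d3$animal_id)])
  # different groups draw from different streams
  expect_false(identical(simulate_displacement(cfg, "buffer")$displacement,
                         simulate_displacement(cfg, "naive")$displacement))
})

test_that("displacement generator honors absorbing-state limits", {
  cfg <- sim_config(seed = 1, n_animals = 2, duration_h = 0.1,
                    groups = list(never = list(enter = 0, exit = 0.5),
                                  stuck = list(enter = 1, exit = 0)))
  d <- simulate_displacement(cfg, "never")
  expect_true(all(d$displacement > 0))
  d2 <- simulate_displacement(cfg, "stuck")   # enters at frame 1, never exits
  expect_true(all(d2$displacement[d2$frame_index >= 1] == 0))
  expect_error(simulate_displacement(cfg, "nope"), "nope")
})

test_that("symmetric two-state chain spends half its time quiescent", {
  cfg <- sim_config(seed = 7, n_animals = 200, duration_h = 1,
                    groups = list(sym = list(enter = 0.1, exit = 0.1)))
  d <- simulate_displacement(cfg, "sym")
  frac <- mean(d$displacement == 0)
  # stationary occupancy 0.5; 3 SE with conservative iid binomial SE on
  # the animal-level means (chain mixing makes the true SE smaller)
  se <- stats::sd(tapply(d$displacement == 0, d$animal_id, mean)) / sqrt(200)
  expect_lt(abs(frac - 0.5), 3 * max(se, 0.005))
})

test_that("empirical transition frequencies match configured probabilities", {
  cfg <- sim_config(seed = 11, n_animals = 10, duration_h = 4,
                    groups = list(g = list(enter = 0.07, exit = 0.21)))
  d <- simulate_displacement(cfg, "g")
  q <- d$displacement == 0
  by_animal <- split(q, d$animal_id)
  from_active <- 0; enter_n <- 0; from_quiet <- 0; exit_n <- 0
  for (v in by_animal) {
    prev <- v[-length(v)]; cur <- v[-1]
    from_active <- from_active + sum(!prev)
    enter_n <- enter_n + sum(!prev & cur)
    from_quiet <- from_quiet + sum(prev)
    exit_n <- exit_n + sum(prev & !cur)
  }
  expect_gt(from_active + from_quiet, 1e4)
  se_enter <- sqrt(0.07 * 0.93 / from_active)
  se_exit <- sqrt(0.21 * 0.79 / from_quiet)
  expect_lt(abs(enter_n / from_active - 0.07), 3 * se_enter)
  expect_lt(abs(exit_n / from_quiet - 0.21), 3 * se_exit)
})

test_that("plate-count generator reproduces the closed-form expected CI", {
  cfg <- sim_config(seed = 3, plate_probs = list(
    pure = c(1, 0, 0, 0),
    sym = c(0.3, 0.3, 0.2, 0.2),
    skew = c(0.6, 0.1, 0.2, 0.1)))
  p <- simulate_plate_counts(cfg, "pure", 50)
  expect_equal(chemotaxis_index(p$n_odor, p$n_diluent, p$n_origin,
                                p$n_total), 1)
  # per-category counts within 3 binomial SE of n * p
  big <- simulate_plate_counts(cfg, "skew", 1e4)
  expect_lt(abs(big$n_odor - 6000), 3 * sqrt(1e4 * 0.6 * 0.4))
  expect_lt(abs(big$n_diluent - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  expect_lt(abs(big$n_origin - 2000), 3 * sqrt(1e4 * 0.2 * 0.8))
  ci <- chemotaxis_index(big$n_odor, big$n_diluent, big$n_origin,
                         big$n_total)
  expect_lt(abs(ci - 0.625), 0.02)   # (0.6 - 0.1) / (1 - 0.2)
  # symmetric arenas: mean CI over many plates within 3 SE of 0
  cis <- vapply(1:1000, function(i) {
    x <- simulate_plate_counts(cfg, "sym", 60, trial_id = paste0("t", i))
    chemotaxis_index(x$n_odor, x$n_diluent, x$n_origin, x$n_total)
  }, numeric(1))
  expect_lt(abs(mean(cis)), 3 * stats::sd(cis) / sqrt(1000))
  expect_error(simulate_plate_counts(cfg, "unknown", 10), "unknown")
})

test_that("synapse generator follows the hinge mean and truncates at zero", {
  cfg <- sim_config(seed = 2, timepoints_h = c(0, 2, 16),
                    synapse_params = list(
                      g = list(a = 10, b1 = -2, b2 = -0.1, knot_h = 2,
                               sigma = 1e-9)))
  syn <- simulate_synapse_timecourse(cfg, "g")
  m <- tapply(syn$raw_intensity, syn$timepoint_h, mean)
  expect_equal(unname(m[["0"]]), 100, tolerance = 1e-6)     # a^2
  expect_equal(unname(m[["2"]]), 36, tolerance = 1e-6)      # (10 - 4)^2
  expect_equal(unname(m[["16"]]), 4.6^2, tolerance = 1e-6)  # 10 - 4 - 1.4
  # b1 = b2: sqrt(intensity) exactly linear in t
  cfg_lin <- sim_config(seed = 2, timepoints_h = c(0, 1, 2, 8, 16),
                        synapse_params = list(
                          g = list(a = 9, b1 = -0.4, b2 = -0.4, knot_h = 2,
                                   sigma = 1e-12)))
  lin <- simulate_synapse_timecourse(cfg_lin, "g")
  expect_equal(sqrt(lin$raw_intensity), 9 - 0.4 * lin$timepoint_h,
               tolerance = 1e-6)
  # deep-negative means get truncated and counted
  cfg_neg <- sim_config(seed = 2, timepoints_h = c(0, 16),
                        synapse_params = list(
                          g = list(a = 1, b1 = -2, b2 = -0.5, knot_h = 2,
                                   sigma = 0.5)))
  neg <- simulate_synapse_timecourse(cfg_neg, "g")
  expect_true(all(neg$raw_intensity >= 0))
  expect_gt(attr(neg, "n_truncated"), 0)
  expect_error(sim_config(synapse_params = list(g = list(
    a = 1, b1 = 0, b2 = 0, knot_h = 2, sigma = 0))), "sigma")
})

test_that("hinge regression on generator output recovers the parameters", {
  cfg <- sim_config(seed = 31, timepoints_h = c(0, 1, 2, 8, 16),
                    n_per_timepoint = 40,
                    synapse_params = list(
                      g = list(a = 10, b1 = -2, b2 = -0.1, knot_h = 2,
                               sigma = 0.5)))
  syn <- simulate_synapse_timecourse(cfg, "g")
  fit <- fit_piecewise_sqrt(syn, value = "raw_intensity")
  sm <- suppressWarnings(summary(fit$model))$coefficients
  expect_lt(abs(fit$a - 10), 3 * sm["(Intercept)", 2])
  expect_lt(abs(fit$b_early + 2), 3 * sm["t", 2])
  expect_lt(abs(fit$delta - 1.9), 3 * sm["hinge", 2])
})

test_that("sleep-memory pairs hit the target correlation and clip ranges", {
  cfg1 <- sim_config(seed = 5, rho = 1, n_trials = 100,
                     sleep_mean = 30, sleep_sd = 2, li_mean = 0.5,
                     li_sd = 0.1)   # no clipping active at these marginals
  p1 <- simulate_sleep_memory(cfg1)
  expect_equal(stats::cor(p1$quiescence_min, p1$li_16h), 1,
               tolerance = 1e-9)
  expect_false(attr(p1, "clipped"))

  cfg0 <- sim_config(seed = 5, rho = 0, n_trials = 5000,
                     sleep_mean = 30, sleep_sd = 2, li_mean = 0.5,
                     li_sd = 0.1)
  p0 <- simulate_sleep_memory(cfg0)
  expect_lt(abs(stats::cor(p0$quiescence_min, p0$li_16h)), 3 / sqrt(5000))

  cfg61 <- sim_config(seed = 5, rho = 0.61, n_trials = 2000)
  p61 <- simulate_sleep_memory(cfg61)
  expect_lt(abs(stats::cor(p61$quiescence_min, p61$li_16h) - 0.61), 0.05)
  expect_true(all(p61$quiescence_min >= 0 & p61$quiescence_min <= 60))
  expect_true(all(p61$li_16h >= -2 & p61$li_16h <= 2))

  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(simulate_sleep_memory(sim_config(n_trials = 2)), "n_trials")
})

test_that("skeleton shapes have the constructed geometry", {
  expect_equal(bending_angle(simulate_skeleton("straight"))$theta_m, 180)
  v <- simulate_skeleton("v_bend", list(angle_deg = 90))
  expect_equal(bending_angle(v)$theta_m, 90, tolerance = 1e-6)
  v2 <- simulate_skeleton("v_bend", list(angle_deg = 137.5))
  expect_equal(bending_angle(v2)$theta_m, 137.5, tolerance = 1e-6)

  # arc-length-uniform spacing within 1% for every shape
  for (shape in c("straight", "sinusoid", "crook", "v_bend")) {
    sk <- simulate_skeleton(shape)
    seg <- sqrt(diff(sk$x)^2 + diff(sk$y)^2)
    expect_true(all(abs(seg / mean(seg) - 1) < 0.01), info = shape)
  }

  # crook: posterior three quarters straight, anterior quarter curved
  cr <- simulate_skeleton("crook")
  post <- cr[cr$point_index >= 6, ]           # tail-side points
  fitline <- stats::lm(y ~ x, data = post)
  expect_lt(max(abs(stats::resid(fitline))), 1e-6)
  expect_gt(max(abs(cr$y)), 0.01)             # anterior actually bends

  # translating sinusoid: point-9 track length equals imposed translation
  sk <- simulate_skeleton("sinusoid",
                          list(n_frames = 6, translate = c(0.25, 0)))
  tm <- track_metrics(sk, dt = 1)
  expect_equal(tm$track_length, 5 * 0.25, tolerance = 1e-6)
  expect_error(simulate_skeleton("spiral"), "spiral")
})
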