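# End-to-end pipeline: chain the stages into the three headline analyses
# (sleep quantification, learning/memory scoring, synapse time course).

#' Write a full synthetic input bundle
#'
#' Generates one dataset per analysis input (displacement series for every
#' configured group, chemotaxis plates for both conditions at 0 h and 16 h,
#' synapse time-course records for both conditions, sleep--memory trial
#' pairs) and writes them as the CSV dialects [load_table()] reads.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_plate_trials Chemotaxis trials per timepoint (default 10).
#' @param n_worms_per_plate Worms per simulated plate (default 120).
#' @return Named character vector of the written file paths, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir, n_plate_trials = 10L,
                            n_worms_per_plate = 120L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    displacement = file.path(out_dir, "displacement.csv"),
    plate = file.path(out_dir, "plates.csv"),
    synapse = file.path(out_dir, "synapse.csv"),
    sleep_memory = file.path(out_dir, "sleep_memory.csv")
  )
  disp <- dplyr::bind_rows(lapply(names(config$groups), function(g) {
    simulate_displacement(config, g)
  }))
  write_table(disp, paths[["displacement"]])

  plates <- dplyr::bind_rows(lapply(names(config$plate_probs), function(cc) {
    dplyr::bind_rows(lapply(seq_len(n_plate_trials), function(i) {
      dplyr::bind_rows(lapply(c(0, 16), function(tp) {
        simulate_plate_counts(config, cc, n_worms_per_plate,
                              trial_id = sprintf("trial_%03d", i),
                              timepoint_h = tp)
      }))
    }))
  }))
  write_table(plates, paths[["plate"]])

  syn <- dplyr::bind_rows(lapply(names(config$synapse_params), function(cc) {
    simulate_synapse_timecourse(config, cc)
  }))
  write_table(syn, paths[["synapse"]])

  write_table(simulate_sleep_memory(config), paths[["sleep_memory"]])
  invisible(paths)
}

#' Run the analysis pipeline
#'
#' Chains the package's stages into the three headline analyses and writes
#' per-stage CSVs, figures and a run log under `config$out_dir`:
#'
#' * `"sleep"` -- displacement table -> bout detection -> hourly quiescence
#'   -> group summary + raster (CSV matrix and PNG).
#' * `"memory"` -- plate table -> per-plate CI -> per-trial cohort pairs ->
#'   censoring -> LI -> decay-slope comparison when two or more timepoints
#'   are present.
#' * `"synapse"` -- synapse table -> same-day reference normalization ->
#'   per-condition sqrt-scale spline fits -> slope-change table ->
#'   normality-gated group comparisons of the 16-h normalized values.
#' * `"all"` -- every analysis whose input is configured.
#'
#' Given the same configuration the run is deterministic: output CSVs are
#' byte-identical across runs and the log contains no timestamps.
#'
#' @param config A [run_config()]; input paths live in `config$inputs`.
#' @param analysis One of `"sleep"`, `"memory"`, `"synapse"`, `"all"`.
#' @return Invisibly, a list with the computed objects and an `artifacts`
#'   vector of written file paths.
#' @export
run_pipeline <- function(config,
                         analysis = c("all", "sleep", "memory", "synapse")) {
  stopifnot(inherits(config, "run_config"))
  analysis <- match.arg(analysis)
  wanted <- if (analysis == "all") {
    names(Filter(Negate(is.null),
                 config$inputs[c("displacement", "plate", "synapse")]))
  } else {
    need <- c(sleep = "displacement", memory = "plate",
              synapse = "synapse")[[analysis]]
    if (is.null(config$inputs[[need]])) {
      stop_wormsleep(sprintf(
        "analysis '%s' requires config$inputs$%s", analysis, need))
    }
    need
  }
  if (!length(wanted)) {
    stop_wormsleep("no analysis input configured; set config$inputs")
  }
  missing_files <- wanted[!vapply(config$inputs[wanted], file.exists,
                                  logical(1))]
  if (length(missing_files)) {
    stop_wormsleep("missing input file(s): ",
                   paste(unlist(config$inputs[missing_files]),
                         collapse = ", "))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("wormsleep run log",
                 paste0("analysis: ", analysis),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(unclass(config)),
                                       "\n")[[1]]))
  artifacts <- character(0)
  results <- list()
  out <- function(name) file.path(config$out_dir, name)

  if ("displacement" %in% wanted) {
    disp <- load_table(config$inputs$displacement, "displacement")
    qc <- config$quiescence
    attr(disp, "dt") <- qc$dt
    bouts <- detect_bouts(disp, zero_threshold = qc$zero_threshold,
                          min_run = qc$min_run, dt = qc$dt)
    hourly <- quiescence_by_hour(bouts, disp, bin_width = qc$bin_width)
    summary_tbl <- group_summary(hourly)
    ras <- quiescence_raster(disp, zero_threshold = qc$zero_threshold,
                             min_run = qc$min_run, dt = qc$dt)
    write_table(as.data.frame(bouts), out("bouts.csv"))
    write_table(hourly, out("quiescence_hourly.csv"))
    write_table(summary_tbl, out("quiescence_summary.csv"))
    utils::write.table(ras$matrix, out("raster_matrix.csv"), sep = ",",
                       row.names = TRUE, col.names = FALSE)
    artifacts <- c(artifacts, out(c("bouts.csv", "quiescence_hourly.csv",
                                    "quiescence_summary.csv",
                                    "raster_matrix.csv")))
    fig <- try(ggplot2::ggsave(out("raster.png"), ras$plot, width = 8,
                               height = 4, dpi = 150), silent = TRUE)
    if (!inherits(fig, "try-error")) {
      artifacts <- c(artifacts, out("raster.png"))
    }
    log_lines <- c(log_lines, sprintf(
      "sleep: %d animals, %d bouts called (min_run = %d, threshold = %g)",
      length(unique(disp$animal_id)), nrow(bouts), qc$min_run,
      qc$zero_threshold))
    results$sleep <- list(bouts = bouts, hourly = hourly,
                          summary = summary_tbl, raster = ras)
  }

  if ("plate" %in% wanted) {
    plates <- load_table(config$inputs$plate, "plate")
    scored <- score_plates(plates)
    pairs <- scored |>
      dplyr::select(dplyr::all_of(c("trial_id", "condition", "timepoint_h",
                                    "ci"))) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "ci",
                         names_prefix = "ci_")
    check_columns(pairs, c("ci_buffer", "ci_butanone"),
                  "per-trial cohort pairs")
    pairs <- censor_trials(pairs, config$chemotaxis$min_buffer_ci)
    pairs <- learning_index(pairs)
    n_censored <- sum(pairs$censored)
    write_table(scored, out("plate_ci.csv"))
    write_table(pairs, out("learning_index.csv"))
    artifacts <- c(artifacts, out(c("plate_ci.csv", "learning_index.csv")))
    log_lines <- c(log_lines, sprintf(
      "memory: %d plates, %d trial pairs, %d censored (buffer CI < %g)",
      nrow(scored), nrow(pairs), n_censored,
      config$chemotaxis$min_buffer_ci))
    results$memory <- list(plates = scored, pairs = pairs)
    li_long <- tibble::tibble(condition = "butanone",
                              timepoint_h = pairs$timepoint_h,
                              li = pairs$li)
    if (length(unique(li_long$timepoint_h[!is.na(li_long$li)])) >= 2L) {
      slopes <- decay_slope_compare(li_long)
      write_table(slopes$slopes, out("memory_decay_slopes.csv"))
      artifacts <- c(artifacts, out("memory_decay_slopes.csv"))
      results$memory$decay <- slopes
      log_lines <- c(log_lines, sprintf(
        "memory: decay slope %.4g LI/h", slopes$slopes$slope[1]))
    }
  }

  if ("synapse" %in% wanted) {
    syn <- load_table(config$inputs$synapse, "synapse")
    syn <- normalize_intensity(syn, reference = config$synapse$reference)
    fits <- lapply(split(syn, as.character(syn$condition)),
                   fit_piecewise_sqrt,
                   knot_h = config$synapse$knot_h,
                   value = config$synapse$value)
    fit_tbl <- slope_change_summary(fits)
    write_table(syn, out("synapse_normalized.csv"))
    write_table(fit_tbl, out("synapse_spline_fits.csv"))
    artifacts <- c(artifacts, out(c("synapse_normalized.csv",
                                    "synapse_spline_fits.csv")))
    final_t <- max(syn$timepoint_h)
    final <- syn[syn$timepoint_h == final_t, ]
    if (length(unique(final$condition)) >= 2L &&
        all(table(final$condition) >= 3L)) {
      plan <- choose_and_run_tests(
        data.frame(group = as.character(final$condition),
                   value = final$normalized_pct),
        alpha = config$stats$alpha, adjust = config$stats$adjust)
      write_table(plan$pairwise, out("synapse_pairwise_tests.csv"))
      artifacts <- c(artifacts, out("synapse_pairwise_tests.csv"))
      results$synapse_tests <- plan
      log_lines <- c(log_lines, sprintf(
        "synapse: %s branch at %g h (%s adjustment)", plan$branch, final_t,
        plan$adjust_method))
    }
    log_lines <- c(log_lines, sprintf(
      "synapse: %d records, conditions: %s; slope-change p: %s",
      nrow(syn), paste(fit_tbl$condition, collapse = ", "),
      paste(signif(fit_tbl$p_slope_change, 3), collapse = ", ")))
    results$synapse <- list(records = syn, fits = fits, table = fit_tbl)
  }

  writeLines(log_lines, out("run_log.txt"))
  artifacts <- c(artifacts, out("run_log.txt"))
  invisible(c(results, list(artifacts = artifacts)))
}
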