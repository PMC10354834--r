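# CSV schemas, validated loading, and run configuration.

# Column name -> coercion target for each table dialect the pipeline reads
# and the simulator writes.
.schemas <- list(
  displacement = c(animal_id = "character", group = "character",
                   frame_index = "integer", displacement = "numeric"),
  skeleton = c(animal_id = "character", frame_index = "integer",
               point_index = "integer", x = "numeric", y = "numeric"),
  plate = c(trial_id = "character", condition = "character",
            timepoint_h = "numeric", n_odor = "integer",
            n_diluent = "integer", n_origin = "integer",
            n_total = "integer"),
  trace = c(worm_id = "character", frame_index = "integer",
            roi_mean = "numeric", bg_mean = "numeric"),
  synapse = c(worm_id = "character", marker = "character",
              condition = "character", sleep_status = "character",
              timepoint_h = "numeric", assay_day = "character",
              raw_intensity = "numeric"),
  feeding = c(animal_id = "character", group = "character",
              pumps_15s = "integer", paused_ge4s = "logical"),
  samples = c(group = "character", value = "numeric"),
  sleep_memory = c(trial_id = "character", quiescence_min = "numeric",
                   li_16h = "numeric")
)

#' Table schemas understood by [load_table()]
#'
#' @return Named list: for each schema label, the required columns and
#'   their types.
#' @export
table_schemas <- function() .schemas

#' Load and validate a CSV table
#'
#' Reads a tidy CSV, checks that every column the schema requires is
#' present (extra columns are kept as-is), and coerces the required
#' columns to their declared types. An unparsable cell is reported with
#' its row number; an empty file with a valid header yields an empty
#' table with a warning.
#'
#' @param path Path to a CSV file.
#' @param schema One of `names(table_schemas())`.
#' @return A validated tibble.
#' @export
load_table <- function(path, schema) {
  if (!schema %in% names(.schemas)) {
    stop_wormsleep(sprintf("unknown schema '%s' (have: %s)", schema,
                           paste(names(.schemas), collapse = ", ")))
  }
  if (!file.exists(path)) stop_wormsleep("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  spec <- .schemas[[schema]]
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    stop_wormsleep(sprintf(
      "%s does not match schema '%s': missing column%s %s", path, schema,
      if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warning(sprintf("%s: empty table under schema '%s'", path, schema))
  }
  for (col in names(spec)) {
    raw <- df[[col]]
    val <- switch(spec[[col]],
                  character = raw,
                  integer = suppressWarnings(as.integer(raw)),
                  numeric = suppressWarnings(as.numeric(raw)),
                  logical = suppressWarnings(as.logical(raw)))
    bad <- which(is.na(val) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad)) {
      stop_wormsleep(sprintf(
        "%s: cannot parse column '%s' as %s at row %d (value '%s')",
        path, col, spec[[col]], bad[1], raw[bad[1]]))
    }
    df[[col]] <- val
  }
  tibble::as_tibble(df)
}

write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "wormsleep-out",
    log_level = "info",
    inputs = list(displacement = NULL, skeleton = NULL, plate = NULL,
                  trace = NULL, synapse = NULL, feeding = NULL),
    quiescence = list(zero_threshold = 0, min_run = 9L, dt = 3,
                      bin_width = 3600),
    kinematics = list(dt = 3, ma_window = 10L, still_window = 10L),
    chemotaxis = list(min_buffer_ci = 0.5),
    calcium = list(fps = 2, f0_frames = 3L, pre_window = c(20, 30),
                   post_window = c(30.5, 40.5)),
    synapse = list(knot_h = 2, value = "normalized_pct",
                   reference = list(condition = "buffer",
                                    sleep_status = "slept",
                                    timepoint_h = 16)),
    stats = list(alpha = 0.05, adjust = "auto")
  )
}

#' Build a pipeline run configuration
#'
#' Merges user settings over the documented defaults. Unknown top-level or
#' stage-level keys are rejected rather than silently ignored, and every
#' parameter is echoed into the run log by [run_pipeline()].
#'
#' @param ... Named settings; nested stages (e.g. `quiescence`) are lists
#'   merged key-wise over their defaults.
#' @return Object of class `run_config`.
#' @export
#' @examples
#' run_config(seed = 7, quiescence = list(min_run = 9))
run_config <- function(...) {
  user <- list(...)
  base <- .default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop_wormsleep("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      sub_unknown <- setdiff(names(user[[nm]]), names(base[[nm]]))
      if (length(sub_unknown)) {
        stop_wormsleep(sprintf("unknown config key(s) under '%s': %s", nm,
                               paste(sub_unknown, collapse = ", ")))
      }
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]],
                                      keep.null = TRUE)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base$seed <- as.integer(base$seed)
  structure(base, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The on-disk form round-trips: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
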