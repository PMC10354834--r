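# Chemotaxis / learning-index scoring, trial censoring, imaging-batch
# behavioral gates, and memory-decay slope comparison.

#' Chemotaxis index
#'
#' `CI = (n_odor - n_diluent) / (n_total - n_origin)`: worms that stayed at
#' the plate origin never scored, while worms elsewhere on the plate (in
#' neither arena) still count in the denominator. Vectorized.
#'
#' @param n_odor,n_diluent,n_origin,n_total Nonnegative worm counts;
#'   `n_odor + n_diluent + n_origin <= n_total`.
#' @return Numeric CI in \[-1, 1\].
#' @export
#' @examples
#' chemotaxis_index(70, 10, 20, 100)   # 0.75
chemotaxis_index <- function(n_odor, n_diluent, n_origin, n_total) {
  counts <- cbind(n_odor, n_diluent, n_origin, n_total)
  if (any(counts < 0)) stop_wormsleep("counts must be >= 0")
  if (any(n_odor + n_diluent + n_origin > n_total)) {
    stop_wormsleep("arena + origin counts exceed n_total")
  }
  scoring <- n_total - n_origin
  if (any(scoring == 0)) {
    stop_wormsleep("CI undefined: no worm left the origin (n_total == n_origin)")
  }
  (n_odor - n_diluent) / scoring
}

#' Score a table of chemotaxis plates
#'
#' @param plates Data frame with columns `trial_id`, `condition`,
#'   `timepoint_h`, `n_odor`, `n_diluent`, `n_origin`, `n_total`.
#' @return The table with a `ci` column appended.
#' @export
score_plates <- function(plates) {
  check_columns(plates, c("trial_id", "condition", "timepoint_h", "n_odor",
                          "n_diluent", "n_origin", "n_total"), "plate table")
  plates$ci <- chemotaxis_index(plates$n_odor, plates$n_diluent,
                                plates$n_origin, plates$n_total)
  tibble::as_tibble(plates)
}

#' Censor trials with a failed buffer control
#'
#' A trial is censored when its buffer-trained cohort's CI is strictly
#' below `min_buffer_ci` (default 0.5): such a population could not
#' chemotax to the odor, so its learning index is uninterpretable.
#' Censored trials are flagged, not dropped, and are excluded from
#' downstream LI statistics.
#'
#' @param pairs Data frame with columns `trial_id`, `timepoint_h`,
#'   `ci_buffer`, `ci_butanone` (one row per trial x timepoint).
#' @param min_buffer_ci Censoring threshold (strict `<`).
#' @return The table with a logical `censored` column.
#' @export
censor_trials <- function(pairs, min_buffer_ci = 0.5) {
  if (nrow(pairs) == 0L) {
    pairs$censored <- logical(0)
    return(tibble::as_tibble(pairs))
  }
  check_columns(pairs, c("ci_buffer", "ci_butanone"), "cohort-pair table")
  pairs$censored <- pairs$ci_buffer < min_buffer_ci
  tibble::as_tibble(pairs)
}

#' Learning index
#'
#' `LI = CI_buffer - CI_butanone`, so that learning (reduced attraction in
#' the odor-trained cohort) is positive. With data-frame input, censored
#' rows get `NA` unless `force = TRUE`.
#'
#' @param pairs Either a data frame with `ci_buffer` / `ci_butanone`
#'   (optionally `censored`) columns, or a numeric vector of buffer CIs.
#' @param ci_butanone Butanone-cohort CIs when `pairs` is numeric.
#' @param force Compute LI for censored rows anyway.
#' @return Numeric LI in \[-2, 2\], or the table with an `li` column.
#' @export
#' @examples
#' learning_index(0.8, 0.1)   # 0.7
learning_index <- function(pairs, ci_butanone = NULL, force = FALSE) {
  if (is.data.frame(pairs)) {
    check_columns(pairs, c("ci_buffer", "ci_butanone"), "cohort-pair table")
    li <- pairs$ci_buffer - pairs$ci_butanone
    if (!force && "censored" %in% names(pairs)) {
      li[pairs$censored] <- NA_real_
    }
    pairs$li <- li
    return(tibble::as_tibble(pairs))
  }
  pairs - ci_butanone
}

#' Imaging-batch behavioral gate
#'
#' Decides whether a training batch's chemotaxis check qualifies its
#' animals for synaptic imaging. Butanone-trained batches allowed to sleep
#' pass only if they were *not* attracted to the odor (`CI < 0.5`);
#' buffer-trained batches (any sleep status) and butanone-trained batches
#' whose sleep was disrupted pass only if they *were* attracted
#' (`CI > 0.5`). Both rules are strict, so a CI of exactly 0.5 always
#' fails. Vectorized; a pure function of (condition, sleep status, CI).
#'
#' @param condition `"buffer"` or `"butanone"`.
#' @param sleep_status `"slept"`, `"disturbed"`, `"disturbed_mech"` or
#'   `"disturbed_food"` (the latter two are forms of `"disturbed"`).
#' @param ci Batch chemotaxis index.
#' @param batch_id Optional identifier carried into the output.
#' @return Tibble `batch_id`, `condition`, `sleep_status`, `ci`, `passed`.
#' @export
#' @examples
#' imaging_batch_gate("butanone", "slept", 0.2)$passed   # TRUE
imaging_batch_gate <- function(condition, sleep_status, ci,
                               batch_id = NULL) {
  ok_cond <- condition %in% c("buffer", "butanone")
  ok_status <- sleep_status %in% c("slept", "disturbed", "disturbed_mech",
                                   "disturbed_food")
  if (!all(ok_cond)) {
    stop_wormsleep("unknown condition: ",
                   paste(unique(condition[!ok_cond]), collapse = ", "))
  }
  if (!all(ok_status)) {
    stop_wormsleep("unknown sleep_status: ",
                   paste(unique(sleep_status[!ok_status]), collapse = ", "))
  }
  slept_btn <- condition == "butanone" & sleep_status == "slept"
  passed <- ifelse(slept_btn, ci < 0.5, ci > 0.5)
  n <- max(length(condition), length(sleep_status), length(ci))
  tibble::tibble(
    batch_id = if (is.null(batch_id)) sprintf("batch_%d", seq_len(n))
               else batch_id,
    condition = condition, sleep_status = sleep_status, ci = ci,
    passed = passed
  )
}

#' Compare memory-decay slopes across conditions
#'
#' Fits, per condition, the least-squares slope of learning index on time
#' (LI/h), then tests each pair of conditions for slope equality via the
#' time-by-condition interaction term of a joint linear model (two-sided).
#' On noiseless data with a zero interaction the p-value is reported as 1,
#' and as 0 for a nonzero interaction with zero residual error.
#'
#' @param li_records Data frame with columns `condition`, `timepoint_h`,
#'   `li` (censored/NA rows are dropped). Conditions observed at fewer
#'   than 2 distinct timepoints are excluded with a warning.
#' @return List of class `decay_slopes`: `slopes` tibble (`condition`,
#'   `slope`, `se`, `n`) and `comparisons` tibble (`condition1`,
#'   `condition2`, `slope_diff`, `p_value`).
#' @export
decay_slope_compare <- function(li_records) {
  check_columns(li_records, c("condition", "timepoint_h", "li"), "LI table")
  d <- li_records[!is.na(li_records$li), ]
  keep <- vapply(split(d$timepoint_h, d$condition),
                 function(t) length(unique(t)) >= 2L, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warning("excluding condition(s) with a single timepoint: ",
            paste(dropped, collapse = ", "))
  }
  d <- d[d$condition %in% names(keep)[keep], ]
  conds <- unique(as.character(d$condition))
  if (!length(conds)) stop_wormsleep("no condition with >= 2 timepoints")

  slopes <- dplyr::bind_rows(lapply(conds, function(cc) {
    sub <- d[d$condition == cc, ]
    fit <- lm(li ~ timepoint_h, data = sub)
    sm <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(condition = cc, slope = sm["timepoint_h", 1],
                   se = sm["timepoint_h", 2], n = nrow(sub))
  }))

  pairs <- if (length(conds) >= 2L) utils::combn(conds, 2, simplify = FALSE)
           else list()
  comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    sub <- d[d$condition %in% pr, ]
    sub$condition <- factor(as.character(sub$condition), levels = pr)
    fit <- lm(li ~ timepoint_h * condition, data = sub)
    sm <- suppressWarnings(summary(fit))  # perfect fits handled below
    cf <- sm$coefficients
    term <- grep("^timepoint_h:", rownames(cf), value = TRUE)
    est <- cf[term, 1]
    se <- cf[term, 2]
    scale <- max(abs(sub$li), 1)
    if (sm$sigma < 1e-8 * scale) {   # noiseless data: pin exact-fit values
      se <- 0
      if (abs(est) < 1e-8 * scale) est <- 0
    }
    p <- two_sided_p(est, se, df = fit$df.residual)
    tibble::tibble(condition1 = pr[1], condition2 = pr[2],
                   slope_diff = est, p_value = p)
  }))
  structure(list(slopes = slopes, comparisons = comparisons),
            class = "decay_slopes")
}

#' @export
print.decay_slopes <- function(x, ...) {
  cat("<decay_slopes>\n")
  print(x$slopes)
  if (nrow(x$comparisons)) print(x$comparisons)
  invisible(x)
}
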