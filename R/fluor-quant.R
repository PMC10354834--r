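# Calcium dF/F0 responses and transsynaptic-marker intensity
# quantification, normalization and single-worm change classification.

#' Background-subtracted dF/F0 trace
#'
#' `F_t = roi_mean_t - bg_mean_t`; `F0` is the mean of the first
#' `f0_frames` values of `F` (default 3); `dff_t = 100 * (F_t - F0) / F0`,
#' in percent. Adding a common offset to both ROI and background leaves the
#' trace unchanged.
#'
#' @param trace Data frame with columns `roi_mean`, `bg_mean` (optionally
#'   `worm_id`, `frame_index`), or a numeric `roi_mean` vector with
#'   `bg_mean` supplied separately.
#' @param bg_mean Background series when `trace` is numeric.
#' @param fps Frames per second (default 2); sets the `time_s` column.
#' @param f0_frames Number of initial frames defining F0.
#' @return Tibble `frame_index` (0-based), `time_s`, `f`, `dff` (percent),
#'   plus `worm_id` when present.
#' @export
#' @examples
#' dff_trace(rep(110, 8), rep(10, 8))$dff   # all 0
dff_trace <- function(trace, bg_mean = NULL, fps = 2, f0_frames = 3L) {
  if (is.data.frame(trace)) {
    check_columns(trace, c("roi_mean", "bg_mean"), "fluorescence trace")
    if ("frame_index" %in% names(trace)) {
      trace <- trace[order(trace$frame_index), ]
    }
    roi <- trace$roi_mean
    bg <- trace$bg_mean
    worm <- if ("worm_id" %in% names(trace)) trace$worm_id[1] else NULL
  } else {
    roi <- trace
    bg <- bg_mean
    worm <- NULL
  }
  check_number(fps, "fps", lower = 1e-12)
  f0_frames <- as.integer(f0_frames)
  if (length(roi) != length(bg)) {
    stop_wormsleep("roi_mean and bg_mean must have equal length")
  }
  if (length(roi) <= f0_frames) {
    stop_wormsleep("trace must be longer than f0_frames")
  }
  f <- roi - bg
  f0 <- mean(f[seq_len(f0_frames)])
  if (!is.finite(f0) || f0 <= 0) {
    stop_wormsleep(sprintf("F0 = %.4g <= 0: dF/F0 undefined", f0))
  }
  out <- tibble::tibble(
    frame_index = seq_along(f) - 1L,
    time_s = (seq_along(f) - 1L) / fps,
    f = f,
    dff = 100 * (f - f0) / f0
  )
  if (!is.null(worm)) out <- dplyr::mutate(out, worm_id = worm, .before = 1)
  out
}

#' Odor-switch response magnitude
#'
#' Absolute difference between the mean dF/F0 in a pre-switch window
#' (default 20--30 s) and a post-switch window (default 30.5--40.5 s).
#' Frames are mapped to times `t = frame_index / fps` and window bounds are
#' inclusive, so at 2 fps the defaults cover frames 40--60 and 61--81.
#' Missing values inside a window are averaged over the available frames
#' and flagged via `complete = FALSE`.
#'
#' @param dff A tibble from [dff_trace()] (uses its `time_s`/`dff`
#'   columns), or a numeric dF/F0 vector with `fps` giving the timing.
#' @param pre_window,post_window Length-2 numeric `c(start, end)` seconds.
#' @param fps Frames per second for vector input.
#' @return One-row tibble: `pre_mean`, `post_mean`, `magnitude`, `n_pre`,
#'   `n_post`, `complete`.
#' @export
response_magnitude <- function(dff, pre_window = c(20, 30),
                               post_window = c(30.5, 40.5), fps = 2) {
  if (is.data.frame(dff)) {
    check_columns(dff, c("time_s", "dff"), "dF/F0 table")
    t <- dff$time_s
    v <- dff$dff
  } else {
    t <- (seq_along(dff) - 1L) / fps
    v <- dff
  }
  win_mean <- function(win, label) {
    sel <- t >= win[1] & t <= win[2]
    if (!any(sel)) {
      stop_wormsleep(sprintf("%s window [%g, %g] s contains no frame",
                             label, win[1], win[2]))
    }
    vals <- v[sel]
    list(mean = mean(vals, na.rm = TRUE), n = sum(!is.na(vals)),
         complete = !anyNA(vals))
  }
  pre <- win_mean(pre_window, "pre")
  post <- win_mean(post_window, "post")
  tibble::tibble(
    pre_mean = pre$mean, post_mean = post$mean,
    magnitude = abs(pre$mean - post$mean),
    n_pre = pre$n, n_post = post$n,
    complete = pre$complete && post$complete
  )
}

#' Punctal-cluster intensity
#'
#' Sums pixel intensities over a hand-drawn punctal-cluster mask. In
#' `"raw_sum"` mode the mask pixels are summed as-is. In
#' `"local_min_subtracted"` mode (used for markers over autofluorescent
#' tissue) the minimum intensity of a disjoint surround region is
#' subtracted from every mask pixel before summing, with negative adjusted
#' pixels clamped to 0.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param mask Logical (or 0/1) matrix the same size as `image`, or an
#'   integer index vector, selecting the punctal cluster.
#' @param mode `"raw_sum"` or `"local_min_subtracted"`.
#' @param surround Region directly surrounding the puncta (same encodings
#'   as `mask`); required and disjoint from `mask` in subtracted mode.
#' @return Single numeric intensity.
#' @export
#' @examples
#' img <- matrix(c(10, 20, 5, 7), 2)
#' cluster_intensity(img, c(1, 3), "local_min_subtracted", surround = 4)
cluster_intensity <- function(image, mask,
                              mode = c("raw_sum", "local_min_subtracted"),
                              surround = NULL) {
  mode <- match.arg(mode)
  as_index <- function(m, name) {
    if (is.matrix(m) || is.array(m)) {
      if (!all(dim(m) == dim(image))) {
        stop_wormsleep(sprintf("`%s` dimensions differ from `image`", name))
      }
      which(m != 0)
    } else {
      as.integer(m)
    }
  }
  idx <- as_index(mask, "mask")
  if (length(idx) == 0L) stop_wormsleep("mask is empty")
  if (mode == "raw_sum") return(sum(image[idx]))
  if (is.null(surround)) {
    stop_wormsleep("`surround` is required for local_min_subtracted mode")
  }
  sidx <- as_index(surround, "surround")
  if (length(sidx) == 0L) stop_wormsleep("surround is empty")
  if (length(intersect(idx, sidx))) {
    stop_wormsleep("mask and surround must be disjoint")
  }
  bg <- min(image[sidx])
  sum(pmax(image[idx] - bg, 0))
}

#' Read an image + integer label mask TIFF pair
#'
#' Convenience loader for [cluster_intensity()]: reads a grayscale
#' intensity TIFF and a label-mask TIFF (0 = background, k = region k) and
#' returns them as matrices. Requires the `tiff` package.
#'
#' @param image_path,mask_path Paths to the intensity and label TIFFs.
#' @return List with `image` (numeric matrix, native scale) and `mask`
#'   (integer matrix).
#' @export
read_intensity_tiff <- function(image_path, mask_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_wormsleep("the 'tiff' package is required to read TIFF input")
  }
  img <- tiff::readTIFF(image_path, as.is = TRUE)
  msk <- tiff::readTIFF(mask_path, as.is = TRUE)
  list(image = img * 1.0, mask = round(msk))
}

#' Normalize synaptic intensities to a same-day reference
#'
#' Each animal's raw punctal intensity is expressed as a percentage of the
#' median raw intensity of that assay day's reference animals -- by default
#' buffer-trained animals that slept, imaged at 16 h (placed on food for
#' 16 h). Reference animals therefore normalize to a day-median of 100%,
#' and rescaling any whole day's raw intensities leaves the percentages
#' unchanged.
#'
#' @param records Data frame with columns `condition`, `sleep_status`,
#'   `timepoint_h`, `assay_day`, `raw_intensity` (see
#'   [simulate_synapse_timecourse()] for the full schema).
#' @param reference Named list selecting reference animals; entries are
#'   matched against columns of `records`.
#' @return The table with a `normalized_pct` column.
#' @export
normalize_intensity <- function(records,
                                reference = list(condition = "buffer",
                                                 sleep_status = "slept",
                                                 timepoint_h = 16)) {
  check_columns(records, c(names(reference), "assay_day", "raw_intensity"),
                "synapse table")
  if (any(records$raw_intensity < 0)) {
    stop_wormsleep("raw_intensity must be >= 0")
  }
  is_ref <- rep(TRUE, nrow(records))
  for (nm in names(reference)) {
    is_ref <- is_ref & records[[nm]] == reference[[nm]]
  }
  days <- unique(records$assay_day)
  no_ref <- setdiff(days, unique(records$assay_day[is_ref]))
  if (length(no_ref)) {
    stop_wormsleep("no reference animals on day(s): ",
                   paste(no_ref, collapse = ", "))
  }
  ref_median <- tapply(records$raw_intensity[is_ref],
                       records$assay_day[is_ref], median)
  records$normalized_pct <-
    100 * records$raw_intensity /
    as.numeric(ref_median[as.character(records$assay_day)])
  tibble::as_tibble(records)
}

#' Single-worm intensity change between two timepoints
#'
#' For animals imaged twice, the first timepoint is taken as 100% and the
#' second expressed relative to it; an animal is classified as reduced when
#' the drop reaches the cutoff fraction -- `>= 50%` reduction (i.e.
#' `pct <= 50`) at the default, boundary inclusive.
#'
#' @param first,second Raw intensities at the two timepoints (`first > 0`).
#' @param cut Reduction fraction for the `reduced` call (default 0.5).
#' @return Tibble `pct` (second as % of first) and `reduced` (logical).
#' @export
#' @examples
#' single_worm_change(200, 100)$reduced   # TRUE: exactly 50% reduction
single_worm_change <- function(first, second, cut = 0.5) {
  if (any(first <= 0)) stop_wormsleep("first-timepoint intensity must be > 0")
  if (any(second < 0)) stop_wormsleep("second-timepoint intensity must be >= 0")
  check_number(cut, "cut", lower = 0, upper = 1)
  pct <- 100 * second / first
  tibble::tibble(pct = pct, reduced = (first - second) / first >= cut)
}
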