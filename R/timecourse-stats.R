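# Square-root-scale piecewise-linear time-course model of synaptic change,
# plus the statistical decision tree used across the behavioral figures
# (normality gate, pairwise tests, Hochberg/Bonferroni adjustment, Pearson
# correlation, two-proportion Z-test).

#' Fit the piecewise-linear sqrt-scale time-course model
#'
#' Least-squares regression of `sqrt(intensity)` on the continuous hinge
#' basis `{1, t, max(0, t - knot_h)}`. The mean is piecewise linear in time
#' with a possible slope change at the knot (2 h post-training, the
#' critical period, by default): `b_early` is the slope over 0 to `knot_h`
#' and `b_late = b_early + delta` the slope after it, all in sqrt-intensity
#' units per hour. The square-root transformation stabilizes the residuals
#' of intensity data toward normality.
#'
#' The slope change is tested through the hinge coefficient:
#' `t = delta / se(delta)` against Student's t with `n - 3` df, two-sided.
#' On noiseless (exactly interpolated) data the p-value is reported as 1
#' when `delta = 0` and 0 otherwise.
#'
#' @param records Data frame with columns `timepoint_h` and the response
#'   named by `value` (default `normalized_pct`, the display scale; use
#'   `"raw_intensity"` for raw mode). If a `condition` column is present it
#'   must be constant; fit conditions separately.
#' @param knot_h Knot location in hours (> 0), fixed, not estimated.
#' @param value Name of the response column; values must be >= 0.
#' @return Object of class `spline_fit`: a list with `condition`, `a`
#'   (sqrt-scale intercept at t = 0), `b_early`, `b_late`, `delta`,
#'   `knot_h`, `se_delta`, `t_stat`, `df` (= n - 3), `p_slope_change`, `n`,
#'   and the underlying `lm` fit (`model`).
#' @export
fit_piecewise_sqrt <- function(records, knot_h = 2,
                               value = "normalized_pct") {
  check_number(knot_h, "knot_h", lower = 1e-9)
  check_columns(records, c("timepoint_h", value), "time-course table")
  cond <- if ("condition" %in% names(records)) {
    u <- unique(as.character(records$condition))
    if (length(u) > 1L) {
      stop_wormsleep("records span several conditions; fit them separately")
    }
    u
  } else NA_character_
  y_raw <- records[[value]]
  t <- records$timepoint_h
  ok <- !is.na(y_raw) & !is.na(t)
  y_raw <- y_raw[ok]
  t <- t[ok]
  if (any(y_raw < 0)) {
    stop_wormsleep("negative intensities: sqrt transform undefined")
  }
  n <- length(y_raw)
  if (n < 4L) stop_wormsleep("need at least 4 observations")
  if (length(unique(t[t <= knot_h])) < 2L || !any(t > knot_h)) {
    stop_wormsleep(
      "hinge basis is rank deficient: need >= 2 distinct timepoints at or ",
      "before the knot and >= 1 after it")
  }
  d <- data.frame(y = sqrt(y_raw), t = t, hinge = pmax(0, t - knot_h))
  fit <- lm(y ~ t + hinge, data = d)
  cf <- coef(fit)
  sm_fit <- suppressWarnings(summary(fit))  # perfect fits handled below
  se_delta <- sm_fit$coefficients["hinge", 2]
  if (!is.finite(se_delta)) se_delta <- 0
  delta <- unname(cf["hinge"])
  # exact interpolation: the residual SE and the hinge estimate are pure
  # floating-point dust, so pin them to their exact-fit values
  scale <- max(abs(d$y), 1)
  if (sm_fit$sigma < 1e-8 * scale) {
    se_delta <- 0
    if (abs(delta) < 1e-8 * scale) delta <- 0
  }
  p <- two_sided_p(delta, se_delta, df = n - 3)
  t_stat <- if (se_delta > 0) delta / se_delta else {
    if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  }
  structure(list(
    condition = cond,
    a = unname(cf["(Intercept)"]),
    b_early = unname(cf["t"]),
    b_late = unname(cf["t"] + cf["hinge"]),
    delta = delta,
    knot_h = knot_h,
    se_delta = se_delta,
    t_stat = t_stat,
    df = n - 3,
    p_slope_change = p,
    n = n,
    model = fit
  ), class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "<spline_fit%s> n = %d, knot = %g h\n",
    if (is.na(x$condition)) "" else paste0(": ", x$condition), x$n, x$knot_h))
  cat(sprintf("  sqrt scale: a = %.4g, slope 0-%g h = %.4g, slope after = %.4g\n",
              x$a, x$knot_h, x$b_early, x$b_late))
  cat(sprintf("  slope change: delta = %.4g (SE %.3g), t(%d) = %.3g, p = %.4g\n",
              x$delta, x$se_delta, x$df, x$t_stat, x$p_slope_change))
  invisible(x)
}

#' Predicted sqrt-scale mean of a spline fit
#'
#' @param object A `spline_fit`.
#' @param t Hours post-training.
#' @param ... Unused.
#' @return Predicted `sqrt(intensity)` at `t`.
#' @export
predict.spline_fit <- function(object, t, ...) {
  object$a + object$b_early * pmin(t, object$knot_h) +
    (object$b_late) * pmax(0, t - object$knot_h)
}

#' Tabulate slope-change fits
#'
#' @param fits A `spline_fit` or list of them (e.g. one per condition).
#' @return Tibble with one row per fit: `condition`, `a`, `b_early`,
#'   `b_late`, `delta`, `se_delta`, `p_slope_change`, `n`.
#' @export
slope_change_summary <- function(fits) {
  if (inherits(fits, "spline_fit")) fits <- list(fits)
  if (!length(fits)) stop_wormsleep("no fits supplied")
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(condition = f$condition, a = f$a, b_early = f$b_early,
                   b_late = f$b_late, delta = f$delta,
                   se_delta = f$se_delta,
                   p_slope_change = f$p_slope_change, n = f$n)
  }))
}

#' Hochberg step-up p-value adjustment
#'
#' With the m raw p-values sorted ascending, the largest is left unchanged
#' and, stepping down, `adj(i) = min(adj(i+1), (m - i + 1) * p(i))`,
#' capped at 1 and mapped back to the input order. Uniformly no more
#' conservative than Bonferroni.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' hochberg_adjust(c(0.01, 0.04, 0.03))   # 0.03 0.04 0.04
hochberg_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_wormsleep("p-values must be in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  adj[m] <- ps[m]
  if (m > 1L) {
    for (i in (m - 1L):1L) {
      adj[i] <- min(adj[i + 1L], (m - i + 1L) * ps[i])
    }
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Normality-gated group comparisons
#'
#' The statistical decision tree applied to every multi-group panel: each
#' group is screened with the Shapiro-Wilk test; if all groups look normal
#' (p > `alpha`) the parametric branch runs (one-way ANOVA omnibus, then
#' pairwise two-sided t-tests with Bonferroni adjustment), otherwise the
#' nonparametric branch runs (Kruskal-Wallis omnibus, then pairwise
#' two-tailed Mann-Whitney U-tests with Hochberg adjustment). With exactly
#' two groups the omnibus is skipped and the single pairwise test is run
#' under the same gate. Mann-Whitney uses the normal approximation with
#' tie correction.
#'
#' @param groups Either a data frame with columns `group`, `value`, or a
#'   named list of numeric vectors. Each group needs n >= 3.
#' @param alpha Gate level for the normality screen (default 0.05).
#' @param adjust `"auto"` (Bonferroni on the parametric branch, Hochberg on
#'   the nonparametric, as above), or force `"hochberg"`/`"bonferroni"`.
#' @return Object of class `test_plan`: `normality` tibble (`group`, `n`,
#'   `shapiro_p`), `branch` (`"parametric"`/`"nonparametric"`), `omnibus`
#'   (list: `method`, `statistic`, `p`; p is `NA` for two groups),
#'   `pairwise` tibble (`group1`, `group2`, `raw_p`, `adjusted_p`,
#'   `method`), and `adjust_method`.
#' @export
choose_and_run_tests <- function(groups, alpha = 0.05,
                                 adjust = c("auto", "hochberg",
                                            "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(groups)) {
    check_columns(groups, c("group", "value"), "sample table")
    groups <- split(groups$value, as.character(groups$group))
  }
  if (length(groups) < 2L) stop_wormsleep("need at least 2 groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3L)) {
    stop_wormsleep("every group needs n >= 3 (normality test undefined): ",
                   paste(names(groups)[ns < 3L], collapse = ", "))
  }
  norm_p <- vapply(groups, function(v) {
    if (length(unique(v)) == 1L) return(0)   # a constant sample: not normal
    shapiro.test(v)$p.value
  }, numeric(1))
  branch <- if (all(norm_p > alpha)) "parametric" else "nonparametric"
  adj_method <- if (adjust == "auto") {
    if (branch == "parametric") "bonferroni" else "hochberg"
  } else adjust

  long <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns))
  )
  omnibus <- if (length(groups) == 2L) {
    list(method = "none (two groups)", statistic = NA_real_, p = NA_real_)
  } else if (branch == "parametric") {
    av <- summary(aov(value ~ group, data = long))[[1]]
    list(method = "one-way ANOVA", statistic = av[1, "F value"],
         p = av[1, "Pr(>F)"])
  } else {
    kw <- kruskal.test(value ~ group, data = long)
    list(method = "Kruskal-Wallis", statistic = unname(kw$statistic),
         p = kw$p.value)
  }

  prs <- utils::combn(names(groups), 2, simplify = FALSE)
  raw_p <- vapply(prs, function(pr) {
    x <- groups[[pr[1]]]
    y <- groups[[pr[2]]]
    if (branch == "parametric") {
      t.test(x, y)$p.value
    } else {
      suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    }
  }, numeric(1))
  adj_p <- if (adj_method == "hochberg") hochberg_adjust(raw_p)
           else pmin(raw_p * length(raw_p), 1)
  pairwise <- tibble::tibble(
    group1 = vapply(prs, `[`, character(1), 1),
    group2 = vapply(prs, `[`, character(1), 2),
    raw_p = raw_p, adjusted_p = adj_p,
    method = if (branch == "parametric") "t-test" else "Mann-Whitney U"
  )
  structure(list(
    normality = tibble::tibble(group = names(groups), n = unname(ns),
                               shapiro_p = unname(norm_p)),
    branch = branch, omnibus = omnibus, pairwise = pairwise,
    adjust_method = adj_method, alpha = alpha
  ), class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat(sprintf("<test_plan> branch: %s (Shapiro-Wilk gate at alpha = %g)\n",
              x$branch, x$alpha))
  cat(sprintf("  omnibus: %s, p = %s\n", x$omnibus$method,
              format(x$omnibus$p, digits = 4)))
  cat(sprintf("  pairwise (%s, %s-adjusted):\n",
              x$pairwise$method[1], x$adjust_method))
  print(x$pairwise)
  invisible(x)
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation and its two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with nonzero
#'   variance; pairs with missing values are dropped.
#' @return Tibble `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_wormsleep("x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_wormsleep("need at least 3 complete pairs")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) stop_wormsleep("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Two-proportion Z-test
#'
#' Pooled-proportion z statistic for `x1/n1` vs `x2/n2` with a two-sided
#' normal p-value (no continuity correction). When the pooled proportion
#' is 0 or 1 the statistic is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param x1,n1,x2,n2 Successes and totals, `0 <= x <= n`, `n >= 1`.
#' @return Tibble `z`, `p`, `p1`, `p2`.
#' @export
#' @examples
#' two_proportion_ztest(30, 100, 10, 100)$z   # about 3.54
two_proportion_ztest <- function(x1, n1, x2, n2) {
  for (v in list(c(x1, n1), c(x2, n2))) {
    if (v[2] < 1 || v[1] < 0 || v[1] > v[2]) {
      stop_wormsleep("need 0 <= x <= n and n >= 1")
    }
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    warning("degenerate pooled proportion (all failures or all successes)")
    return(tibble::tibble(z = 0, p = 1, p1 = p1, p2 = p2))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}
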