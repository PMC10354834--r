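# Piecewise sqrt-scale time-course model and the statistical decision tree.

test_that("noiseless hinge data are interpolated exactly", {
  t <- c(0, 1, 2, 4, 8, 16)
  mu <- 10 - 2 * pmin(t, 2) - 0.1 * pmax(t - 2, 0)
  d <- data.frame(timepoint_h = t, normalized_pct = mu^2)
  fit <- fit_piecewise_sqrt(d)
  expect_equal(fit$a, 10, tolerance = 1e-9)
  expect_equal(fit$b_early, -2, tolerance = 1e-9)
  expect_equal(fit$b_late, -0.1, tolerance = 1e-9)
  expect_equal(fit$delta, 1.9, tolerance = 1e-9)
  expect_equal(fit$p_slope_change, 0)
  expect_equal(fit$df, length(t) - 3L)
  # equal slopes: delta exactly 0, p = 1
  lin <- data.frame(timepoint_h = t, normalized_pct = (10 - 0.5 * t)^2)
  fl <- fit_piecewise_sqrt(lin)
  expect_equal(fl$delta, 0)
  expect_equal(fl$t_stat, 0)
  expect_equal(fl$p_slope_change, 1)
})

test_that("the fitted mean is continuous at the knot", {
  set.seed(61)
  for (i in 1:20) {
    t <- rep(c(0, 1, 2, 8, 16), each = 4)
    y <- (8 + rnorm(1) - runif(1) * pmin(t, 2) -
            runif(1, 0, 0.3) * pmax(t - 2, 0) + rnorm(length(t), 0, 0.4))^2
    fit <- fit_piecewise_sqrt(data.frame(timepoint_h = t,
                                         normalized_pct = y))
    eps <- 1e-7
    expect_lt(abs(predict(fit, fit$knot_h - eps) -
                    predict(fit, fit$knot_h + eps)), 1e-6)
  }
})

test_that("degenerate time-course inputs are refused", {
  d <- data.frame(timepoint_h = c(0, 0, 1, 1), normalized_pct = 1:4)
  expect_error(fit_piecewise_sqrt(d), "rank deficient")
  neg <- data.frame(timepoint_h = c(0, 1, 2, 16), normalized_pct = c(1, -1, 1, 1))
  expect_error(fit_piecewise_sqrt(neg), "sqrt")
  tiny <- data.frame(timepoint_h = c(0, 2, 16), normalized_pct = c(1, 1, 1))
  expect_error(fit_piecewise_sqrt(tiny), "4 observations")
  two_cond <- data.frame(timepoint_h = c(0, 1, 2, 16),
                         normalized_pct = 1:4,
                         condition = c("a", "a", "b", "b"))
  expect_error(fit_piecewise_sqrt(two_cond), "separately")
})

test_that("slope-change summary tabulates one row per fit, unchanged", {
  t <- c(0, 1, 2, 4, 16)
  fit <- fit_piecewise_sqrt(data.frame(
    timepoint_h = t, normalized_pct = (10 - pmin(t, 2))^2))
  tab1 <- slope_change_summary(fit)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$b_early, fit$b_early)
  expect_equal(tab1$p_slope_change, fit$p_slope_change)
  tab2 <- slope_change_summary(list(fit, fit))
  expect_equal(nrow(tab2), 2L)
  expect_equal(tab2[1, ], tab2[2, ])
})

test_that("hochberg adjustment matches the worked example and p.adjust", {
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(hochberg_adjust(0.2), 0.2)
  set.seed(62)
  for (i in 1:100) {
    p <- runif(sample(1:8, 1))
    adj <- hochberg_adjust(p)
    # independent oracle: stats::p.adjust step-up implementation
    expect_equal(adj, p.adjust(p, "hochberg"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(p * length(p), 1)))   # never beyond Bonferroni
    expect_true(all(diff(adj[order(p)]) > -1e-15))    # rank preserving
  }
  expect_error(hochberg_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the normality gate picks the branch the data call for", {
  set.seed(63)
  # clean normal separation: parametric branch, tiny adjusted p
  g <- list(a = rnorm(30), b = rnorm(30, 5))
  plan <- choose_and_run_tests(g)
  expect_equal(plan$branch, "parametric")
  expect_equal(plan$adjust_method, "bonferroni")
  expect_lt(plan$pairwise$adjusted_p, 1e-3)
  expect_true(is.na(plan$omnibus$p))    # two groups: no omnibus
  # a sample compared with itself: no difference declared
  same <- choose_and_run_tests(list(x = g$a, y = g$a))
  expect_equal(same$pairwise$raw_p, 1)
  # heavily skewed samples route to the nonparametric branch most runs
  hits <- 0
  for (i in 1:50) {
    gg <- list(a = stats::rexp(30), b = stats::rexp(30), c = stats::rexp(30))
    pl <- choose_and_run_tests(gg)
    if (pl$branch == "nonparametric") hits <- hits + 1
    if (pl$branch == "nonparametric") {
      expect_equal(pl$adjust_method, "hochberg")
      expect_equal(pl$omnibus$method, "Kruskal-Wallis")
    }
  }
  expect_gte(hits, 45)
  expect_error(choose_and_run_tests(list(a = 1:5)), "2 groups")
  expect_error(choose_and_run_tests(list(a = 1:5, b = 1:2)), "n >= 3")
})

test_that("three-group plans adjust pairwise p-values as configured", {
  set.seed(64)
  g <- list(a = rnorm(20), b = rnorm(20, 3), c = rnorm(20, 6))
  plan <- choose_and_run_tests(g)
  if (plan$branch == "parametric") {
    expect_equal(plan$omnibus$method, "one-way ANOVA")
  }
  expect_equal(nrow(plan$pairwise), 3L)
  expect_true(all(plan$pairwise$adjusted_p >= plan$pairwise$raw_p))
  forced <- choose_and_run_tests(g, adjust = "hochberg")
  expect_equal(forced$pairwise$adjusted_p,
               hochberg_adjust(forced$pairwise$raw_p))
})

test_that("pearson_r matches the closed form and cor.test", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  # three-point dataset by hand: x = (0,1,2), y = (0,1,3);
  # sum dx*dy = 3, sum dx^2 = 2, sum dy^2 = 14/3 -> r = 3/sqrt(28/3)
  got <- pearson_r(c(0, 1, 2), c(0, 1, 3))
  expect_equal(got$r, 3 / sqrt(28 / 3), tolerance = 1e-12)
  oracle <- stats::cor.test(c(0, 1, 2), c(0, 1, 3))
  expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
  set.seed(65)
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x))
    got <- pearson_r(x, y)
    oracle <- stats::cor.test(x, y)
    expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
  expect_error(pearson_r(1:2, 1:2), "3 complete")
})

test_that("generator round trip recovers the configured correlation", {
  cfg <- sim_config(seed = 66, rho = 0.61, n_trials = 2000)
  pairs <- simulate_sleep_memory(cfg)
  res <- pearson_r(pairs$quiescence_min, pairs$li_16h)
  expect_lt(abs(res$r - 0.61), 0.05)
  expect_lt(res$p, 1e-10)
})

test_that("two-proportion z-test matches the pooled formula", {
  expect_equal(two_proportion_ztest(15, 100, 15, 100)$z, 0)
  expect_equal(two_proportion_ztest(15, 100, 15, 100)$p, 1)
  got <- two_proportion_ztest(30, 100, 10, 100)
  expect_equal(got$z, 0.2 / sqrt(0.2 * 0.8 * (1 / 100 + 1 / 100)),
               tolerance = 1e-12)
  expect_equal(got$z, 3.5355, tolerance = 1e-4)
  expect_warning(deg <- two_proportion_ztest(0, 10, 0, 20), "degenerate")
  expect_equal(deg$p, 1)
  expect_error(two_proportion_ztest(5, 3, 1, 2), "<= n")
})
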