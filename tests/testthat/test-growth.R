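## Exponential-phase regression, doubling and lag times, the long-horizon
## no-growth rule, and Welch's t-test.

test_that("a noise-free exponential curve is recovered exactly", {
  ## od(t) = 0.02 * 2^(t/10), t = 0..100 by 5
  cv <- make_growth_curve(od0 = 0.02, t_lag = 0, t_d = 10, od_max = Inf,
                          times = seq(0, 100, 5))
  fit <- fit_exponential(cv$time_h, cv$od600)
  expect_equal(fit$status, "growth")
  expect_equal(fit$slope, log10(2) / 10, tolerance = 1e-12)
  expect_equal(fit$t_d, 10, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(lag_time(fit, cv$time_h, cv$od600), 0, tolerance = 1e-9)
  ## scaling every OD by 3 leaves the slope (and T_D) unchanged
  fit3 <- fit_exponential(cv$time_h, 3 * cv$od600)
  expect_equal(fit3$t_d, fit$t_d, tolerance = 1e-12)
})

test_that("a flat-then-exponential curve yields the geometric lag time exactly", {
  cv <- make_growth_curve(od0 = 0.05, t_lag = 300, t_d = 30, od_max = Inf,
                          times = seq(0, 600, 100))
  fit <- fit_exponential(cv$time_h, cv$od600)
  expect_equal(fit$t_d, 30, tolerance = 1e-9)
  expect_equal(lag_time(fit, cv$time_h, cv$od600), 300, tolerance = 1e-9)
  ## translating the clock by +c translates the lag by +c
  fit_c <- fit_exponential(cv$time_h + 47, cv$od600)
  expect_equal(fit_c$t_d, fit$t_d, tolerance = 1e-9)
  expect_message(
    lag_c <- lag_time(fit_c, cv$time_h + 47, cv$od600), "proxy")
  expect_equal(lag_c, 300 + 47, tolerance = 1e-9)
})

test_that("degenerate and linear curves come out indeterminate, not fitted", {
  ## linear (not exponential) growth fails the R^2 rule on log scale? it
  ## does not; but a concave-on-log curve with a strict r2_min does:
  t <- seq(0, 90, 10)
  expect_equal(fit_exponential(t, 0.05 + 0.01 * t, r2_min = 0.999)$status,
               "indeterminate")
  ## monotone decreasing curve has no positive-slope window at all
  expect_equal(fit_exponential(t, 0.9 * exp(-t / 40))$status, "indeterminate")
  expect_error(fit_exponential(t, rep(0, 10)), "positive")
  expect_error(fit_exponential(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(lag_time(fit_exponential(t, 0.9 * exp(-t / 40)), t, t + 1),
               "growth status")
})

test_that("the six-month no-growth rule needs both flatness and span", {
  flat_long <- make_growth_curve(0.03, 0, 10, od_max = 0.03,
                                 times = seq(0, 4500, 250))
  expect_equal(call_no_growth(flat_long$time_h, flat_long$od600), "no_growth")
  flat_short <- make_growth_curve(0.03, 0, 10, od_max = 0.03,
                                  times = seq(0, 100, 10))
  expect_equal(call_no_growth(flat_short$time_h, flat_short$od600),
               "indeterminate")
  growing <- make_growth_curve(0.02, 0, 400, od_max = 10,
                               times = seq(0, 5000, 250))
  expect_equal(call_no_growth(growing$time_h, growing$od600), "growth")
})

test_that("noisy curves recover the planted doubling and lag times", {
  set.seed(61)
  ok_td <- 0; ok_lag <- 0; n_rep <- 60
  for (r in seq_len(n_rep)) {
    cv <- make_growth_curve(0.02, 20, 10, 0.75, noise_sd = 0.02,
                            times = seq(0, 100, 4))
    fit <- fit_exponential(cv$time_h, cv$od600)
    if (fit$status != "growth") next
    if (abs(fit$t_d - 10) / 10 < 0.05) ok_td <- ok_td + 1
    if (abs(lag_time(fit, cv$time_h, cv$od600) - 20) / 20 < 0.10)
      ok_lag <- ok_lag + 1
  }
  expect_gte(ok_td / n_rep, 0.95)
  expect_gte(ok_lag / n_rep, 0.95)
})

test_that("Welch's test matches its definition and the reference implementation", {
  x <- c(164.3, 159.1, 169.5); y <- c(141.2, 118.4, 163.9)
  w <- welch_t(x, y)
  ref <- stats::t.test(x, y, var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  ## identical samples: t = 0, p = 1; swapping flips the sign only
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_equal(welch_t(y, x)$t, -w$t)
  expect_equal(welch_t(y, x)$p, w$p)
  ## both samples constant
  expect_warning(z <- welch_t(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(z$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  ## 100 random inputs against the t-distribution tail oracle
  set.seed(71)
  for (rep in 1:100) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_t(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the growth table analysis mirrors the per-curve primitives", {
  ds <- make_growth_dataset(seed = 501, n_rep = 3, noise_sd = 0.02)
  res <- analyze_growth(ds$curves)
  expect_equal(nrow(res), 9L)
  expect_true(all(res$status[res$strain == "no_growth"] == "no_growth"))
  expect_true(all(res$status[res$strain != "no_growth"] == "growth"))
  tma <- res[res$strain == "tma_fast", ]
  expect_true(all(abs(tma$t_d_h - 14) / 14 < 0.1))
  expect_true(all(abs(tma$t_lag_h - 12) / 12 < 0.3))
  slow <- res[res$strain == "acetate_slow", ]
  expect_true(all(abs(slow$t_d_h - 80) / 80 < 0.1))
  cmp <- compare_strains(res, "tma_fast", "acetate_slow", "t_d_h")
  expect_lt(cmp$p, 0.01)
  expect_error(compare_strains(res, "tma_fast", "no_growth"), "every replicate")
})
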