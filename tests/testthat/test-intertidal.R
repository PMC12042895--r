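test_that("Gompertz parameters are recovered from noiseless data", {
  yr <- 2001:2010
  y <- 5 * exp(-2 * exp(-0.8 * (yr - 2001)))
  gf <- fit_gompertz(yr, y)
  cf <- coef(gf)
  expect_lt(abs(cf["A"] - 5) / 5, 1e-4)
  expect_lt(abs(cf["b"] - 2) / 2, 1e-4)
  expect_lt(abs(cf["k"] - 0.8) / 0.8, 1e-4)
  expect_lt(max(abs(gf$fitted - y)), 1e-6)
})

test_that("Gompertz predictions respect the asymptote and monotonicity", {
  yr <- 2001:2008
  y <- 12 * exp(-1.5 * exp(-0.4 * (yr - 2001)))
  gf <- fit_gompertz(yr, y)
  expect_equal(predict(gf, 2500), unname(coef(gf)["A"]), tolerance = 1e-6)
  extr <- predict(gf, 2009:2013)
  expect_true(all(diff(extr) >= 0))
  expect_true(all(extr <= coef(gf)["A"]))
})

test_that("degenerate Gompertz inputs are rejected", {
  expect_error(fit_gompertz(2001:2003, c(1, 2, 3)), "at least 4")
  expect_error(fit_gompertz(2001:2006, rep(3, 6)), "constant")
  expect_error(fit_gompertz(2001:2006, c(-1, 1, 2, 3, 4, 5)), "non-negative")
})

test_that("the spline trend reproduces linear data exactly", {
  yr <- 2000:2015
  y <- 2.5 + 0.7 * (yr - 2000)
  sp <- fit_trend_spline(yr, y)
  expect_lt(max(abs(sp$fit - y)), 1e-8)
  expect_true(all(sp$se >= 0))
})

test_that("an infinite smoothing penalty approaches the least-squares line", {
  set.seed(8)
  yr <- 2000:2020
  y <- 3 + 0.5 * (yr - 2000) + rnorm(21, 0, 2)
  sp <- fit_trend_spline(yr, y, sp = 1e9)
  ls <- stats::lm(y ~ yr)
  expect_lt(max(abs(sp$fit - stats::fitted(ls))), 1e-3)
  expect_error(fit_trend_spline(2001:2003, 1:3), "at least 4")
})

test_that("the spline detects a step increase", {
  set.seed(9)
  yr <- 2000:2024
  y <- ifelse(yr >= 2014, 550, 370) + rnorm(length(yr), 0, 40)
  sp <- fit_trend_spline(yr, y)
  expect_gt(mean(sp$fit[sp$year >= 2014]), mean(sp$fit[sp$year < 2014]))
})

test_that("Welch's t test matches the reference implementation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  w <- welch_t_test(a, b)
  r <- stats::t.test(a, b)
  expect_equal(w$t, unname(r$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(r$parameter), tolerance = 1e-10)
  expect_equal(w$p, r$p.value, tolerance = 1e-10)

  set.seed(11)
  for (rep in 1:25) {
    x <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_t_test(x, y)
    r <- stats::t.test(x, y)
    expect_equal(w$t, unname(r$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(r$parameter), tolerance = 1e-10)
    expect_equal(w$p, r$p.value, tolerance = 1e-10)
  }
})

test_that("Welch edge cases behave as documented", {
  x <- c(1, 2, 3)
  w <- welch_t_test(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # increase from a to b gives a negative statistic
  expect_lt(welch_t_test(c(1, 2, 3), c(5, 6, 7))$t, 0)
  # Welch df never exceeds the pooled df
  set.seed(12)
  x <- rnorm(20); y <- rnorm(15, sd = 4)
  expect_lt(welch_t_test(x, y)$df, 20 + 15 - 2)
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero-variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("pre/post summaries mirror the configured mussel expansion", {
  surv <- simulate_intertidal(seed = 2)
  pp <- prepost_summary(surv, cutoff = 2013)
  cmp <- pp$comparisons
  # mussels moved downshore, grew and expanded in cover
  expect_gt(cmp$distance$mean["b"], cmp$distance$mean["a"])
  expect_gt(cmp$size$mean["b"], cmp$size$mean["a"])
  expect_gt(cmp$cover$mean["b"], cmp$cover$mean["a"])
  expect_true(all(vapply(cmp, function(x) x$p, numeric(1)) < 0.05))
  expect_true(all(vapply(cmp, function(x) x$t, numeric(1)) < 0))
})

test_that("a null configuration yields insignificant contrasts", {
  cfg <- intertidal_config(distance_post = c(mean = 9.59, sd = 4.60),
                           size_post = c(mean = 37.5, sd = 13.8),
                           cover_post = c(mean = 5.36, sd = 3.0))
  surv <- simulate_intertidal(cfg, seed = 14)
  pp <- prepost_summary(surv, cutoff = 2013)
  expect_true(all(vapply(pp$comparisons, function(x) x$p, numeric(1)) > 0.05))
})

test_that("pre/post summaries are invariant to record order and labels", {
  surv <- simulate_intertidal(seed = 2)
  shuf <- surv
  set.seed(3)
  shuf$records <- shuf$records[sample(nrow(shuf$records)), ]
  shuf$distances <- shuf$distances[sample(nrow(shuf$distances)), ]
  shuf$sizes <- shuf$sizes[sample(nrow(shuf$sizes)), ]
  shuf$records$site_id <- paste0("relabel_", shuf$records$site_id)
  p1 <- prepost_summary(surv, cutoff = 2013)
  p2 <- prepost_summary(shuf, cutoff = 2013)
  for (v in names(p1$comparisons)) {
    expect_equal(p1$comparisons[[v]]$t, p2$comparisons[[v]]$t)
    expect_equal(p1$comparisons[[v]]$p, p2$comparisons[[v]]$p)
  }
})

test_that("frequency tables conserve observation counts", {
  surv <- simulate_intertidal(seed = 2)
  pp <- prepost_summary(surv, cutoff = 2013)
  expect_equal(sum(pp$tables$distance$pre) + sum(pp$tables$distance$post),
               nrow(surv$distances))
  expect_equal(sum(pp$tables$size$pre) + sum(pp$tables$size$post),
               nrow(surv$sizes))
  expect_equal(sum(pp$tables$cover$pre) + sum(pp$tables$cover$post),
               nrow(surv$records))
})

test_that("census pre/post summaries follow the contract", {
  cen <- simulate_census(seed = 9)
  cp <- census_prepost(cen, cutoff = 2013)
  expect_gt(cp["post", "mean"], cp["pre", "mean"])
  # unsurveyed years reduce n: 2000-2012 minus 2011, 2013-2024 minus 2020
  expect_equal(cp["pre", "n"], 12)
  expect_equal(cp["post", "n"], 11)
  cen_const <- simulate_census(
    census_config(pre = c(mean = 400, sd = 0), post = c(mean = 400, sd = 0)),
    seed = 9)
  cpc <- census_prepost(cen_const, cutoff = 2013)
  expect_equal(cpc$sd, c(0, 0))
  expect_error(census_prepost(cen[cen$year >= 2013, ], cutoff = 2013),
               "both periods")
})

test_that("the sea star trend stage combines Gompertz, gap and spline", {
  surv <- simulate_intertidal(seed = 2)
  pt <- pisaster_trend(surv)
  expect_s3_class(pt$gompertz, "gompertz_fit")
  expect_equal(pt$extrapolation$year, 2008:2012)
  # extrapolated densities continue the pre-collapse growth
  expect_true(all(pt$extrapolation$fit >=
                    max(pt$gompertz$fitted) - 1e-8))
  expect_false(is.null(pt$post_spline))
  # post-collapse spline sits near zero relative to the pre-collapse level
  expect_lt(max(pt$post_spline$fit), 0.2 * max(pt$yearly$pisaster_density))
})
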