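# Rocky intertidal trend stage: Gompertz growth fits, cubic spline trends,
# Welch pre/post comparisons and census summaries.

#' Fit a Gompertz growth curve
#'
#' Nonlinear least squares fit of `y(t) = A * exp(-b * exp(-k * t))` with
#' `t` measured in years since the first observation. A deterministic
#' multi-start grid over the shape and rate, with the asymptote started
#' above the observed maximum, makes the fit reproducible without a
#' supplied initialization.
#'
#' @param years Numeric vector of observation years (>= 4 values).
#' @param values Non-negative observations (e.g. sea star density).
#' @return Object of class `"gompertz_fit"`: `coefficients` (A, b, k),
#'   `sigma` (residual SD), `fitted`, `years`, `t0` (the year mapped to
#'   t = 0), and the underlying `nls` object.
#' @examples
#' yr <- 2001:2007
#' y <- 5 * exp(-2 * exp(-0.8 * (yr - 2001)))
#' coef(fit_gompertz(yr, y))
#' @export
fit_gompertz <- function(years, values) {
  if (length(years) < 4 || length(values) != length(years))
    stop("need at least 4 (year, value) pairs", call. = FALSE)
  if (any(values < 0)) stop("'values' must be non-negative", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate constant series; Gompertz parameters are not identifiable",
         call. = FALSE)
  t <- years - min(years)
  dat <- data.frame(t = t, y = values)
  best <- NULL; best_sse <- Inf
  ymax <- max(values)
  for (A0 in ymax * c(1.05, 1.5, 3)) {
    for (k0 in c(0.1, 0.3, 0.8)) {
      y0 <- max(values[which.min(t)], 1e-3 * ymax)
      b0 <- max(log(A0 / y0), 0.1)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-b * exp(-k * t)), data = dat,
                          start = list(A = A0, b = b0, k = k0),
                          lower = c(A = 1e-8, b = 1e-8, k = 1e-8),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        sse <- sum(stats::residuals(fit)^2)
        if (sse < best_sse) { best <- fit; best_sse <- sse }
      }
    }
  }
  if (is.null(best))
    stop("Gompertz fit failed to converge from every start; ",
         "series may be incompatible with monotone growth", call. = FALSE)
  cf <- stats::coef(best)
  structure(list(coefficients = cf,
                 sigma = sqrt(best_sse / max(length(t) - 3, 1)),
                 fitted = stats::fitted(best), years = years,
                 t0 = min(years), nls = best),
            class = "gompertz_fit")
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Gompertz growth fit: y(t) = A exp(-b exp(-k t)), t = years since",
      x$t0, "\n")
  print(round(x$coefficients, digits))
  cat("Residual SD:", format(x$sigma, digits = digits), "on",
      length(x$years), "observations\n")
  invisible(x)
}

#' @export
predict.gompertz_fit <- function(object, years = object$years, ...) {
  cf <- unname(object$coefficients)
  gompertz_curve(years - object$t0, cf[1], cf[2], cf[3])
}

#' @export
plot.gompertz_fit <- function(x, extrapolate_to = NULL, ...) {
  yy <- x$years
  if (!is.null(extrapolate_to)) yy <- min(yy):extrapolate_to
  plot(x$years, x$fitted + stats::residuals(x$nls), xlab = "Year",
       ylab = "Density", xlim = range(yy), ...)
  graphics::lines(yy, predict(x, yy), lwd = 2, col = 2,
                  lty = ifelse(yy > max(x$years), 2, 1))
  invisible(x)
}

#' Cubic smoothing-spline trend with pointwise uncertainty
#'
#' Smooths a yearly series with a penalized cubic regression spline whose
#' smoothing parameter is chosen by generalized cross-validation
#' (via [mgcv::gam()]), returning fitted values and pointwise standard
#' errors for a ribbon. As the penalty grows the fit approaches the
#' least-squares straight line (the spline's null space).
#'
#' @param years Observation years (>= 4).
#' @param values Observations.
#' @param predict_years Years at which to evaluate the smooth (default the
#'   observed years).
#' @param sp Optional fixed smoothing parameter overriding GCV.
#' @return Data frame with columns `year`, `fit`, `se`, plus the `gam`
#'   object as attribute `"model"`.
#' @export
fit_trend_spline <- function(years, values, predict_years = NULL, sp = NULL) {
  if (length(years) < 4 || length(values) != length(years))
    stop("need at least 4 points for a spline trend", call. = FALSE)
  if (is.null(predict_years)) predict_years <- sort(unique(years))
  kk <- min(10, length(unique(years)) - 1)
  dat <- data.frame(year = years, y = values)
  m <- if (is.null(sp))
    mgcv::gam(y ~ s(year, k = kk, bs = "cr"), data = dat, method = "GCV.Cp")
  else
    mgcv::gam(y ~ s(year, k = kk, bs = "cr"), data = dat, sp = sp)
  pr <- mgcv::predict.gam(m, newdata = data.frame(year = predict_years),
                          se.fit = TRUE)
  out <- data.frame(year = predict_years, fit = as.numeric(pr$fit),
                    se = as.numeric(pr$se.fit))
  attr(out, "model") <- m
  out
}

#' Welch's unequal-variance t test
#'
#' Two-sided two-sample t test with the Welch-Satterthwaite degrees of
#' freedom, computed from first principles. The sign convention matches the
#' field reports the package emulates: `t` has the sign of
#' `mean(a) - mean(b)`, so an increase from period a to period b gives a
#' negative statistic.
#'
#' @param a,b Numeric samples (each n >= 2 with positive variance).
#' @param variable Optional label stored in the result.
#' @return List of class `"prepost_comparison"`: `variable`, `n`, `mean`,
#'   `sd` (two-element vectors), `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
welch_t_test <- function(a, b, variable = NA_character_) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 finite values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("zero-variance samples; the t statistic is undefined", call. = FALSE)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(variable = variable, n = c(a = na, b = nb),
                 mean = c(a = mean(a), b = mean(b)),
                 sd = c(a = stats::sd(a), b = stats::sd(b)),
                 t = tstat, df = df, p = p),
            class = "prepost_comparison")
}

#' @export
print.prepost_comparison <- function(x, digits = 4, ...) {
  if (!is.na(x$variable)) cat("Variable:", x$variable, "\n")
  cat(sprintf("  pre : n = %d, mean = %.3f, sd = %.3f\n",
              x$n[1], x$mean[1], x$sd[1]))
  cat(sprintf("  post: n = %d, mean = %.3f, sd = %.3f\n",
              x$n[2], x$mean[2], x$sd[2]))
  cat(sprintf("  Welch t = %.4f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Pre/post comparison of mussel distribution, size and cover
#'
#' Pools the survey observations into pre- and post-disturbance periods
#' (the cutoff year starts the post period), runs [welch_t_test()] for
#' distance-from-baseline, shell size and percent cover, and tabulates the
#' frequency distributions per period. Cover is compared on site-year
#' values; distances and sizes on pooled individual observations.
#'
#' @param surveys An `"intertidal_surveys"` object ([simulate_intertidal()]),
#'   or any list with `records`, `distances`, `sizes` data frames of the
#'   same shape.
#' @param cutoff First post-period year (default 2013).
#' @param pre_years Optional restriction of the pre period (e.g.
#'   `2009:2012`); default uses all years before the cutoff.
#' @return List of class `"prepost_summary"`: `comparisons` (named list of
#'   `"prepost_comparison"`), `tables` (per-variable pre/post histograms),
#'   `cutoff`.
#' @export
prepost_summary <- function(surveys, cutoff = 2013, pre_years = NULL) {
  recs <- surveys$records
  dist <- surveys$distances
  sizes <- surveys$sizes
  pick <- function(df) {
    pre <- if (is.null(pre_years)) df$year < cutoff else df$year %in% pre_years
    post <- df$year >= cutoff
    list(pre = pre, post = post)
  }
  if (!any(recs$year < cutoff) || !any(recs$year >= cutoff))
    stop("surveys must span both periods around the cutoff", call. = FALSE)
  sel_d <- pick(dist); sel_s <- pick(sizes); sel_c <- pick(recs)
  comparisons <- list(
    distance = welch_t_test(dist$distance_m[sel_d$pre],
                            dist$distance_m[sel_d$post], "distance_m"),
    size = welch_t_test(sizes$size_mm[sel_s$pre],
                        sizes$size_mm[sel_s$post], "size_mm"),
    cover = welch_t_test(recs$mussel_cover[sel_c$pre],
                         recs$mussel_cover[sel_c$post], "mussel_cover")
  )
  tab <- function(v, pre, post, breaks) {
    h_pre <- graphics::hist(v[pre], breaks = breaks, plot = FALSE)
    h_post <- graphics::hist(v[post], breaks = breaks, plot = FALSE)
    data.frame(mid = h_pre$mids, pre = h_pre$counts, post = h_post$counts)
  }
  all_d <- dist$distance_m; all_s <- sizes$size_mm; all_c <- recs$mussel_cover
  tables <- list(
    distance = tab(all_d, sel_d$pre, sel_d$post,
                   seq(0, max(all_d) + 2, by = 2)),
    size = tab(all_s, sel_s$pre, sel_s$post,
               seq(0, max(all_s) + 5, by = 5)),
    cover = tab(all_c, sel_c$pre, sel_c$post,
                seq(0, 100, by = 5))
  )
  structure(list(comparisons = comparisons, tables = tables, cutoff = cutoff),
            class = "prepost_summary")
}

#' @export
print.prepost_summary <- function(x, ...) {
  cat("Pre/post comparison (cutoff", x$cutoff, "):\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Pre/post summary of the census series
#'
#' Arithmetic mean and standard deviation of yearly independent-otter
#' counts before and from the cutoff year on; unsurveyed years are simply
#' absent and do not contribute.
#'
#' @param series A `"census_series"` data frame (columns `year`,
#'   `independents`).
#' @param cutoff First post-period year (default 2013).
#' @return Data frame with rows `pre` and `post` and columns `n`, `mean`,
#'   `sd`, `from`, `to`.
#' @export
census_prepost <- function(series, cutoff = 2013) {
  pre <- series$independents[series$year < cutoff]
  post <- series$independents[series$year >= cutoff]
  if (length(pre) == 0 || length(post) == 0)
    stop("both periods must contain census years", call. = FALSE)
  data.frame(
    period = c("pre", "post"),
    n = c(length(pre), length(post)),
    mean = c(mean(pre), mean(post)),
    sd = c(stats::sd(pre), stats::sd(post)),
    from = c(min(series$year[series$year < cutoff]), cutoff),
    to = c(max(series$year[series$year < cutoff]), max(series$year)),
    row.names = c("pre", "post")
  )
}

#' Sea star trend: Gompertz fit, extrapolation and post-collapse spline
#'
#' Mirrors the three-piece treatment of the sea star series: a Gompertz
#' growth fit to the early surveyed years, extrapolation of that trend over
#' an unsurveyed gap, and a cubic spline through the post-collapse years.
#'
#' @param surveys An `"intertidal_surveys"` object.
#' @param fit_years Years used for the Gompertz fit (default 2001-2007).
#' @param gap_years Years filled by extrapolation (default 2008-2012).
#' @param collapse_year First post-collapse year (default 2013).
#' @return List with elements `gompertz` (`"gompertz_fit"`),
#'   `extrapolation` (data frame year/fit), `post_spline` (data frame
#'   year/fit/se), `yearly` (observed site-mean density per year).
#' @export
pisaster_trend <- function(surveys, fit_years = 2001:2007,
                           gap_years = 2008:2012, collapse_year = 2013) {
  recs <- surveys$records
  yearly <- stats::aggregate(pisaster_density ~ year, data = recs, FUN = mean)
  pre <- yearly[yearly$year %in% fit_years, ]
  gf <- fit_gompertz(pre$year, pre$pisaster_density)
  extr <- data.frame(year = gap_years, fit = predict(gf, gap_years))
  post <- yearly[yearly$year >= collapse_year, ]
  post_spline <- if (nrow(post) >= 4)
    fit_trend_spline(post$year, post$pisaster_density) else NULL
  list(gompertz = gf, extrapolation = extr, post_spline = post_spline,
       yearly = yearly)
}
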