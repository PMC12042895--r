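# One-command orchestration: synthetic data -> Dirichlet precision pre-fit
# -> model fit -> counterfactual scenarios -> intertidal/census trends ->
# report.

#' Configuration for [run_pipeline()]
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param truth A [truth_config()].
#' @param n_draws Foraging-survey posterior draws per year.
#' @param control A [forage_control()].
#' @param intertidal An [intertidal_config()].
#' @param census A [census_config()].
#' @param ssw_year Disturbance (wasting event) year used for pre/post
#'   splits (default 2013).
#' @param scenario_cutoff Last observed-dynamics year for scenarios
#'   (default 2012).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            truth = truth_config(),
                            n_draws = 1000,
                            control = forage_control(),
                            intertidal = intertidal_config(),
                            census = census_config(),
                            ssw_year = 2013,
                            scenario_cutoff = 2012) {
  structure(list(seed = seed, truth = truth, n_draws = n_draws,
                 control = control, intertidal = intertidal,
                 census = census, ssw_year = ssw_year,
                 scenario_cutoff = scenario_cutoff),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic data set, pre-computes per-year Dirichlet
#' precisions, fits the foraging model, resolves the four standard
#' counterfactual scenarios, runs the intertidal and census trend stage,
#' and writes tidy CSV outputs, figure panels and a plain-text report into
#' `out_dir`. Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @param figures Write PNG figure panels (default TRUE).
#' @return Invisibly, a list with the main in-memory objects: `truth`,
#'   `obs`, `fit`, `scenarios`, `prepost`, `census_summary`, `summary`
#'   (the headline contrast table), `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, figures = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) stop("'out_dir' is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- c(
    paste("pipeline seed:", seed),
    paste("prior scales: mu", config$control$prior_mu_scale,
          "| sigma", config$control$prior_sigma_scale,
          "| Delta1 N(", config$control$delta1_mean, ",",
          config$control$delta1_sd, ")"),
    paste("ssw_year:", config$ssw_year,
          "scenario_cutoff:", config$scenario_cutoff))

  # 1. synthetic data
  truth <- stage("simulate", generate_ground_truth(config$truth, seed = seed))
  obs <- stage("simulate",
               simulate_sofa_outputs(truth, n_draws = config$n_draws,
                                     seed = seed + 1L))
  surveys <- stage("simulate",
                   simulate_intertidal(config$intertidal, seed = seed + 2L))
  census <- stage("simulate", simulate_census(config$census, seed = seed + 3L))
  data_dir <- file.path(out_dir, "data")
  files <- stage("simulate",
                 write_synthetic_data(truth, obs, surveys, census, data_dir))

  # 2. Dirichlet precision pre-fit
  tau <- stage("precision", vapply(obs$eta_draws, function(m)
    as.numeric(dirichlet_precision(m)), numeric(1)))
  tau_df <- data.frame(year = obs$years, tau = tau)
  utils::write.csv(tau_df, file.path(out_dir, "dirichlet_precision.csv"),
                   row.names = FALSE)

  # 3. model fit
  fit <- stage("fit", forage_fit(obs, config$control, tau = tau,
                                 seed = seed + 4L))
  post_sum <- summary(fit)
  utils::write.csv(
    data.frame(prey_id = rownames(post_sum$E), post_sum$E, row.names = NULL),
    file.path(out_dir, "posterior_profitabilities.csv"), row.names = FALSE)
  utils::write.csv(fit$diagnostics,
                   file.path(out_dir, "fit_diagnostics.csv"), row.names = FALSE)
  al <- predict(fit, type = "allocation")
  utils::write.csv(al, file.path(out_dir, "posterior_allocation.csv"),
                   row.names = FALSE)

  # 4. scenarios
  iv <- prey_item_values(truth$prey, obs)
  specs <- standard_scenarios(cutoff_year = config$scenario_cutoff,
                              reference_years =
                                max(min(truth$years), 2007):config$scenario_cutoff,
                              seed = seed + 5L)
  scen <- stage("scenarios",
                lapply(specs, function(sp) resolve_scenario(fit, sp, iv)))
  st <- scenario_table(scen)
  utils::write.csv(st, file.path(out_dir, "scenario_results.csv"),
                   row.names = FALSE)

  # 5. intertidal + census trends
  prepost <- stage("intertidal", prepost_summary(surveys, cutoff = config$ssw_year))
  ptrend <- stage("intertidal", pisaster_trend(
    surveys,
    fit_years = min(surveys$records$year):2007,
    collapse_year = config$ssw_year))
  cover_yearly <- stats::aggregate(mussel_cover ~ year, data = surveys$records,
                                   FUN = mean)
  cover_spline <- fit_trend_spline(cover_yearly$year, cover_yearly$mussel_cover)
  census_summary <- stage("census", census_prepost(census, cutoff = config$ssw_year))
  cmp_df <- do.call(rbind, lapply(prepost$comparisons, function(cc)
    data.frame(variable = cc$variable, n_pre = cc$n[1], n_post = cc$n[2],
               mean_pre = cc$mean[1], mean_post = cc$mean[2],
               sd_pre = cc$sd[1], sd_post = cc$sd[2],
               t = cc$t, df = cc$df, p = cc$p, row.names = NULL)))
  utils::write.csv(cmp_df, file.path(out_dir, "intertidal_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(census_summary, file.path(out_dir, "census_prepost.csv"),
                   row.names = FALSE)

  # 6. headline contrasts
  years <- fit$data$years
  pre_y <- years < config$ssw_year; post_y <- years >= config$ssw_year
  eta_hat <- fitted(fit)  # T x K
  eff <- function(pid, idx) mean(eta_hat[idx, pid])
  mussel_fold <- eff("mussel", post_y) / eff("mussel", pre_y)
  en <- scen$baseline$energy
  summary_tab <- data.frame(
    quantity = c("mussel_effort_pre", "mussel_effort_post",
                 "mussel_effort_fold_change",
                 "urchin_effort_pre", "urchin_effort_post",
                 "energy_intake_pre", "energy_intake_post",
                 "census_pre_mean", "census_post_mean",
                 "mussel_cover_pre", "mussel_cover_post",
                 "mussel_size_pre_mm", "mussel_size_post_mm",
                 "mussel_distance_pre_m", "mussel_distance_post_m"),
    value = c(eff("mussel", pre_y), eff("mussel", post_y), mussel_fold,
              eff("urchin", pre_y), eff("urchin", post_y),
              mean(en$mean[pre_y]), mean(en$mean[post_y]),
              census_summary["pre", "mean"], census_summary["post", "mean"],
              prepost$comparisons$cover$mean[1],
              prepost$comparisons$cover$mean[2],
              prepost$comparisons$size$mean[1],
              prepost$comparisons$size$mean[2],
              prepost$comparisons$distance$mean[1],
              prepost$comparisons$distance$mean[2]))
  utils::write.csv(summary_tab, file.path(out_dir, "summary_contrasts.csv"),
                   row.names = FALSE)

  # figures
  if (figures) {
    fig <- function(name, w, h, expr) {
      grDevices::png(file.path(out_dir, name), width = w, height = h,
                     res = 110)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr
    }
    fig("fig_effort_allocation.png", 800, 500,
        plot(fit, prey = intersect(c("urchin", "mussel"), fit$data$prey_id),
             ref_year = config$ssw_year,
             main = "Foraging effort allocation"))
    fig("fig_scenarios.png", 900, 600, {
      graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
      for (nm in c("no_urchin_increase", "no_mussel_increase", "neither")) {
        plot_scenarios(scen[c("baseline", nm)], ref_year = config$ssw_year,
                       main = nm)
      }
      plot_scenarios(scen["baseline"], ref_year = config$ssw_year,
                     main = "baseline")
    })
    fig("fig_intertidal_trends.png", 900, 400, {
      graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
      plot(cover_yearly$year, cover_yearly$mussel_cover, xlab = "Year",
           ylab = "Mussel cover (%)", main = "Mussel cover")
      graphics::polygon(c(cover_spline$year, rev(cover_spline$year)),
                        c(cover_spline$fit - cover_spline$se,
                          rev(cover_spline$fit + cover_spline$se)),
                        col = grDevices::adjustcolor(4, 0.2), border = NA)
      graphics::lines(cover_spline$year, cover_spline$fit, col = 4, lwd = 2)
      graphics::abline(v = config$ssw_year, lty = 3)
      yearly <- ptrend$yearly
      plot(yearly$year, yearly$pisaster_density, xlab = "Year",
           ylab = "Sea star density", main = "Pisaster")
      graphics::lines(ptrend$gompertz$years,
                      predict(ptrend$gompertz), col = 2, lwd = 2)
      graphics::lines(ptrend$extrapolation$year, ptrend$extrapolation$fit,
                      col = "grey40", lwd = 2, lty = 2)
      if (!is.null(ptrend$post_spline))
        graphics::lines(ptrend$post_spline$year, ptrend$post_spline$fit,
                        col = 4, lwd = 2)
      graphics::abline(v = config$ssw_year, lty = 3)
    })
  }

  # report
  rpt <- c(
    "# Pipeline report", "",
    log_lines, "",
    "## Fit", utils::capture.output(print(fit)), "",
    "## Headline contrasts",
    utils::capture.output(print(summary_tab, row.names = FALSE)), "",
    "## Intertidal pre/post comparisons",
    utils::capture.output(print(prepost)), "",
    "## Census",
    utils::capture.output(print(census_summary)))
  writeLines(rpt, file.path(out_dir, "report.md"))

  invisible(list(truth = truth, obs = obs, fit = fit, scenarios = scen,
                 prepost = prepost, census_summary = census_summary,
                 pisaster = ptrend, summary = summary_tab,
                 files = list.files(out_dir, recursive = TRUE)))
}
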