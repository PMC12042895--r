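# Counterfactual prey-dynamics scenarios and bioenergetic derived outputs.

#' Specify a counterfactual prey-dynamics scenario
#'
#' In an alternative scenario, the post-cutoff effective densities of the
#' "frozen" prey types are replaced, per posterior draw, by i.i.d. normal
#' draws whose mean and variance come from that draw's reference-period
#' estimates — i.e. the prey's density remains within its pre-disturbance
#' range. All other prey vary as estimated.
#'
#' @param name Scenario label. The conventional four are `"baseline"`
#'   (nothing frozen), `"no_urchin_increase"`, `"no_mussel_increase"` and
#'   `"neither"`.
#' @param frozen_prey Character vector of prey ids to freeze (empty for the
#'   baseline).
#' @param cutoff_year Last year of observed dynamics; densities after this
#'   year are resampled for frozen prey. Default 2012.
#' @param reference_years Years whose estimates supply the replacement mean
#'   and variance. Default 2007-2012.
#' @param seed Seed for the replacement draws.
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name = "baseline", frozen_prey = character(0),
                          cutoff_year = 2012,
                          reference_years = 2007:2012, seed = 1) {
  if (length(reference_years) == 0 || any(reference_years > cutoff_year))
    stop("'reference_years' must be non-empty and precede the cutoff",
         call. = FALSE)
  structure(list(name = name, frozen_prey = unique(frozen_prey),
                 cutoff_year = cutoff_year,
                 reference_years = reference_years, seed = seed),
            class = "scenario_spec")
}

#' The four standard scenarios
#'
#' @param cutoff_year,reference_years,seed See [scenario_spec()].
#' @return Named list of four [scenario_spec()] objects.
#' @export
standard_scenarios <- function(cutoff_year = 2012,
                               reference_years = 2007:2012, seed = 1) {
  list(
    baseline = scenario_spec("baseline", character(0), cutoff_year,
                             reference_years, seed),
    no_urchin_increase = scenario_spec("no_urchin_increase", "urchin",
                                       cutoff_year, reference_years, seed),
    no_mussel_increase = scenario_spec("no_mussel_increase", "mussel",
                                       cutoff_year, reference_years, seed),
    neither = scenario_spec("neither", c("urchin", "mussel"), cutoff_year,
                            reference_years, seed)
  )
}

#' Per-item prey energy values with propagated variance
#'
#' The mean energy value of one consumed item,
#' `G = caloric_density * a * size^b`, evaluated at the mean size for the
#' point value, and per-draw using the size and caloric-density draws of
#' the foraging-survey emulation so that variance in G propagates into
#' predation rates.
#'
#' @param prey Prey profile data frame ([default_prey_profiles()]).
#' @param obs Optional `"observed_foraging"` with `size_draws`/`cal_draws`;
#'   when omitted, draw-level values collapse to the point value.
#' @return List of class `"prey_item_values"`: `G` (named point values,
#'   kcal/item) and `G_draws` (`n_draws x K`).
#' @export
prey_item_values <- function(prey, obs = NULL) {
  validate_prey_profiles(prey)
  biomass <- prey$biomass_coef_a * prey$size_mean_mm^prey$biomass_exp_b
  G <- stats::setNames(prey$caloric_density * biomass, prey$prey_id)
  if (any(G <= 0)) stop("per-item energy values must be positive", call. = FALSE)
  if (!is.null(obs)) {
    b_draws <- sweep(obs$size_draws^rep(prey$biomass_exp_b,
                                        each = nrow(obs$size_draws)),
                     2, prey$biomass_coef_a, "*")
    G_draws <- obs$cal_draws * b_draws
  } else {
    G_draws <- matrix(G, 1, length(G), dimnames = list(NULL, prey$prey_id))
  }
  structure(list(G = G, G_draws = G_draws), class = "prey_item_values")
}

#' Counterfactual replacement of post-cutoff density draws
#'
#' For each posterior draw and each frozen prey, log effective densities in
#' years after the cutoff are replaced by i.i.d. normal draws with the mean
#' and standard deviation of that draw's reference-year values. Draw-level
#' coherence is preserved: replacements use the same posterior draw's
#' reference estimates, not cross-draw summaries.
#'
#' @param fit A `"forage_fit"`.
#' @param spec A [scenario_spec()].
#' @return An `S x K x T` array of adjusted `Delta` draws.
#' @export
counterfactual_densities <- function(fit, spec) {
  stopifnot(inherits(fit, "forage_fit"), inherits(spec, "scenario_spec"))
  Delta <- fit$draws$Delta
  if (length(spec$frozen_prey) == 0) return(Delta)
  years <- fit$data$years
  miss <- setdiff(spec$frozen_prey, fit$data$prey_id)
  if (length(miss) > 0)
    stop("scenario references unfitted prey: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ref_idx <- match(intersect(spec$reference_years, years), years)
  if (length(ref_idx) == 0)
    stop("no reference years inside the fitted range", call. = FALSE)
  post_idx <- which(years > spec$cutoff_year)
  if (length(post_idx) == 0) return(Delta)
  set.seed(spec$seed)
  S <- dim(Delta)[1]
  for (pid in spec$frozen_prey) {
    i <- match(pid, fit$data$prey_id)
    ref <- Delta[, i, ref_idx, drop = FALSE]
    m <- apply(ref, 1, mean)
    s <- apply(ref, 1, stats::sd)
    repl <- matrix(stats::rnorm(S * length(post_idx), mean = m, sd = s),
                   S, length(post_idx))
    Delta[, i, post_idx] <- repl
  }
  Delta
}

#' Resolve a counterfactual scenario
#'
#' Re-solves the optimal-foraging process model for every posterior draw
#' under the scenario's adjusted densities: patch encounter probabilities,
#' joint choice probabilities and effort allocations are recomputed from
#' the adjusted `Delta`, then the yearly mean energy intake and per-prey
#' predation rates are summarised across draws with credible intervals.
#' The baseline scenario takes no resampling path and reproduces the
#' fitted quantities exactly.
#'
#' @param fit A `"forage_fit"`.
#' @param spec A [scenario_spec()].
#' @param item_values A [prey_item_values()] covering the fitted prey
#'   (needed for predation rates; optional).
#' @param prob Credible mass (default 0.95).
#' @param normalized Energy intake and predation rates weight
#'   profitabilities by the unnormalized joint encounter probabilities
#'   (default FALSE): the expected energy per dive-minute counting dives
#'   that encounter no suitable patch, which is the rate an intake-
#'   maximizing forager maximizes and the form under which density
#'   reductions are monotone. Set TRUE to condition on encountering
#'   a patch (simplex-normalized weights).
#' @return A list of class `"scenario_result"`: `name`, `energy` (data
#'   frame year/mean/lo/hi), `predation` (data frame prey_id/year/mean/lo/
#'   hi), `allocation` (data frame prey_id/year/mean/lo/hi), and
#'   `Ebar_draws` (S x T matrix).
#' @export
resolve_scenario <- function(fit, spec, item_values = NULL, prob = 0.95,
                             normalized = FALSE) {
  stopifnot(inherits(fit, "forage_fit"), inherits(spec, "scenario_spec"))
  Delta <- counterfactual_densities(fit, spec)
  S <- dim(Delta)[1]; K <- dim(Delta)[2]; Tn <- dim(Delta)[3]
  years <- fit$data$years; prey_id <- fit$data$prey_id
  tt <- fit$control$tie_tol
  eta <- array(NA_real_, c(S, K, Tn))   # normalized effort shares
  wgt <- array(NA_real_, c(S, K, Tn))   # weights for energy/predation
  Ebar <- matrix(NA_real_, S, Tn)
  for (s in seq_len(S)) {
    lam <- -expm1(-exp(Delta[s, , ]))
    piM <- .alloc_pi(exp(fit$draws$mu[s, ]), lam, tt)
    eta[s, , ] <- sweep(piM, 2, colSums(piM), "/")
    wgt[s, , ] <- if (normalized) eta[s, , ] else piM
    Ebar[s, ] <- colSums(wgt[s, , ] * exp(fit$draws$mu[s, ]))
  }
  a <- (1 - prob) / 2
  energy <- data.frame(year = years, mean = colMeans(Ebar),
                       lo = apply(Ebar, 2, stats::quantile, a),
                       hi = apply(Ebar, 2, stats::quantile, 1 - a),
                       row.names = NULL)
  alloc <- expand.grid(prey_id = prey_id, year = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alloc$mean <- as.vector(apply(eta, c(2, 3), mean))
  alloc$lo <- as.vector(apply(eta, c(2, 3), stats::quantile, a))
  alloc$hi <- as.vector(apply(eta, c(2, 3), stats::quantile, 1 - a))
  predation <- NULL
  if (!is.null(item_values)) {
    stopifnot(inherits(item_values, "prey_item_values"))
    Gd <- item_values$G_draws
    if (!all(prey_id %in% colnames(Gd)))
      stop("item values do not cover all fitted prey", call. = FALSE)
    Gd <- Gd[, prey_id, drop = FALSE]
    gi <- ((seq_len(S) - 1) %% nrow(Gd)) + 1  # pair draws cyclically
    P <- array(NA_real_, c(S, K, Tn))
    Emat <- exp(fit$draws$mu)
    for (s in seq_len(S))
      P[s, , ] <- wgt[s, , ] * Emat[s, ] / Gd[gi[s], ]
    predation <- expand.grid(prey_id = prey_id, year = years,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    predation$mean <- as.vector(apply(P, c(2, 3), mean))
    predation$lo <- as.vector(apply(P, c(2, 3), stats::quantile, a))
    predation$hi <- as.vector(apply(P, c(2, 3), stats::quantile, 1 - a))
  }
  structure(list(name = spec$name, spec = spec, energy = energy,
                 allocation = alloc, predation = predation,
                 Ebar_draws = Ebar),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (length(x$spec$frozen_prey))
    cat("  frozen prey:", paste(x$spec$frozen_prey, collapse = ", "),
        " (post-", x$spec$cutoff_year, " densities resampled from ",
        min(x$spec$reference_years), "-", max(x$spec$reference_years),
        ")\n", sep = "")
  cat("Yearly mean energy intake (kcal/min):\n")
  print(round(utils::head(x$energy, 20), 3))
  invisible(x)
}

#' Tidy comparison table across scenarios
#'
#' @param results List of `"scenario_result"` objects.
#' @return Data frame with columns `scenario`, `year`, `statistic`, `mean`,
#'   `lo95`, `hi95` (energy intake plus per-prey predation rates when
#'   available).
#' @export
scenario_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    out <- data.frame(scenario = r$name, year = r$energy$year,
                      statistic = "energy_intake",
                      mean = r$energy$mean, lo95 = r$energy$lo,
                      hi95 = r$energy$hi, row.names = NULL)
    if (!is.null(r$predation)) {
      p <- data.frame(scenario = r$name, year = r$predation$year,
                      statistic = paste0("predation_rate:", r$predation$prey_id),
                      mean = r$predation$mean, lo95 = r$predation$lo,
                      hi95 = r$predation$hi, row.names = NULL)
      out <- rbind(out, p)
    }
    out
  }))
}

#' Plot energy-intake trajectories under alternative scenarios
#'
#' Line plus credible ribbon per scenario, with an optional disturbance
#' reference year.
#'
#' @param results List of `"scenario_result"` objects (the first is drawn
#'   as the reference band).
#' @param ref_year Vertical dotted reference line (default 2013).
#' @param ... Passed to [plot()].
#' @export
plot_scenarios <- function(results, ref_year = 2013, ...) {
  stopifnot(length(results) >= 1)
  years <- results[[1]]$energy$year
  rng <- range(unlist(lapply(results, function(r) c(r$energy$lo, r$energy$hi))))
  plot(range(years), rng, type = "n", xlab = "Year",
       ylab = "Energy intake (kcal/min)", ...)
  cols <- seq_along(results) + 1
  for (j in seq_along(results)) {
    e <- results[[j]]$energy
    graphics::polygon(c(e$year, rev(e$year)), c(e$lo, rev(e$hi)),
                      col = grDevices::adjustcolor(cols[j], 0.2), border = NA)
    graphics::lines(e$year, e$mean, col = cols[j], lwd = 2)
  }
  if (!is.null(ref_year)) graphics::abline(v = ref_year, lty = 3)
  graphics::legend("topright", legend = vapply(results, `[[`, "", "name"),
                   col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(results)
}
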