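# Synthetic-data module: ground-truth prey dynamics, foraging-survey style
# posterior outputs, rocky intertidal surveys and census counts.

#' Default prey profiles
#'
#' Eleven prey-type profiles used throughout the package as the default
#' study configuration. The taxa labels are placeholders for the prey
#' categories typically distinguished in sea otter foraging work (urchin,
#' mussel, abalone, cancrid crab, kelp crab, clam, snail, sea star,
#' cephalopod, worm, other); profitabilities, caloric densities and
#' size-biomass coefficients are configurable stand-ins with realistic
#' magnitudes, not published values.
#'
#' `mu` is the log of the expected energy-intake rate E (kcal/min) while
#' feeding within a suitable patch. Edible biomass (g) at size s (mm) is
#' `biomass_coef_a * s^biomass_exp_b`, and the per-item energy value is
#' `G = caloric_density * biomass` evaluated at the mean size.
#'
#' @return A data frame with one row per prey type and columns `prey_id`,
#'   `mu`, `caloric_density`, `size_mean_mm`, `size_sd_mm`,
#'   `biomass_coef_a`, `biomass_exp_b`.
#' @export
default_prey_profiles <- function() {
  p <- data.frame(
    prey_id = c("urchin", "mussel", "abalone", "cancrid_crab", "kelp_crab",
                "clam", "snail", "sea_star", "cephalopod", "worm", "other"),
    mu = log(c(7, 5, 18, 16, 11, 8, 3.5, 10, 14, 2.5, 2)),
    caloric_density = c(0.9, 0.8, 1.2, 0.9, 0.8, 0.8, 0.8, 0.5, 1.0, 0.7, 0.8),
    size_mean_mm = c(60, 55, 120, 110, 70, 70, 30, 150, 150, 200, 50),
    size_sd_mm = c(15, 12, 25, 20, 15, 15, 8, 40, 50, 60, 20),
    biomass_coef_a = 6e-4,
    biomass_exp_b = 2.7,
    stringsAsFactors = FALSE
  )
  validate_prey_profiles(p)
  p
}

validate_prey_profiles <- function(prey) {
  stopifnot(is.data.frame(prey))
  need <- c("prey_id", "mu", "caloric_density", "size_mean_mm", "size_sd_mm",
            "biomass_coef_a", "biomass_exp_b")
  if (!all(need %in% names(prey)))
    stop("prey profiles must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(prey$prey_id))
    stop("'prey_id' must be unique", call. = FALSE)
  if (any(!is.finite(prey$mu)))
    stop("'mu' must be finite (E = exp(mu) > 0)", call. = FALSE)
  if (any(prey$caloric_density <= 0) || any(prey$biomass_exp_b <= 0))
    stop("caloric densities and biomass exponents must be positive",
         call. = FALSE)
  invisible(prey)
}

#' Configuration for the synthetic ground truth
#'
#' Defines the prey community, study years, process/observation scales and
#' regime shifts of the simulated system. The defaults encode the study
#' conditions emulated by the package: eleven prey types whose pre-period
#' effort allocation puts about 17% of dives on urchins and 7% on mussels; a
#' step increase in urchin effective density in 2014 (a fast behavioural
#' shift); a four-year ramp increase in mussel density from 2016 (a slow
#' demographic shift following mesopredator collapse); and a three-year ramp
#' decline of the five most profitable prey types from 2014. The shift
#' magnitudes are chosen so that the yearly total patch-encounter
#' probability stays near its base value while the post-period effort
#' shares move to roughly a fifth of dives on mussels and a third on
#' urchins.
#'
#' Base log effective densities are derived from `eta_pre` (the target
#' pre-period effort allocation) by sequentially inverting the optimal
#' allocation map with total per-dive encounter probability `encounter_total`.
#'
#' @param prey Prey profile data frame; see [default_prey_profiles()].
#' @param years Integer vector of consecutive study years.
#' @param sigma_D Per-prey random-walk innovation scale for the log
#'   effective densities (recycled to the number of prey).
#' @param sigma_E Per-prey observation scale for log intake rates.
#' @param tau Per-year Dirichlet precision of observed effort compositions
#'   (recycled to the number of years).
#' @param eta_pre Target pre-period effort allocation used to locate the
#'   base densities; must be a probability vector, one entry per prey.
#' @param encounter_total Probability that a dive encounters at least one
#'   suitable patch in the base (pre-shift) state.
#' @param regime_shifts Data frame with columns `prey_id`, `start_year`,
#'   `ramp_years` (1 = step change), `log_increase` (may be negative).
#' @param missing_frac Fraction of prey-year intake observations set to
#'   missing (rarely observed prey); default 0.
#' @return A list of class `"truth_config"`.
#' @export
truth_config <- function(prey = default_prey_profiles(),
                         years = 2007:2024,
                         sigma_D = 0.10,
                         sigma_E = 0.10,
                         tau = 300,
                         eta_pre = c(0.172, 0.069, 0.12, 0.13, 0.10,
                                     0.11, 0.06, 0.07, 0.08, 0.04, 0.049),
                         encounter_total = 0.8,
                         regime_shifts = default_regime_shifts(),
                         missing_frac = 0) {
  validate_prey_profiles(prey)
  K <- nrow(prey)
  if (K < 2) stop("need at least 2 prey types", call. = FALSE)
  if (length(years) < 2 || any(diff(years) != 1L))
    stop("'years' must be consecutive calendar years", call. = FALSE)
  sigma_D <- rep_len(sigma_D, K); sigma_E <- rep_len(sigma_E, K)
  tau <- rep_len(tau, length(years))
  if (any(sigma_D < 0) || any(sigma_E < 0) || any(tau <= 0))
    stop("scales must be non-negative and 'tau' positive", call. = FALSE)
  if (length(eta_pre) != K || any(eta_pre <= 0))
    stop("'eta_pre' must be a positive vector with one entry per prey",
         call. = FALSE)
  eta_pre <- eta_pre / sum(eta_pre)
  if (encounter_total <= 0 || encounter_total >= 1)
    stop("'encounter_total' must be in (0, 1)", call. = FALSE)
  if (nrow(regime_shifts) > 0) {
    if (!all(regime_shifts$prey_id %in% prey$prey_id))
      stop("regime shift prey_id not found in prey profiles", call. = FALSE)
    if (any(regime_shifts$start_year < min(years)) ||
        any(regime_shifts$start_year > max(years)))
      stop("regime shift years fall outside the study years", call. = FALSE)
    if (any(regime_shifts$ramp_years < 1))
      stop("'ramp_years' must be >= 1", call. = FALSE)
  }
  if (missing_frac < 0 || missing_frac >= 1)
    stop("'missing_frac' must be in [0, 1)", call. = FALSE)
  structure(list(prey = prey, years = years, sigma_D = sigma_D,
                 sigma_E = sigma_E, tau = tau, eta_pre = eta_pre,
                 encounter_total = encounter_total,
                 regime_shifts = regime_shifts,
                 missing_frac = missing_frac),
            class = "truth_config")
}

#' @rdname truth_config
#' @export
default_regime_shifts <- function() {
  data.frame(
    prey_id = c("urchin", "mussel", "abalone", "cancrid_crab", "kelp_crab",
                "sea_star", "cephalopod"),
    start_year = c(2014, 2016, 2014, 2014, 2014, 2014, 2014),
    ramp_years = c(1, 4, 3, 3, 3, 3, 3),
    log_increase = c(0.4, 1.4, -1.2, -1.2, -1.2, -1.2, -1.2),
    stringsAsFactors = FALSE
  )
}

# Invert the allocation map: given a target effort allocation and the total
# encounter probability s, solve for per-prey lambda in profitability order.
invert_allocation <- function(eta_target, mu, s = 0.8, lambda_max = 0.98) {
  K <- length(eta_target)
  ord <- order(mu, decreasing = TRUE)
  lam <- numeric(K); Q <- 1
  for (i in ord) {
    lam[i] <- min(lambda_max, max(1e-5, s * eta_target[i] / Q))
    Q <- Q * (1 - lam[i])
  }
  lam
}

#' Generate the synthetic ground truth
#'
#' Simulates the latent state of the system: per-prey log effective density
#' trajectories \eqn{\Delta_{i,t}} as Gaussian random walks around a base
#' state located by inverting the target pre-period allocation, plus the
#' deterministic regime-shift offsets configured in `config`.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A list of class `"forage_truth"` with elements `prey`, `years`,
#'   `Delta` (K x T matrix of log effective densities), `Delta_base`,
#'   `shift_offset`, `sigma_D`, `sigma_E`, `tau`, `eta` (true per-year
#'   allocation, K x T), `Ebar` (true yearly mean per-dive energy intake
#'   rate, unnormalized; see [mean_energy_intake()]), `config` and `seed`.
#' @examples
#' tr <- generate_ground_truth(truth_config(), seed = 1)
#' dim(tr$Delta)
#' @export
generate_ground_truth <- function(config = truth_config(), seed = 1) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(seed)
  prey <- config$prey; years <- config$years
  K <- nrow(prey); Tn <- length(years)
  mu <- prey$mu
  lam0 <- invert_allocation(config$eta_pre, mu, s = config$encounter_total)
  Delta_base <- matrix(log(-log1p(-lam0)), K, Tn,
                       dimnames = list(prey$prey_id, years))
  # deterministic regime-shift offsets (linear ramp over ramp_years)
  offset <- matrix(0, K, Tn, dimnames = dimnames(Delta_base))
  rs <- config$regime_shifts
  if (nrow(rs) > 0) {
    for (r in seq_len(nrow(rs))) {
      i <- match(rs$prey_id[r], prey$prey_id)
      frac <- pmin(pmax((years - rs$start_year[r] + 1) / rs$ramp_years[r], 0), 1)
      offset[i, ] <- offset[i, ] + frac * rs$log_increase[r]
    }
  }
  # Gaussian random walk innovations
  walk <- matrix(0, K, Tn)
  for (i in seq_len(K))
    walk[i, ] <- cumsum(stats::rnorm(Tn, 0, config$sigma_D[i]))
  Delta <- Delta_base + offset + walk
  lam <- encounter_probability(exp(Delta))
  piM <- .alloc_pi(exp(mu), lam)
  eta <- sweep(piM, 2, colSums(piM), "/")
  Ebar <- colSums(piM * exp(mu))  # per-dive expected energy, empty dives included
  structure(list(prey = prey, years = years, Delta = Delta,
                 Delta_base = Delta_base, shift_offset = offset,
                 sigma_D = config$sigma_D, sigma_E = config$sigma_E,
                 tau = config$tau, eta = eta, Ebar = Ebar,
                 config = config, seed = seed),
            class = "forage_truth")
}

#' @export
print.forage_truth <- function(x, ...) {
  cat("Synthetic foraging ground truth:", nrow(x$prey), "prey types,",
      length(x$years), "years (", min(x$years), "-", max(x$years), ")\n")
  cat("sigma_D:", paste(unique(x$sigma_D), collapse = ", "),
      " sigma_E:", paste(unique(x$sigma_E), collapse = ", "),
      " tau:", paste(unique(x$tau), collapse = ", "), "\n")
  if (nrow(x$config$regime_shifts) > 0) {
    cat("Regime shifts:\n"); print(x$config$regime_shifts)
  }
  invisible(x)
}

#' Simulate foraging-survey style posterior outputs
#'
#' Emulates the bias-corrected posterior summaries produced by a prior
#' sea otter foraging analysis: for each year, effort-allocation posterior
#' draws are Dirichlet around the true optimal allocation with the year's
#' precision, observed per-prey log intake rates are normal around the true
#' log profitabilities, and per-prey size and caloric-density draws are
#' provided for propagating variance in per-item energy values.
#'
#' @param truth A `"forage_truth"` from [generate_ground_truth()].
#' @param n_draws Posterior draws per year (>= 100).
#' @param seed Integer seed.
#' @return A list of class `"observed_foraging"`: `eta_draws` (list of
#'   `n_draws x K` matrices, one per year), `eta_obs` (T x K matrix of
#'   per-year posterior means), `mu_obs` (K x T, NA where unobserved),
#'   `size_draws`, `cal_draws` (`n_draws x K`), `prey`, `years`, `seed`.
#' @export
simulate_sofa_outputs <- function(truth, n_draws = 1000, seed = 1) {
  stopifnot(inherits(truth, "forage_truth"))
  if (n_draws < 100) stop("'n_draws' must be at least 100", call. = FALSE)
  set.seed(seed)
  prey <- truth$prey; years <- truth$years
  K <- nrow(prey); Tn <- length(years)
  lam <- encounter_probability(exp(truth$Delta))
  piM <- .alloc_pi(exp(prey$mu), lam)
  if (any(!is.finite(piM)) || any(piM < 0))
    stop("invalid allocation probabilities computed from truth", call. = FALSE)
  eta_true <- sweep(piM, 2, colSums(piM), "/")
  tau <- rep_len(truth$tau, Tn)
  eta_draws <- vector("list", Tn); names(eta_draws) <- years
  for (t in seq_len(Tn)) {
    eta_draws[[t]] <- rdirichlet(n_draws, tau[t] * eta_true[, t])
    colnames(eta_draws[[t]]) <- prey$prey_id
  }
  eta_obs <- t(vapply(eta_draws, colMeans, numeric(K)))
  dimnames(eta_obs) <- list(years, prey$prey_id)
  mu_obs <- matrix(stats::rnorm(K * Tn, prey$mu, truth$sigma_E), K, Tn,
                   dimnames = list(prey$prey_id, years))
  mf <- truth$config$missing_frac
  if (mf > 0) {
    drop <- which(stats::runif(K * Tn) < mf)
    mu_obs[drop] <- NA_real_
  }
  size_draws <- matrix(stats::rnorm(n_draws * K, rep(prey$size_mean_mm, each = n_draws),
                                    rep(prey$size_sd_mm, each = n_draws)),
                       n_draws, K, dimnames = list(NULL, prey$prey_id))
  # truncate below at a third of the mean size: consumed items of a prey
  # type do not shrink to zero, and per-item energy must stay bounded away
  # from zero for the predation-rate propagation
  size_draws <- pmax(size_draws,
                     matrix(prey$size_mean_mm / 3, n_draws, K, byrow = TRUE))
  cal_draws <- matrix(stats::rnorm(n_draws * K, rep(prey$caloric_density, each = n_draws),
                                   rep(0.1 * prey$caloric_density, each = n_draws)),
                      n_draws, K, dimnames = list(NULL, prey$prey_id))
  cal_draws <- pmax(cal_draws, 1e-3)
  structure(list(eta_draws = eta_draws, eta_obs = eta_obs, mu_obs = mu_obs,
                 size_draws = size_draws, cal_draws = cal_draws,
                 prey = prey, years = years, truth_seed = truth$seed,
                 seed = seed),
            class = "observed_foraging")
}

#' @export
print.observed_foraging <- function(x, ...) {
  cat("Simulated foraging-survey outputs:", nrow(x$prey), "prey x",
      length(x$years), "years,", nrow(x$eta_draws[[1]]), "draws/year\n")
  cat("Observed mean effort allocation (first and last year):\n")
  print(round(x$eta_obs[c(1, nrow(x$eta_obs)), ], 3))
  invisible(x)
}

#' Configuration for synthetic rocky intertidal surveys
#'
#' Defaults encode the monitored system: four sites surveyed 2001-2021; a
#' sea star population following a Gompertz trajectory until its collapse in
#' 2013; and mussel observations drawn from pre- or post-collapse
#' distributions (distance from the high-intertidal baseline in m, shell
#' size in mm, percent cover) whose means equal the reported field
#' comparisons the generator emulates. The switch to post-collapse mussel
#' distributions happens `mussel_lag_years` after the collapse.
#'
#' @param sites Character vector of site ids.
#' @param years Survey years.
#' @param collapse_year First year of the sea star wasting collapse.
#' @param mussel_lag_years Years between collapse and the mussel response.
#' @param gompertz Named list `A`, `b`, `k` for the pre-collapse sea star
#'   density trajectory (per standard plot), time measured from the first
#'   survey year.
#' @param pisaster_collapse_factor Multiplier applied to the Gompertz level
#'   from `collapse_year` on.
#' @param pisaster_cv Lognormal observation noise CV for sea star density.
#' @param distance_pre,distance_post Mean and SD (m) of mussel distance from
#'   the baseline transect, pre/post response.
#' @param size_pre,size_post Mean and SD (mm) of mussel shell size.
#' @param cover_pre,cover_post Mean and SD (%) of site-year mussel cover.
#' @param n_distance,n_size Observations per site-year.
#' @param n_transects Perpendicular transects per site (grid columns).
#' @param transect_length_m Length of each perpendicular transect.
#' @return A list of class `"intertidal_config"`.
#' @export
intertidal_config <- function(sites = paste0("site_", 1:4),
                              years = 2001:2021,
                              collapse_year = 2013,
                              mussel_lag_years = 2,
                              gompertz = list(A = 24, b = 2.5, k = 0.45),
                              pisaster_collapse_factor = 0.03,
                              pisaster_cv = 0.15,
                              distance_pre = c(mean = 9.59, sd = 4.60),
                              distance_post = c(mean = 12.1, sd = 4.71),
                              size_pre = c(mean = 37.5, sd = 13.8),
                              size_post = c(mean = 47.6, sd = 16.9),
                              cover_pre = c(mean = 5.36, sd = 3.0),
                              cover_post = c(mean = 18.4, sd = 8.0),
                              n_distance = 40, n_size = 30,
                              n_transects = 11, transect_length_m = 20) {
  if (collapse_year <= min(years) || collapse_year > max(years))
    stop("'collapse_year' must fall inside 'years'", call. = FALSE)
  if (mussel_lag_years < 0)
    stop("'mussel_lag_years' must be non-negative", call. = FALSE)
  stopifnot(gompertz$A > 0, gompertz$k > 0)
  structure(list(sites = sites, years = years, collapse_year = collapse_year,
                 mussel_lag_years = mussel_lag_years, gompertz = gompertz,
                 pisaster_collapse_factor = pisaster_collapse_factor,
                 pisaster_cv = pisaster_cv,
                 distance_pre = distance_pre, distance_post = distance_post,
                 size_pre = size_pre, size_post = size_post,
                 cover_pre = cover_pre, cover_post = cover_post,
                 n_distance = n_distance, n_size = n_size,
                 n_transects = n_transects,
                 transect_length_m = transect_length_m),
            class = "intertidal_config")
}

gompertz_curve <- function(t, A, b, k) A * exp(-b * exp(-k * t))

#' Simulate rocky intertidal monitoring surveys
#'
#' Emits one record per site-year with sea star density (Gompertz growth
#' through the year before the collapse, then near-zero), site-year mussel
#' percent cover, mussel distance-from-baseline and shell-size observations,
#' and a presence/absence grid over perpendicular transects. Mussel fields
#' switch from the pre- to the post-collapse distributions
#' `mussel_lag_years` after the collapse year.
#'
#' @param config An [intertidal_config()].
#' @param seed Integer seed.
#' @return A list of class `"intertidal_surveys"`: `records` (data frame of
#'   site-year rows: `site_id`, `year`, `pisaster_density`, `mussel_cover`),
#'   `distances`, `sizes` (data frames of per-observation rows), `grid`
#'   (presence records: site, year, transect, distance_m, present),
#'   `config`, `seed`.
#' @export
simulate_intertidal <- function(config = intertidal_config(), seed = 1) {
  stopifnot(inherits(config, "intertidal_config"))
  set.seed(seed)
  cfg <- config
  resp_year <- cfg$collapse_year + cfg$mussel_lag_years
  recs <- expand.grid(site_id = cfg$sites, year = cfg$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs <- recs[order(recs$site_id, recs$year), ]
  g <- cfg$gompertz
  base <- gompertz_curve(recs$year - min(cfg$years), g$A, g$b, g$k)
  base[recs$year >= cfg$collapse_year] <-
    base[recs$year >= cfg$collapse_year] * cfg$pisaster_collapse_factor
  noise <- if (cfg$pisaster_cv > 0)
    exp(stats::rnorm(nrow(recs), 0, cfg$pisaster_cv)) else 1
  recs$pisaster_density <- base * noise
  post <- recs$year >= resp_year
  cv <- ifelse(post, cfg$cover_post["mean"], cfg$cover_pre["mean"]) +
    stats::rnorm(nrow(recs)) * ifelse(post, cfg$cover_post["sd"], cfg$cover_pre["sd"])
  recs$mussel_cover <- pmin(pmax(cv, 0), 100)
  draw_obs <- function(n_per, pre_par, post_par) {
    out <- vector("list", nrow(recs))
    for (r in seq_len(nrow(recs))) {
      par <- if (recs$year[r] >= resp_year) post_par else pre_par
      v <- stats::rnorm(n_per, par["mean"], par["sd"])
      out[[r]] <- data.frame(site_id = recs$site_id[r], year = recs$year[r],
                             value = pmax(v, 0), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  distances <- draw_obs(cfg$n_distance, cfg$distance_pre, cfg$distance_post)
  names(distances)[3] <- "distance_m"
  sizes <- draw_obs(cfg$n_size, cfg$size_pre, cfg$size_post)
  names(sizes)[3] <- "size_mm"
  # presence/absence grid: probability declines down-shore, expands post
  grid <- expand.grid(site_id = cfg$sites, year = cfg$years,
                      transect = seq_len(cfg$n_transects),
                      distance_m = 0:cfg$transect_length_m,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gp <- grid$year >= resp_year
  pfront <- ifelse(gp, stats::plogis((13 - grid$distance_m) / 2.5) * 0.8,
                   stats::plogis((8 - grid$distance_m) / 2.0) * 0.6)
  grid$present <- as.integer(stats::runif(nrow(grid)) < pfront)
  structure(list(records = recs, distances = distances, sizes = sizes,
                 grid = grid, config = cfg, seed = seed),
            class = "intertidal_surveys")
}

#' @export
print.intertidal_surveys <- function(x, ...) {
  cat("Synthetic intertidal surveys:", length(unique(x$records$site_id)),
      "sites,", min(x$records$year), "-", max(x$records$year), "\n")
  cat("Collapse year:", x$config$collapse_year,
      "; mussel response from:", x$config$collapse_year + x$config$mussel_lag_years, "\n")
  invisible(x)
}

#' Configuration for the synthetic sea otter census
#'
#' @param years Census years (default 2000-2024 with the two unsurveyed
#'   years 2011 and 2020 removed).
#' @param cutoff_year First year of the post period.
#' @param pre,post Named vectors `c(mean=, sd=)` of independent-otter counts
#'   per period.
#' @return A list of class `"census_config"`.
#' @export
census_config <- function(years = setdiff(2000:2024, c(2011, 2020)),
                          cutoff_year = 2013,
                          pre = c(mean = 373, sd = 49),
                          post = c(mean = 535, sd = 91)) {
  if (any(pre < 0) || any(post < 0)) stop("census moments must be non-negative",
                                          call. = FALSE)
  structure(list(years = years, cutoff_year = cutoff_year,
                 pre = pre, post = post),
            class = "census_config")
}

#' Simulate yearly census counts of independent sea otters
#'
#' Counts are drawn from the period-appropriate normal distribution, rounded
#' to non-negative integers. Unsurveyed years are simply absent.
#'
#' @param config A [census_config()].
#' @param seed Integer seed.
#' @return Data frame of class `"census_series"` with columns `year`,
#'   `independents`.
#' @export
simulate_census <- function(config = census_config(), seed = 1) {
  stopifnot(inherits(config, "census_config"))
  set.seed(seed)
  post <- config$years >= config$cutoff_year
  mean_v <- ifelse(post, config$post["mean"], config$pre["mean"])
  sd_v <- ifelse(post, config$post["sd"], config$pre["sd"])
  counts <- pmax(round(stats::rnorm(length(config$years), mean_v, sd_v)), 0)
  out <- data.frame(year = config$years, independents = as.integer(counts))
  class(out) <- c("census_series", "data.frame")
  attr(out, "cutoff_year") <- config$cutoff_year
  out
}

#' Write the synthetic data set to tidy CSV files plus a JSON sidecar
#'
#' @param truth,obs,surveys,census Objects from the four generators.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_data <- function(truth, obs, surveys, census, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- character(0)
  w <- function(d, name) {
    path <- file.path(dir, name)
    utils::write.csv(d, path, row.names = FALSE)
    f <<- c(f, path)
  }
  ed <- do.call(rbind, lapply(seq_along(obs$eta_draws), function(t) {
    m <- obs$eta_draws[[t]]
    data.frame(year = obs$years[t], draw = seq_len(nrow(m)), m,
               check.names = FALSE)
  }))
  w(ed, "foraging_effort_draws.csv")
  mo <- data.frame(prey_id = rep(rownames(obs$mu_obs), ncol(obs$mu_obs)),
                   year = rep(obs$years, each = nrow(obs$mu_obs)),
                   mu_obs = as.vector(obs$mu_obs))
  w(mo, "foraging_intake_obs.csv")
  w(surveys$records, "intertidal_site_year.csv")
  w(surveys$distances, "intertidal_distances.csv")
  w(surveys$sizes, "intertidal_sizes.csv")
  w(surveys$grid, "intertidal_grid.csv")
  w(as.data.frame(census), "otter_census.csv")
  sidecar <- list(
    seed = list(truth = truth$seed, observations = obs$seed,
                intertidal = surveys$seed),
    prey = truth$prey,
    years = truth$years,
    sigma_D = truth$sigma_D, sigma_E = truth$sigma_E, tau = truth$tau,
    regime_shifts = truth$config$regime_shifts,
    Delta = as.data.frame(truth$Delta)
  )
  jpath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sidecar, jpath, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(c(f, jpath))
}
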