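test_that("all four generators are deterministic given a seed", {
  cfg <- truth_config()
  t1 <- generate_ground_truth(cfg, seed = 5)
  t2 <- generate_ground_truth(cfg, seed = 5)
  expect_identical(t1, t2)
  o1 <- simulate_sofa_outputs(t1, n_draws = 150, seed = 6)
  o2 <- simulate_sofa_outputs(t1, n_draws = 150, seed = 6)
  expect_identical(o1, o2)
  s1 <- simulate_intertidal(seed = 7)
  s2 <- simulate_intertidal(seed = 7)
  expect_identical(s1, s2)
  c1 <- simulate_census(seed = 8)
  c2 <- simulate_census(seed = 8)
  expect_identical(c1, c2)
})

test_that("zero innovation and no shifts give constant density trajectories", {
  cfg <- truth_config(sigma_D = 0, regime_shifts = default_regime_shifts()[0, ])
  tr <- generate_ground_truth(cfg, seed = 1)
  expect_true(all(apply(tr$Delta, 1, function(z) max(z) - min(z)) == 0))
})

test_that("random-walk increments have the configured variance", {
  cfg <- truth_config(sigma_D = 0.3, regime_shifts = default_regime_shifts()[0, ])
  incr <- unlist(lapply(1:60, function(s) {
    tr <- generate_ground_truth(cfg, seed = s)
    as.vector(tr$Delta[, -1] - tr$Delta[, -ncol(tr$Delta)])
  }))
  expect_gt(length(incr), 10000)
  expect_lt(abs(stats::var(incr) - 0.09), 0.05 * 0.09)
})

test_that("regime shifts are exact offsets in the noise-free limit", {
  cfg <- truth_config(sigma_D = 0)
  tr <- generate_ground_truth(cfg, seed = 1)
  post <- tr$years >= 2014
  step <- tr$Delta["urchin", post] - tr$Delta_base["urchin", post]
  expect_true(all(step == 0.4))
  # mussel ramp reaches its full size after ramp_years
  full <- tr$years >= 2019
  expect_true(all(tr$Delta["mussel", full] - tr$Delta_base["mussel", full] == 1.4))
})

test_that("invalid truth configurations are rejected", {
  expect_error(truth_config(prey = default_prey_profiles()[1, , drop = FALSE]),
               "at least 2")
  expect_error(truth_config(tau = 0), "positive")
  bad <- default_regime_shifts()
  bad$start_year[1] <- 1990
  expect_error(truth_config(regime_shifts = bad), "outside")
  bad2 <- default_regime_shifts()
  bad2$prey_id[1] <- "kraken"
  expect_error(truth_config(regime_shifts = bad2), "not found")
})

test_that("effort draws sit on the simplex and concentrate as tau grows", {
  tr <- generate_ground_truth(truth_config(), seed = 3)
  obs <- simulate_sofa_outputs(tr, n_draws = 200, seed = 4)
  for (m in obs$eta_draws[c(1, 9, 18)])
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))

  # Dirichlet concentration limit: enormous tau pins draws at the truth
  tr_hi <- generate_ground_truth(truth_config(tau = 1e8), seed = 3)
  obs_hi <- simulate_sofa_outputs(tr_hi, n_draws = 300, seed = 4)
  for (t in c(1, 10)) {
    expect_true(all(abs(colMeans(obs_hi$eta_draws[[t]]) - tr_hi$eta[, t]) < 1e-3))
  }
})

test_that("effort draw variance follows the Dirichlet formula", {
  tr <- generate_ground_truth(truth_config(tau = 50, sigma_D = 0), seed = 3)
  obs <- simulate_sofa_outputs(tr, n_draws = 10000, seed = 4)
  t <- 3
  v_obs <- apply(obs$eta_draws[[t]], 2, stats::var)
  v_exp <- tr$eta[, t] * (1 - tr$eta[, t]) / 51
  expect_true(all(abs(v_obs - v_exp) <= 0.1 * v_exp))
})

test_that("zero observation noise reproduces the log profitabilities exactly", {
  tr <- generate_ground_truth(truth_config(sigma_E = 0), seed = 3)
  obs <- simulate_sofa_outputs(tr, n_draws = 150, seed = 4)
  expect_equal(as.vector(obs$mu_obs),
               rep(tr$prey$mu, length(tr$years)), tolerance = 1e-12)
})

test_that("missing observations appear at the configured rate", {
  tr <- generate_ground_truth(truth_config(missing_frac = 0.3), seed = 3)
  obs <- simulate_sofa_outputs(tr, n_draws = 150, seed = 4)
  frac <- mean(!is.finite(obs$mu_obs))
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
})

test_that("intertidal surveys encode the mesopredator collapse", {
  surv <- simulate_intertidal(seed = 2)
  recs <- surv$records
  for (s in unique(recs$site_id)) {
    pre_min <- min(recs$pisaster_density[recs$site_id == s & recs$year < 2013])
    post_max <- max(recs$pisaster_density[recs$site_id == s & recs$year >= 2013])
    expect_lt(post_max, pre_min)
  }
  # pooled post-period mussels are larger than pre-period
  pre_sz <- surv$sizes$size_mm[surv$sizes$year < 2013]
  post_sz <- surv$sizes$size_mm[surv$sizes$year >= 2013]
  expect_gt(mean(post_sz), mean(pre_sz))
  expect_true(all(recs$mussel_cover >= 0 & recs$mussel_cover <= 100))
  expect_true(all(surv$grid$transect %in% 1:11))
  expect_true(all(surv$grid$distance_m >= 0))
})

test_that("zero-variance intertidal config reproduces configured means exactly", {
  cfg <- intertidal_config(distance_pre = c(mean = 9.59, sd = 0),
                           distance_post = c(mean = 12.1, sd = 0),
                           size_pre = c(mean = 37.5, sd = 0),
                           size_post = c(mean = 47.6, sd = 0),
                           cover_pre = c(mean = 5.36, sd = 0),
                           cover_post = c(mean = 18.4, sd = 0),
                           pisaster_cv = 0)
  surv <- simulate_intertidal(cfg, seed = 1)
  resp <- cfg$collapse_year + cfg$mussel_lag_years
  expect_equal(unique(surv$sizes$size_mm[surv$sizes$year < resp]), 37.5)
  expect_equal(unique(surv$sizes$size_mm[surv$sizes$year >= resp]), 47.6)
  expect_equal(unique(surv$records$mussel_cover[surv$records$year >= resp]), 18.4)
})

test_that("census series has the survey gaps and period structure", {
  cen <- simulate_census(seed = 9)
  expect_false(any(c(2011, 2020) %in% cen$year))
  expect_true(all(cen$independents >= 0))
  expect_true(all(cen$independents == round(cen$independents)))
  expect_false(anyDuplicated(cen$year) > 0)

  cfg0 <- census_config(pre = c(mean = 373, sd = 0), post = c(mean = 535, sd = 0))
  cen0 <- simulate_census(cfg0, seed = 9)
  expect_true(all(cen0$independents[cen0$year < 2013] == 373))
  expect_true(all(cen0$independents[cen0$year >= 2013] == 535))
})

test_that("census counts average to the configured post mean (law of large numbers)", {
  post_counts <- unlist(lapply(1:1000, function(s) {
    cen <- simulate_census(seed = s)
    cen$independents[cen$year >= 2013]
  }))
  expect_lt(abs(mean(post_counts) - 535) / 535, 0.02)
})

test_that("synthetic data round-trips through tidy CSV files", {
  tr <- generate_ground_truth(truth_config(), seed = 1)
  obs <- simulate_sofa_outputs(tr, n_draws = 120, seed = 2)
  surv <- simulate_intertidal(seed = 3)
  cen <- simulate_census(seed = 4)
  dir <- file.path(tempdir(), "synthcsv")
  files <- write_synthetic_data(tr, obs, surv, cen, dir)
  expect_true(all(file.exists(files)))
  ed <- utils::read.csv(file.path(dir, "foraging_effort_draws.csv"),
                        check.names = FALSE)
  expect_equal(nrow(ed), length(tr$years) * 120)
  expect_equal(max(abs(rowSums(ed[, tr$prey$prey_id]) - 1)), 0, tolerance = 1e-9)
  sidecar <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$seed$truth, 1)
  expect_equal(sidecar$Delta[["_row"]], tr$prey$prey_id)
  D_back <- do.call(cbind, sidecar$Delta[as.character(tr$years)])
  expect_equal(unname(D_back), unname(tr$Delta), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
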