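# Shared fixtures. Fits are cached per test run so several test files can
# reuse the same posterior without refitting.

.fixture_env <- new.env(parent = emptyenv())

# a small 4-prey community for fast fits
small_prey <- function() {
  p <- default_prey_profiles()
  p <- p[match(c("abalone", "clam", "urchin", "snail"), p$prey_id), ]
  rownames(p) <- NULL
  p
}

small_truth_config <- function(years = 2007:2018, sigma_D = 0.1,
                               regime_shifts = small_shifts(), tau = 100) {
  truth_config(prey = small_prey(), years = years,
               sigma_D = sigma_D, sigma_E = 0.1, tau = tau,
               eta_pre = c(0.35, 0.25, 0.25, 0.15),
               regime_shifts = regime_shifts)
}

small_shifts <- function() {
  data.frame(prey_id = "urchin", start_year = 2013, ramp_years = 1,
             log_increase = 0.8, stringsAsFactors = FALSE)
}

small_control <- function(...) {
  forage_control(n_samp = 400, n_burn = 80, n_tune = 60, ...)
}

# one cached small fit (plus its truth and observations)
small_fit_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    truth <- generate_ground_truth(small_truth_config(), seed = 11)
    obs <- simulate_sofa_outputs(truth, n_draws = 300, seed = 12)
    fit <- suppressWarnings(forage_fit(obs, small_control(), seed = 13))
    .fixture_env$small <- list(truth = truth, obs = obs, fit = fit)
  }
  .fixture_env$small
}

# one cached fit of the full default synthetic configuration
default_fit_fixture <- function() {
  if (is.null(.fixture_env$default)) {
    truth <- generate_ground_truth(truth_config(), seed = 1)
    obs <- simulate_sofa_outputs(truth, n_draws = 1000, seed = 101)
    fit <- suppressWarnings(
      forage_fit(obs, forage_control(n_samp = 2000), seed = 201))
    .fixture_env$default <- list(truth = truth, obs = obs, fit = fit)
  }
  .fixture_env$default
}

# Monte-Carlo dive simulator: independent Bernoulli(lambda_i) encounters per
# dive, otter takes the highest-E prey encountered, dives with no encounter
# are recorded as 0. Independent oracle for the allocation rule.
mc_dive_allocation <- function(E, lambda, n_dives = 1e5) {
  K <- length(E)
  ord <- order(E, decreasing = TRUE)
  enc <- matrix(stats::runif(n_dives * K), n_dives, K) <
    matrix(lambda, n_dives, K, byrow = TRUE)
  # first encountered prey in profitability order
  score <- sweep(enc[, ord, drop = FALSE], 2, K:1, "*")
  choice <- max.col(score, ties.method = "first")
  any_enc <- rowSums(enc) > 0
  chosen <- ord[choice][any_enc]
  counts <- tabulate(chosen, nbins = K)
  list(eta = counts / sum(counts),
       p_any = mean(any_enc),
       energy_per_dive = sum(E[chosen]) / n_dives,
       energy_cond = sum(E[chosen]) / sum(any_enc),
       n_cond = sum(any_enc))
}

# internal allocation kernel, used by property tests
.alloc_pi_test <- function(E, lam) otterforage:::.alloc_pi(E, lam)
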