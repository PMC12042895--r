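test_that("fits are reproducible given the same seed and control", {
  fx <- small_fit_fixture()
  fit2 <- suppressWarnings(forage_fit(fx$obs, small_control(), seed = 13))
  expect_identical(fx$fit$draws, fit2$draws)
  expect_identical(summary(fx$fit)$E, summary(fit2)$E)
  expect_identical(fx$fit$tau, fit2$tau)
})

test_that("the fit recovers profitabilities on a small community", {
  fx <- small_fit_fixture()
  true_mu <- fx$truth$prey$mu
  q <- apply(fx$fit$draws$mu, 2, stats::quantile, c(0.025, 0.975))
  covered <- sum(true_mu >= q[1, ] & true_mu <= q[2, ])
  expect_gte(covered, 3)  # at least 3 of 4 prey in a typical run
  expect_lt(max(abs(colMeans(fx$fit$draws$mu) - true_mu)), 0.15)
})

test_that("dynamic truth produces larger fitted density changes than static truth", {
  cfg_flat <- small_truth_config(sigma_D = 0.05,
                                 regime_shifts = small_shifts()[0, ])
  tr_flat <- generate_ground_truth(cfg_flat, seed = 21)
  obs_flat <- simulate_sofa_outputs(tr_flat, n_draws = 300, seed = 22)
  fit_flat <- suppressWarnings(forage_fit(obs_flat, small_control(), seed = 23))

  fx <- small_fit_fixture()  # truth contains an urchin step of +0.8
  move <- function(fit, pid) {
    d <- fit$draws$Delta[, pid, ]
    mean(abs(d[, dim(d)[2]] - d[, 1]))
  }
  expect_gt(move(fx$fit, "urchin"), move(fit_flat, "urchin"))
})

test_that("per-year Dirichlet precisions are computed in the pre-fit", {
  fx <- small_fit_fixture()
  expect_length(fx$fit$tau, length(fx$truth$years))
  expect_true(all(fx$fit$tau > 0))
  # tau was configured at 100 in the generator; ML estimates should be near
  expect_true(all(fx$fit$tau > 60 & fx$fit$tau < 160))
})

test_that("posterior allocation obeys simplex constraints", {
  fx <- small_fit_fixture()
  al <- posterior_allocation(fx$fit, 2012)
  expect_true(all(al$lo <= al$mean & al$mean <= al$hi))
  expect_true(all(al$lo >= 0 & al$hi <= 1))
  draws <- attr(al, "draws")
  expect_equal(rowSums(draws), rep(1, nrow(draws)), tolerance = 1e-9)
  expect_error(posterior_allocation(fx$fit, 1999), "outside")
})

test_that("methods return consistently shaped summaries", {
  fx <- small_fit_fixture()
  fit <- fx$fit
  K <- 4; Tn <- length(fx$truth$years)
  expect_length(coef(fit), 3 * K)
  fhat <- fitted(fit)
  expect_equal(dim(fhat), c(Tn, K))
  expect_equal(rowSums(fhat), rep(1, Tn), tolerance = 1e-9,
               ignore_attr = TRUE)
  res <- residuals(fit)
  expect_equal(dim(res), dim(fit$data$eta_obs))
  expect_lt(max(abs(res)), 0.2)  # fitted shares track observed compositions
  en <- predict(fit, type = "energy")
  expect_equal(en$year, fx$truth$years)
  expect_true(all(en$lo <= en$mean & en$mean <= en$hi))
  # normalized energy conditions on an encounter, so it is larger
  en_n <- predict(fit, type = "energy", normalized = TRUE)
  expect_true(all(en_n$mean > en$mean))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(fit$data$eta_obs))
  expect_equal(rowSums(sims[[1]]), rep(1, Tn), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_output(print(fit), "state-space")
  expect_output(print(summary(fit)), "Patch profitabilities")
})

test_that("missing intake observations are dropped, not imputed", {
  tr <- generate_ground_truth(small_truth_config(), seed = 31)
  obs <- simulate_sofa_outputs(tr, n_draws = 300, seed = 32)
  obs$mu_obs[2, c(3, 7)] <- NA_real_
  fit <- suppressWarnings(forage_fit(obs, small_control(), seed = 33))
  expect_true(all(is.finite(fit$draws$mu)))
  expect_lt(abs(mean(fit$draws$mu[, 2]) - tr$prey$mu[2]), 0.2)
})

test_that("the convergence gate reports and escalates", {
  fx <- small_fit_fixture()
  # an absurdly strict gate must trigger the warning path...
  strict <- small_control(rhat_max = 1.000001, ess_min = 1e7)
  expect_warning(forage_fit(fx$obs, strict, seed = 13), "convergence")
  # ...and the error path when configured to fail hard
  strict_err <- small_control(rhat_max = 1.000001, ess_min = 1e7,
                              on_nonconvergence = "error")
  expect_error(forage_fit(fx$obs, strict_err, seed = 13), "convergence")
  expect_true(all(c("rhat", "ess") %in% names(fx$fit$diagnostics)))
})

test_that("malformed observations are rejected", {
  fx <- small_fit_fixture()
  bad <- fx$obs
  bad$eta_obs[1, ] <- bad$eta_obs[1, ] * 2
  expect_error(forage_fit(bad, small_control(), seed = 1), "simplex")
  expect_error(forage_fit(fx$obs, small_control(), tau = c(-1), seed = 1),
               "positive")
  one_year <- fx$obs
  one_year$eta_obs <- one_year$eta_obs[1, , drop = FALSE]
  one_year$mu_obs <- one_year$mu_obs[, 1, drop = FALSE]
  one_year$years <- one_year$years[1]
  one_year$eta_draws <- one_year$eta_draws[1]
  expect_error(forage_fit(one_year, small_control(), seed = 1), "2 years")
})

test_that("posterior means agree with an independent Gibbs sampler (JAGS)", {
  # small, well-identified configuration; compare the well-mixing
  # parameters (log profitabilities and observation scales)
  set.seed(77)
  K <- 3; Tn <- 10
  prey <- default_prey_profiles()[c(3, 6, 7), ]  # abalone, clam, snail
  cfg <- truth_config(prey = prey, years = 2007:2016, sigma_D = 0.12,
                      sigma_E = 0.1, tau = 80, eta_pre = c(0.5, 0.3, 0.2),
                      regime_shifts = default_regime_shifts()[0, ])
  tr <- generate_ground_truth(cfg, seed = 41)
  obs <- simulate_sofa_outputs(tr, n_draws = 400, seed = 42)
  fit <- suppressWarnings(
    forage_fit(obs, forage_control(n_samp = 1500, n_burn = 100), seed = 43))

  library(rjags)
  model_str <- "
  model {
    for (i in 1:K) {
      mu_e[i] ~ dt(0, 0.16, 1)
      sig_D[i] ~ dt(0, 0.16, 1) T(0,)
      sig_E[i] ~ dt(0, 0.16, 1) T(0,)
      Delta[i,1] ~ dnorm(-1, 0.25)
      for (t in 2:T) { Delta[i,t] ~ dnorm(Delta[i,t-1], pow(sig_D[i], -2)) }
      for (t in 1:T) {
        lambda[i,t] <- 1 - exp(-exp(Delta[i,t]))
        for (j in 1:K) { M[i,j,t] <- 1 - lambda[j,t]*step(mu_e[j]-mu_e[i]-1e-9) }
        pi[i,t] <- lambda[i,t] * prod(M[i,1:K,t])
        mu_obs[i,t] ~ dnorm(mu_e[i], pow(sig_E[i], -2))
      }
    }
    for (t in 1:T) {
      Spi[t] <- sum(pi[1:K,t])
      alpha[1:K,t] <- tau[t] * pi[1:K,t] / Spi[t]
      eta_obs[t,1:K] ~ ddirch(alpha[1:K,t])
      z[t] ~ dnorm(log(Spi[t]/(1-Spi[t])), pow(0.3, -2))
    }
  }"
  dat <- list(K = K, T = Tn, tau = fit$tau, eta_obs = obs$eta_obs,
              mu_obs = obs$mu_obs, z = rep(qlogis(0.85), Tn))
  inits <- lapply(1:2, function(c)
    list(mu_e = rowMeans(obs$mu_obs),
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = 50 + c))
  jm <- jags.model(textConnection(model_str), data = dat, inits = inits,
                   n.chains = 2, n.adapt = 2000, quiet = TRUE)
  update(jm, 4000)
  s <- coda.samples(jm, c("mu_e", "sig_E"), n.iter = 20000, thin = 10)
  ref <- summary(s)$statistics
  expect_equal(unname(colMeans(fit$draws$mu)),
               unname(ref[paste0("mu_e[", 1:K, "]"), "Mean"]),
               tolerance = 0.05)
  expect_equal(unname(colMeans(fit$draws$sigma_E)),
               unname(ref[paste0("sig_E[", 1:K, "]"), "Mean"]),
               tolerance = 0.25)
})
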