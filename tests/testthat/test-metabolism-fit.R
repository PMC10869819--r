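# Least-squares oracle, MCMC fit behavior, diagnostics, re-run policy.

test_that("oracle inverts the forward map exactly at zero noise", {
  site <- noise_free_site()
  ora <- ls_oracle_fit(site$obs, data.frame(date = site$truth$date,
                                            K600 = site$truth$K600_true))
  expect_equal(ora$GPP, site$truth$GPP_true, tolerance = 1e-10)
  expect_equal(ora$ER, site$truth$ER_true, tolerance = 1e-10)
  # same property under the explicit-Euler discretization pair
  eul <- forward_simulate(site$forcing,
                          data.frame(date = site$truth$date,
                                     GPP = site$truth$GPP_true,
                                     ER = site$truth$ER_true,
                                     K600 = site$truth$K600_true),
                          o2_init = site$forcing$DO.sat[1],
                          ode_method = "euler")
  eul$DO.obs <- eul$DO.mod
  ora_e <- ls_oracle_fit(eul, data.frame(date = site$truth$date,
                                         K600 = site$truth$K600_true),
                         ode_method = "euler")
  expect_equal(ora_e$GPP, site$truth$GPP_true, tolerance = 1e-10)
  expect_equal(ora_e$ER, site$truth$ER_true, tolerance = 1e-10)
})

test_that("oracle drops GPP on dark days but still estimates ER", {
  cfg <- synthetic_config(n_days = 2, gpp_mean = 0, gpp_sd = 0,
                          sigma_proc = 0, sigma_obs = 0, seed = 9)
  f <- generate_forcing(cfg)
  f$light <- rep(0, nrow(f))
  tr <- generate_truth(cfg, f)
  obs <- generate_do(tr, f, cfg)
  ora <- ls_oracle_fit(obs, data.frame(date = tr$date,
                                       K600 = tr$K600_true))
  expect_true(all(is.na(ora$GPP)))
  expect_equal(ora$ER, tr$ER_true, tolerance = 1e-8)
})

test_that("oracle is unbiased under pure observation noise", {
  cfg0 <- synthetic_config(n_days = 1, gpp_sd = 0, er_sd = 0,
                           sigma_proc = 0, sigma_obs = 0, k600_sdlog = 0,
                           lnQ_sd = 0, seed = 2)
  f <- generate_forcing(cfg0)
  tr <- generate_truth(cfg0, f)
  clean <- generate_do(tr, f, cfg0)
  ests <- t(sapply(1:100, function(s) {
    noisy <- clean
    noisy$DO.obs <- clean$DO.obs +
      withr::with_seed(s, rnorm(nrow(clean), 0, 0.1))
    o <- ls_oracle_fit(noisy, data.frame(date = tr$date,
                                         K600 = tr$K600_true))
    c(o$GPP, o$ER)
  }))
  expect_equal(mean(ests[, 1]), tr$GPP_true, tolerance = 0.02)
  expect_equal(abs(mean(ests[, 2])), abs(tr$ER_true), tolerance = 0.02)
})

test_that("fits are reproducible under a fixed seed and report NEP = GPP + ER", {
  cfg <- synthetic_config(n_days = 4, seed = 6)
  f <- generate_forcing(cfg)
  tr <- generate_truth(cfg, f)
  obs <- generate_do(tr, f, cfg)
  fit1 <- fit_metabolism(obs, n_chains = 2, n_warmup = 150, n_iter = 150,
                         seed = 12)
  fit2 <- fit_metabolism(obs, n_chains = 2, n_warmup = 150, n_iter = 150,
                         seed = 12)
  expect_identical(fit1$daily, fit2$daily)
  expect_equal(fit1$daily$NEP, fit1$daily$GPP + fit1$daily$ER)
  expect_true(all(fit1$daily$GPP.sd >= 0))
  expect_true(all(fit1$daily$K600 > 0))
  # split-chain R-hat has a small finite-sample downward bias bounded by
  # sqrt((n-1)/n), so "at least 1" holds only up to that factor
  expect_true(all(c(fit1$diagnostics$rhat_sigma_obs,
                    fit1$diagnostics$rhat_sigma_proc,
                    fit1$diagnostics$rhat_sigma_K600) >= 0.98))
  expect_equal(fit1$daily$n_obs, rep(96L, 4))
})

test_that("fit matches the oracle on low-noise data and is robust to inits", {
  cfg <- synthetic_config(n_days = 4, sigma_proc = 0.005,
                          sigma_obs = 0.02, k600_sdlog = 0, seed = 21)
  f <- generate_forcing(cfg)
  tr <- generate_truth(cfg, f)
  obs <- generate_do(tr, f, cfg)
  ora <- ls_oracle_fit(obs, data.frame(date = tr$date,
                                       K600 = tr$K600_true))
  fit <- fit_metabolism(obs, n_chains = 2, n_warmup = 400, n_iter = 400,
                        seed = 5)
  expect_equal(fit$daily$GPP, ora$GPP, tolerance = 0.05)
  expect_equal(fit$daily$ER, ora$ER, tolerance = 0.05)
  # halving/doubling the initial values leaves posterior means in place
  fit2 <- fit_metabolism(obs, n_chains = 2, n_warmup = 400, n_iter = 400,
                         seed = 5, init_factor = 2)
  expect_equal(fit2$daily$GPP, fit$daily$GPP, tolerance = 0.1)
  expect_equal(fit2$daily$ER, fit$daily$ER, tolerance = 0.1)
})

test_that("empty forcing produces an empty result, not a crash", {
  cfg <- synthetic_config(n_days = 2, seed = 3)
  f <- generate_forcing(cfg)
  tr <- generate_truth(cfg, f)
  obs <- generate_do(tr, f, cfg)
  obs$DO.obs[10] <- NA  # breaks day 1; drop day 2 entirely
  obs <- obs[obs$date == obs$date[1], ]
  expect_message(fit <- fit_metabolism(obs), "no complete usable days")
  expect_equal(fit$n_days, 0L)
  expect_equal(nrow(fit$daily), 0)
})

test_that("re-run policy escalates on poor convergence or ER~K600 collinearity", {
  good <- structure(list(rhat_sigma_obs = 1.0, rhat_sigma_proc = 1.0,
                         rhat_sigma_K600 = 1.0, er_k600_r2 = 0.1),
                    class = "fit_diagnostics")
  expect_equal(rerun_policy(good, attempt = 1), "accept")
  bad_rhat <- good; bad_rhat$rhat_sigma_K600 <- 1.3
  expect_equal(rerun_policy(bad_rhat, attempt = 1),
               "rerun_with_1500_warmup")
  bad_cor <- good; bad_cor$er_k600_r2 <- 0.6
  expect_equal(rerun_policy(bad_cor, attempt = 1),
               "rerun_with_1500_warmup")
  # boundary values do not trigger
  edge <- good; edge$rhat_sigma_obs <- 1.1; edge$er_k600_r2 <- 0.5
  expect_equal(rerun_policy(edge, attempt = 1), "accept")
  # after the escalated re-run the fit is accepted regardless
  expect_equal(rerun_policy(bad_rhat, attempt = 2), "accept")
})

test_that("split R-hat separates converged from diverged chains", {
  draws_ok <- withr::with_seed(1, matrix(rnorm(4000), 1000, 4))
  expect_lt(split_rhat(draws_ok), 1.05)
  draws_bad <- draws_ok
  draws_bad[, 1] <- draws_bad[, 1] + 5
  expect_gt(split_rhat(draws_bad), 1.5)
  expect_equal(split_rhat(matrix(1, 100, 4)), 1)
})
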