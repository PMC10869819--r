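# Shared fixtures, built in code. Heavier objects are memoized so several
# test files can reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# noise-free 5-day synthetic site (forcing + truth + observations)
noise_free_site <- function() {
  memo("noise_free_site", {
    cfg <- synthetic_config(n_days = 5, sigma_proc = 0, sigma_obs = 0,
                            seed = 11)
    f <- generate_forcing(cfg)
    tr <- generate_truth(cfg, f)
    list(cfg = cfg, forcing = f, truth = tr,
         obs = generate_do(tr, f, cfg))
  })
}

# the 30-day recovery experiment at the study conditions
# (sigma_obs = 0.1 mg/L, ~2 m depth, K600 tied to lnQ), reduced MCMC
recovery_experiment <- function() {
  memo("recovery_experiment", {
    cfg <- synthetic_config(n_days = 30, sigma_obs = 0.1, seed = 1)
    f <- generate_forcing(cfg)
    tr <- generate_truth(cfg, f)
    obs <- generate_do(tr, f, cfg)
    fit <- fit_metabolism(obs, n_chains = 4, n_warmup = 500, n_iter = 500,
                          seed = 1)
    list(cfg = cfg, truth = tr, obs = obs, fit = fit,
         merged = merge(tr, fit$daily, by = "date"))
  })
}

# one synthetic day with constant conditions handy for integrator tests
one_day_forcing <- function() {
  memo("one_day_forcing", {
    cfg <- synthetic_config(n_days = 1, sigma_proc = 0, sigma_obs = 0,
                            lnQ_sd = 0, seed = 3)
    generate_forcing(cfg)
  })
}

daily_params <- function(forcing, GPP, ER, K600) {
  data.frame(date = sort(unique(forcing$date)), GPP = GPP, ER = ER,
             K600 = K600)
}
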