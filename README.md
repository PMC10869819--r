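# rivermet

Daily river metabolism — gross primary productivity (GPP), ecosystem
respiration (ER), net ecosystem productivity (NEP = GPP + ER), and the
gas-exchange rate constant K600 — estimated from single-station 15-minute
dissolved-oxygen records. The package implements the full workflow used
for the Illinois River Basin (IRB) metabolism data release
(doi:[10.5066/P9TEBOUR](https://doi.org/10.5066/P9TEBOUR)): input
preparation, rating-curve depth estimation, Bayesian state-space inversion
of the oxygen mass balance, and the daily-flag / confidence-rubric quality
assurance — plus a synthetic diel-oxygen generator so every stage is
testable without downloads.

It is written for freshwater ecologists and biogeochemists who want
tested, reproducible metabolism estimation for large, regulated rivers
where questions about eutrophication, hypoxia, and algal blooms hinge on
the balance of GPP and ER.

## The model

The one-station oxygen mass balance equates the rate of change of
dissolved oxygen with metabolism and air–water exchange:

    d[O2]/dt = P_t + R_t + D_t

    P_t = GPP · (1/h) · PPFD_t / (Δt · Σ PPFD)     (light-apportioned)
    R_t = ER / h                                    (uniform in time)
    D_t = K2(T) · (O_sat − O_mod),  K2 = K600 · (Sc(T)/600)^−1/2
    Sc(T) = 1568 − 86.04 T + 2.142 T² − 0.0216 T³

Daily GPP, ER and K600 are estimated jointly by MCMC over the
linear-Gaussian state-space discretization (process noise in the DO
state, observation noise on the record), with an exact Kalman-filter
marginal likelihood and hierarchical partial pooling of ln(K600) on a
piecewise-linear function of ln(discharge). A deterministic per-day
least-squares oracle (`ls_oracle_fit()`) inverts noise-free forward
simulations exactly and serves as the independent check on the sampler.
See the vignette (`vignettes/river-metabolism-workflow.Rmd`) for the
science, priors, and numerical choices.

## A worked example

Simulate a 10-day synthetic river (defaults: ~50 m³/s, ~2 m deep, GPP ≈ 5,
ER ≈ −6 g O₂ m⁻² d⁻¹, K600 ≈ 3 d⁻¹ tied to discharge, 0.1 mg/L sensor
noise), then invert it:

```r
library(rivermet)

cfg     <- synthetic_config(n_days = 10, seed = 1)
forcing <- generate_forcing(cfg)
truth   <- generate_truth(cfg, forcing)
obs     <- generate_do(truth, forcing, cfg)

fit <- fit_metabolism(obs, n_chains = 4, n_warmup = 500, n_iter = 500,
                      seed = 1)
fit
#> Metabolism fit: 10 days, 4 chains x 500 warmup + 500 iter
#>   mean GPP 4.81, mean ER -6.12, mean K600 2.91
#>   Rhat(sigma_obs/proc/K600) = 1.006 / 1.018 / 1.281; ER~K600 r2 = 0.20
```

The per-day posterior summaries track the generating truth closely:

```r
head(fit$daily[, c("date", "GPP", "ER", "K600")], 3)
#>   date         GPP    ER  K600
#> 1 2019-06-01  5.60  -9.54  2.67     (truth: 5.63, -9.47, 2.67)
#> 2 2019-06-02  4.46  -7.30  2.68     (truth: 4.57, -7.46, 2.85)
#> 3 2019-06-03  6.54  -4.87  2.90     (truth: 6.47, -4.68, 3.01)
```

GPP/ER posterior means land within ~0.1–0.2 g O₂ m⁻² d⁻¹ of truth and
K600 within a few percent. At these short-record settings the K600
deviation-scale chain has not fully converged (R̂ = 1.28 > 1.1), so the
workflow's re-run policy escalates, exactly as it would on real data:

```r
rerun_policy(fit$diagnostics)
#> [1] "rerun_with_1500_warmup"
```

Quality assurance and summaries:

```r
flags <- apply_flags(fit$daily)
site_summary(fit$daily, flags, truth$mean_discharge)
#>   n_days n_days_unflagged pct_unflagged q_mean gpp_mean er_mean nep_mean pct_autotrophic
#> 1     10               10           100   51.8     4.81   -6.12    -1.31              20
```

meaning: no day tripped the biological/physical flags, mean metabolism over
unflagged days was heterotrophic (NEP = −1.31 g O₂ m⁻² d⁻¹), and 20% of
days were autotrophic (NEP > 0).

The same pipeline runs from the shell over CSV files and a YAML site
config (`inst/scripts/rivermet`): `simulate`, `prepare`, `depth`, `fit`,
`qa`, `summarize`, or `all`.

## Published IRB site summaries

`irb_site_summaries()` returns the published per-site aggregates for the
17 IRB sites (from the data-release summary tables), and
`basin_rollup()` reproduces the basin-level numbers from them — e.g.
across-site mean GPP 2.76, ER −6.05, NEP −3.28 g O₂ m⁻² d⁻¹, and 43% of
days autotrophic on the Fox River versus 1% on the Kankakee.

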