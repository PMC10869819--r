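# Synthetic forcing, daily truth, noisy DO observations, and channel field
# measurements with the statistical structure the analysis assumes, so the
# whole pipeline is testable without downloads: clear-sky diel light,
# sinusoidal temperature, AR(1) lognormal discharge, a piecewise-linear
# ln(K600)~ln(Q) dependence, and process + observation noise on DO.

#' Synthetic site configuration
#'
#' Defaults describe a mid-sized, regulated Midwestern river in early
#' summer: ~50 m3/s discharge, ~2 m deep, productive (GPP ~ 5, ER ~ -6
#' g O2 m-2 d-1) with moderate gas exchange (K600 ~ 3 1/day) increasing
#' with discharge.
#'
#' @param latitude,longitude site coordinates, degrees
#' @param start_date first calendar day (solar time)
#' @param n_days number of days
#' @param timestep_min grid spacing, minutes (must divide 1440)
#' @param temp_mean,temp_diel_amp,temp_seasonal_amp water temperature model,
#'   degC: mean, diel amplitude (peak mid-afternoon), seasonal amplitude
#' @param pressure_mb constant barometric pressure
#' @param salinity_psu constant salinity
#' @param lnQ_mean,lnQ_sd,lnQ_ar1 stationary mean, sd, and daily lag-1
#'   autocorrelation of the log-discharge AR(1) process
#' @param k600_nodes data.frame (`lnQ`, `lnK600`) defining the
#'   piecewise-linear ln(K600)~ln(Q) dependence
#' @param k600_sdlog lognormal jitter sd of daily K600 about the relation
#' @param gpp_mean,gpp_sd,er_mean,er_sd truncated-normal daily truth
#'   schedules, g O2 m-2 d-1 (GPP >= 0, ER <= 0)
#' @param depth_rating `c(m, b)` of the linear depth rating h = m*GH + b
#' @param gh_ref_discharge,gh_exponent stage-discharge shape used to derive
#'   gage height from discharge: GH = (Q / gh_ref_discharge)^gh_exponent
#' @param sigma_proc process-noise scale, mg L-1 d-0.5
#' @param sigma_obs observation-noise sd, mg/L
#' @param seed integer RNG seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(latitude = 41.1, longitude = -88.25,
                             start_date = "2019-06-01", n_days = 30,
                             timestep_min = 15,
                             temp_mean = 22, temp_diel_amp = 1.5,
                             temp_seasonal_amp = 2,
                             pressure_mb = 1013.25, salinity_psu = 0.3,
                             lnQ_mean = log(50), lnQ_sd = 0.3,
                             lnQ_ar1 = 0.8,
                             k600_nodes = data.frame(
                               lnQ = c(log(20), log(150)),
                               lnK600 = c(log(2.2), log(4.2))),
                             k600_sdlog = 0.05,
                             gpp_mean = 5, gpp_sd = 1.5,
                             er_mean = -6, er_sd = 1.5,
                             depth_rating = c(m = 1.2, b = 0.8),
                             gh_ref_discharge = 50, gh_exponent = 0.4,
                             sigma_proc = 0.03, sigma_obs = 0.1,
                             seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_days < 1) stop("n_days must be >= 1")
  if (1440 %% cfg$timestep_min != 0) stop("timestep must divide 1440 minutes")
  if (cfg$gpp_mean < 0) stop("gpp_mean must be >= 0")
  if (cfg$er_mean > 0) stop("er_mean must be <= 0")
  if (cfg$sigma_proc < 0 || cfg$sigma_obs < 0) {
    stop("noise scales must be >= 0")
  }
  if (is.null(cfg$k600_nodes) || nrow(cfg$k600_nodes) == 0) {
    stop("k600_nodes must contain at least one (lnQ, lnK600) pair")
  }
  if (any(!is.finite(cfg$k600_nodes$lnK600))) {
    stop("node lnK600 values must be finite")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic forcing series
#'
#' Builds the gridded environmental drivers over the configured span:
#' clear-sky light (zero at night, unimodal by day), seasonal + diel
#' sinusoidal water temperature peaking mid-afternoon, AR(1) lognormal
#' discharge interpolated from daily values, gage height from a
#' stage-discharge shape, and depth through the configured linear rating
#' (so the rating inverse reproduces gage height from depth). All draws
#' are seed-reproducible.
#'
#' @param config a [synthetic_config()]
#' @return a `forcing_series` tibble (no `DO.obs`; see [generate_do()])
#' @export
generate_forcing <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_per_day <- 1440 / config$timestep_min
  n <- config$n_days * n_per_day
  # grid starts at the metabolic-day boundary (solar 04:00) so every
  # configured day is a complete metabolic day
  t0 <- as.POSIXct(paste(config$start_date, "04:00:00"), tz = "UTC")
  solar_time <- t0 + (seq_len(n) - 1) * config$timestep_min * 60
  lt <- as.POSIXlt(solar_time, tz = "UTC")
  hour <- lt$hour + lt$min / 60
  doy <- lt$yday + 1
  temp <- config$temp_mean +
    config$temp_seasonal_amp * sin(2 * pi * (doy - 110) / 365) +
    config$temp_diel_amp * sin(2 * pi * (hour - 10) / 24)
  # daily AR(1) on lnQ (stationary sd = lnQ_sd), interpolated to the grid
  lnQ_daily <- withr::with_seed(config$seed, {
    e <- numeric(config$n_days)
    if (config$lnQ_sd > 0) {
      innov_sd <- config$lnQ_sd * sqrt(1 - config$lnQ_ar1^2)
      e[1] <- stats::rnorm(1, 0, config$lnQ_sd)
      if (config$n_days > 1) {
        for (d in 2:config$n_days) {
          e[d] <- config$lnQ_ar1 * e[d - 1] + stats::rnorm(1, 0, innov_sd)
        }
      }
    }
    config$lnQ_mean + e
  })
  if (config$n_days == 1) {
    lnQ <- rep(lnQ_daily, n)
  } else {
    mid <- (seq_len(config$n_days) - 0.5) * n_per_day
    lnQ <- stats::approx(mid, lnQ_daily, xout = seq_len(n), rule = 2)$y
  }
  discharge <- exp(lnQ)
  gage_height <- (discharge / config$gh_ref_discharge)^config$gh_exponent
  depth <- config$depth_rating[["m"]] * gage_height +
    config$depth_rating[["b"]]
  out <- tibble::tibble(
    solar.time = solar_time,
    temp.water = temp,
    salinity = config$salinity_psu,
    pressure = config$pressure_mb,
    discharge = discharge,
    gage.height = gage_height,
    depth = depth,
    light = light_ppfd(solar_time, config$latitude),
    DO.sat = do_saturation(temp, config$pressure_mb, config$salinity_psu)
  )
  out$date <- metab_date(out$solar.time)
  out$usable <- TRUE
  class(out) <- c("forcing_series", class(out))
  out
}

#' Generate per-day true metabolism parameters
#'
#' One truth row per metabolic day: K600 from the piecewise-linear
#' ln(K600)~ln(Q) relation at the daily mean ln(Q) times lognormal jitter;
#' GPP and ER from truncated normals respecting their sign conventions.
#'
#' @param config a [synthetic_config()]
#' @param forcing output of [generate_forcing()]
#' @return tibble with `date`, `GPP_true`, `ER_true`, `K600_true`,
#'   `mean_depth`, `mean_discharge`
#' @export
generate_truth <- function(config, forcing) {
  stopifnot(inherits(config, "synthetic_config"))
  dates <- sort(unique(forcing$date))
  D <- length(dates)
  lnQ_mean <- vapply(dates, function(d)
    mean(log(forcing$discharge[forcing$date == d])), numeric(1))
  lnk <- piecewise_lnk600(lnQ_mean, config$k600_nodes)
  withr::with_seed(config$seed + 1L, {
    jit <- if (config$k600_sdlog > 0) {
      stats::rnorm(D, 0, config$k600_sdlog)
    } else rep(0, D)
    gpp <- rtrunc_norm(D, config$gpp_mean, config$gpp_sd, lower = 0)
    er <- rtrunc_norm(D, config$er_mean, config$er_sd, upper = 0)
    tibble::tibble(
      date = dates,
      GPP_true = gpp,
      ER_true = er,
      K600_true = exp(lnk + jit),
      mean_depth = vapply(dates, function(d)
        mean(forcing$depth[forcing$date == d]), numeric(1)),
      mean_discharge = vapply(dates, function(d)
        mean(forcing$discharge[forcing$date == d]), numeric(1))
    )
  })
}

#' Generate noisy dissolved-oxygen observations
#'
#' Runs the forward simulator with the daily truth (process noise folded
#' into the state as the simulation advances), then adds Gaussian
#' observation noise to the recorded values. DO starts at saturation.
#'
#' @param truth output of [generate_truth()]
#' @param forcing output of [generate_forcing()]
#' @param config a [synthetic_config()]
#' @return the forcing tibble with `DO.obs` (and noise-free-state `DO.mod`
#'   with process noise included) attached
#' @export
generate_do <- function(truth, forcing, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(truth$date %in% forcing$date)) {
    stop("truth and forcing spans are misaligned")
  }
  daily <- tibble::tibble(date = truth$date, GPP = truth$GPP_true,
                          ER = truth$ER_true, K600 = truth$K600_true)
  sim <- forward_simulate(forcing, daily, o2_init = forcing$DO.sat[1],
                          sigma_proc = config$sigma_proc,
                          seed = config$seed + 2L)
  obs_noise <- withr::with_seed(config$seed + 3L, {
    if (config$sigma_obs > 0) {
      stats::rnorm(nrow(sim), 0, config$sigma_obs)
    } else rep(0, nrow(sim))
  })
  sim$DO.obs <- pmax(sim$DO.mod + obs_noise, 1e-6)
  sim
}

#' Generate synthetic channel field measurements
#'
#' Produces USGS-style episodic measurements consistent with true linear
#' depth and area ratings at the supplied gage heights, with multiplicative
#' lognormal noise; refitting the ratings from the output recovers the
#' generating coefficients exactly at zero noise.
#'
#' @param true_depth_rating,true_area_rating `c(m, b)` coefficients
#' @param gage_heights gage heights of the measurement visits, m
#' @param noise_sd lognormal sdlog of the multiplicative noise (fractional)
#' @param quality_labels quality ratings recycled over measurements
#' @param mean_velocity nominal section velocity used to invent a
#'   consistent discharge, m/s
#' @param seed RNG seed
#' @return tibble with `date`, `width`, `area`, `gage_height`, `discharge`,
#'   `rating`
#' @export
generate_field_measurements <- function(true_depth_rating, true_area_rating,
                                        gage_heights, noise_sd = 0.05,
                                        quality_labels = "good",
                                        mean_velocity = 0.5, seed = 1) {
  h_true <- true_depth_rating[["m"]] * gage_heights +
    true_depth_rating[["b"]]
  A_true <- true_area_rating[["m"]] * gage_heights +
    true_area_rating[["b"]]
  if (any(h_true <= 0) || any(A_true <= 0)) {
    stop("ratings imply non-positive depth or area at the supplied stages")
  }
  n <- length(gage_heights)
  withr::with_seed(seed, {
    jit <- function() if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else
      rep(1, n)
    A_fm <- A_true * jit()
    h_fm <- h_true * jit()
    q_fm <- A_fm * mean_velocity * jit()
    tibble::tibble(
      date = as.Date("2019-01-01") + seq_len(n) * 14,
      width = A_fm / h_fm,
      area = A_fm,
      gage_height = gage_heights,
      discharge = q_fm,
      rating = rep_len(quality_labels, n)
    )
  })
}
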