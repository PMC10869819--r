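# Preparation of raw sensor series into the gridded, unit-consistent,
# solar-time model input: regridding + gap filling, salinity from specific
# conductance, solar time, oxygen saturation, clear-sky light, assembly.

.canonical_units <- c(
  do = "mg/L", temp = "degC", spc = "uS/cm", sal = "PSU",
  discharge = "m3/s", gage_height = "m", pressure = "mb"
)

# multiplicative factors into the canonical unit of each kind
.unit_factors <- list(
  discharge = c("m3/s" = 1, "ft3/s" = 0.3048^3, "cfs" = 0.3048^3),
  gage_height = c("m" = 1, "ft" = 0.3048),
  pressure = c("mb" = 1, "hPa" = 1, "inHg" = 33.8639),
  do = c("mg/L" = 1),
  temp = c("degC" = 1),
  spc = c("uS/cm" = 1),
  sal = c("PSU" = 1)
)

#' Convert a series to its canonical unit
#'
#' @param values numeric vector
#' @param kind one of `"do"`, `"temp"`, `"spc"`, `"sal"`, `"discharge"`,
#'   `"gage_height"`, `"pressure"`
#' @param units source unit label
#' @return values in the canonical unit for `kind`
#' @export
convert_units <- function(values, kind, units) {
  kind <- match.arg(kind, names(.unit_factors))
  fac <- .unit_factors[[kind]]
  if (!units %in% names(fac)) {
    stop(sprintf("unknown unit '%s' for kind '%s' (expected one of: %s)",
                 units, kind, paste(names(fac), collapse = ", ")))
  }
  values * fac[[units]]
}

#' Regrid a raw series to a regular timestep and fill short gaps
#'
#' Aligns observations to a regular grid (default 15 minutes), linearly
#' interpolating interior gaps strictly shorter than `max_gap_hours`; longer
#' gaps are left missing, and nothing is extrapolated beyond the first or
#' last observation. Duplicate timestamps are averaged with a warning; unit
#' conversion to the canonical unit happens first.
#'
#' @param raw data.frame with columns `datetime` (POSIXct, UTC) and `value`
#' @param kind series kind, see [convert_units()]
#' @param units source unit (default: already canonical)
#' @param grid_minutes grid spacing in minutes
#' @param max_gap_hours gaps `>= max_gap_hours` are not filled
#' @return tibble with `datetime` on the grid and `value` (NA where unfilled)
#' @export
regrid_and_fill <- function(raw, kind, units = .canonical_units[[kind]],
                            grid_minutes = 15, max_gap_hours = 3) {
  stopifnot(all(c("datetime", "value") %in% names(raw)))
  ok <- !is.na(raw$value) & !is.na(raw$datetime)
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) == 0) {
    return(tibble::tibble(datetime = as.POSIXct(character(), tz = "UTC"),
                          value = numeric()))
  }
  val <- convert_units(raw$value, kind, units)
  t <- as.numeric(raw$datetime)
  o <- order(t)
  t <- t[o]; val <- val[o]
  if (anyDuplicated(t)) {
    warning("duplicate timestamps averaged")
    val <- as.numeric(tapply(val, t, mean))
    t <- sort(unique(t))
  }
  if (length(t) < 2) {
    grid <- t
  } else {
    step <- grid_minutes * 60
    grid <- seq(ceiling(t[1] / step) * step, floor(t[length(t)] / step) * step,
                by = step)
  }
  if (length(t) == 1) {
    out_val <- if (length(grid) && grid[1] == t[1]) val else NA_real_
    return(tibble::tibble(
      datetime = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
      value = out_val))
  }
  yi <- stats::approx(t, val, xout = grid)$y
  # mask grid points inside long observation gaps, except exact observations
  idx <- findInterval(grid, t)
  gap <- (t[pmin(idx + 1, length(t))] - t[idx])
  is_obs <- grid %in% t
  long_gap <- gap >= max_gap_hours * 3600 & !is_obs
  yi[long_gap] <- NA_real_
  tibble::tibble(
    datetime = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
    value = yi)
}

#' Practical salinity from specific conductance at 25 degC
#'
#' PSS-78 practical salinity evaluated at 25 degC from the conductivity
#' ratio to the KCl reference (53,087 uS/cm), offset so that zero
#' conductance maps to zero salinity and clamped at zero.
#'
#' @param spc specific conductance, uS/cm at 25 degC
#' @return practical salinity, PSU
#' @export
salinity_from_conductance <- function(spc) {
  if (any(spc < 0, na.rm = TRUE)) stop("specific conductance must be >= 0")
  a <- c(0.0080, -0.1692, 25.3851, 14.0941, -7.0261, 2.7081)
  b <- c(0.0005, -0.0056, -0.0066, -0.0375, 0.0636, -0.0144)
  pss <- function(R, T = 25) {
    rt <- sqrt(pmax(R, 0))
    powers <- cbind(1, rt, rt^2, rt^3, rt^4, rt^5)
    dS <- (T - 15) / (1 + 0.0162 * (T - 15)) * drop(powers %*% b)
    drop(powers %*% a) + dS
  }
  R <- spc / 53087
  pmax(0, pss(R) - pss(0))
}

#' Convert UTC time to mean solar time
#'
#' Shifts clock time by `longitude / 15` hours so that solar noons are
#' exactly 24 h apart (mean, not apparent, solar time).
#'
#' @param t_utc POSIXct in UTC
#' @param longitude degrees east (negative west), in `[-180, 180]`
#' @return POSIXct mean solar time (labelled UTC)
#' @export
utc_to_solar <- function(t_utc, longitude) {
  if (any(longitude < -180 | longitude > 180)) {
    stop("longitude must lie in [-180, 180]")
  }
  t_utc + longitude / 15 * 3600
}

#' Dissolved-oxygen saturation concentration
#'
#' Garcia-Gordon (Benson-Krause refit) equilibrium oxygen solubility with
#' salinity dependence, corrected for barometric pressure through the
#' vapor-pressure-adjusted ratio. Freshwater at 20 degC and 1013.25 mb
#' gives ~9.09 mg/L.
#'
#' @param temp water temperature, degC, in `[-1, 45]`
#' @param pressure barometric pressure, mb
#' @param salinity practical salinity, PSU
#' @return saturation concentration, mg O2/L
#' @export
do_saturation <- function(temp, pressure = 1013.25, salinity = 0) {
  if (any(temp < -1 | temp > 45, na.rm = TRUE)) {
    stop("temperature outside [-1, 45] degC")
  }
  if (any(pressure <= 0, na.rm = TRUE)) stop("pressure must be positive")
  Ts <- log((298.15 - temp) / (273.15 + temp))
  A <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  B <- c(-0.00624523, -0.00737614, -0.0103410, -0.00817083)
  C0 <- -4.88682e-07
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 +
    A[6] * Ts^5 +
    salinity * (B[1] + B[2] * Ts + B[3] * Ts^2 + B[4] * Ts^3) +
    C0 * salinity^2
  cstar <- exp(lnC) * 1.42905  # ml/L -> mg/L
  # vapor-pressure corrected barometric scaling
  tk <- temp + 273.15
  pwv_atm <- exp(11.8571 - 3840.70 / tk - 216961 / tk^2)
  pwv_mb <- pwv_atm * 1013.25
  cstar * (pressure - pwv_mb) / (1013.25 - pwv_mb)
}

#' Clear-sky photosynthetic photon flux density
#'
#' Theoretical cloud-free PPFD from the solar zenith angle at the given
#' mean solar time and latitude: zero when the sun is below the horizon,
#' maximal at solar noon, symmetric within a day. Only the within-day shape
#' matters for metabolism (daily GPP is apportioned by the normalized light
#' curve), so the absolute scale is a nominal full-sun maximum.
#'
#' @param solar_time POSIXct mean solar time
#' @param latitude degrees north
#' @param max_ppfd nominal full-sun PPFD, umol m-2 s-1
#' @return PPFD, umol photons m-2 s-1
#' @export
light_ppfd <- function(solar_time, latitude, max_ppfd = 2326) {
  if (any(latitude < -90 | latitude > 90)) stop("invalid latitude")
  lt <- as.POSIXlt(solar_time, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  H <- (hour - 12) / 24 * 2 * pi  # hour angle, radians
  phi <- latitude * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  pmax(0, cosz) * max_ppfd
}

#' Assemble gridded components into a model-input forcing series
#'
#' Merges DO, water temperature, salinity, pressure, discharge, gage height
#' and depth (all on the same UTC grid) into one solar-time forcing table,
#' attaches computed DO saturation and clear-sky light, and marks rows
#' lacking DO, temperature, or depth as unusable.
#'
#' @param do,temp,sal,barop,discharge,gage_height,depth gridded tibbles from
#'   [regrid_and_fill()] (`datetime`, `value`); `sal`, `barop`,
#'   `gage_height` may be NULL (defaults: 0 PSU, 1013.25 mb, NA)
#' @param latitude,longitude site coordinates, degrees
#' @return a `forcing_series` tibble with columns `solar.time`, `date`,
#'   `DO.obs`, `temp.water`, `salinity`, `pressure`, `discharge`,
#'   `gage.height`, `depth`, `DO.sat`, `light`, `usable`
#' @export
assemble_input <- function(do, temp, depth, discharge,
                           sal = NULL, barop = NULL, gage_height = NULL,
                           latitude, longitude) {
  grid <- do$datetime
  align <- function(x, default = NA_real_) {
    if (is.null(x)) return(rep(default, length(grid)))
    if (length(intersect(as.numeric(x$datetime), as.numeric(grid))) == 0) {
      stop("component time span does not overlap the DO grid")
    }
    x$value[match(as.numeric(grid), as.numeric(x$datetime))]
  }
  temp_v <- align(temp)
  out <- tibble::tibble(
    solar.time = utc_to_solar(grid, longitude),
    DO.obs = do$value,
    temp.water = temp_v,
    salinity = align(sal, 0),
    pressure = align(barop, 1013.25),
    discharge = align(discharge),
    gage.height = align(gage_height),
    depth = align(depth)
  )
  out$date <- metab_date(out$solar.time)
  out$DO.sat <- ifelse(is.na(out$temp.water), NA_real_,
                       do_saturation(pmin(pmax(out$temp.water, -1), 45),
                                     out$pressure, out$salinity))
  out$light <- light_ppfd(out$solar.time, latitude)
  out$usable <- !is.na(out$DO.obs) & !is.na(out$temp.water) &
    !is.na(out$depth) & out$depth > 0
  class(out) <- c("forcing_series", class(out))
  out
}
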