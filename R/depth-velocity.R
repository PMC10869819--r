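# Continuous river depth, cross-sectional area, and velocity from episodic
# USGS-style channel field measurements (linear stage ratings) or from
# hydraulic-geometry power laws.

#' Cross-section averaged depth from a field measurement
#'
#' Divides the measured flow cross-sectional area by the wetted width.
#'
#' @param A_fm field-measured cross-sectional area, m2
#' @param w_fm field-measured wetted width, m
#' @return depth, m
#' @export
depth_from_measurement <- function(A_fm, w_fm) {
  if (any(w_fm <= 0, na.rm = TRUE)) stop("wetted width must be positive")
  A_fm / w_fm
}

#' Fit a linear stage rating for depth or cross-sectional area
#'
#' Ordinary least-squares regression of field-measured depth (area / width)
#' or area on gage height. Measurements quality-rated "poor" are excluded
#' when `exclude_poor = TRUE`; if that leaves fewer than two points the fit
#' falls back to including them with a warning, mirroring field practice at
#' sites where most measurements are poor-rated.
#'
#' @param measurements data.frame with columns `gage_height`, `width`,
#'   `area`, and `rating` (one of excellent/good/fair/poor)
#' @param target `"depth"` or `"area"`
#' @param exclude_poor drop poor-rated measurements before fitting
#' @return a `rating_curve` object: list with `target`, `slope`,
#'   `intercept`, `n_points`, `r_squared`, `excluded_poor`
#' @export
fit_rating <- function(measurements, target = c("depth", "area"),
                       exclude_poor = TRUE) {
  target <- match.arg(target)
  m <- measurements
  stopifnot(all(c("gage_height", "area") %in% names(m)))
  used_exclusion <- isTRUE(exclude_poor)
  if (used_exclusion) {
    keep <- is.na(m$rating) | tolower(m$rating) != "poor"
    if (sum(keep) < 2) {
      if (nrow(m) < 2) {
        stop("fewer than 2 usable field measurements (exclude_poor = TRUE)")
      }
      warning("fewer than 2 non-poor measurements; including poor-rated ones")
      used_exclusion <- FALSE
    } else {
      m <- m[keep, , drop = FALSE]
    }
  }
  if (nrow(m) < 2) {
    stop("fewer than 2 usable field measurements (exclude_poor = ",
         exclude_poor, ")")
  }
  y <- if (target == "depth") depth_from_measurement(m$area, m$width) else m$area
  fit <- stats::lm(y ~ m$gage_height)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(
    target = target,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = nrow(m),
    r_squared = r2,
    excluded_poor = used_exclusion
  ), class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  cat(sprintf(
    "Linear %s rating: %s = %.4f * GH + %.4f  (n = %d, r^2 = %.3f%s)\n",
    x$target, if (x$target == "depth") "h" else "A",
    x$slope, x$intercept, x$n_points, x$r_squared,
    if (x$excluded_poor) ", poor-rated excluded" else ""))
  invisible(x)
}

#' Predict a continuous depth or area series from a rating curve
#'
#' Evaluates `slope * GH + intercept` elementwise. Non-positive predictions
#' are physically meaningless (e.g. strongly negative intercept at low
#' stage) and are returned but flagged.
#'
#' @param curve a [fit_rating()] result
#' @param gage_height gage height series, m
#' @return tibble with `value` and logical `flagged_nonphysical`
#' @export
predict_series <- function(curve, gage_height) {
  stopifnot(inherits(curve, "rating_curve"))
  v <- curve$slope * gage_height + curve$intercept
  tibble::tibble(value = v,
                 flagged_nonphysical = !is.na(v) & v <= 0)
}

#' Depth from hydraulic geometry
#'
#' Power-law depth `h = c * Q^f` with reach-scale hydraulic-geometry
#' coefficients, for sites where the gaging cross section is not
#' representative of upstream conditions.
#'
#' @param coeffs list or data.frame with elements `c` and `f`
#' @param Q discharge series, m3/s
#' @return depth series, m (NA where `Q <= 0`)
#' @export
depth_hydraulic <- function(coeffs, Q) {
  cc <- coeffs$c; ff <- coeffs$f
  if (is.null(cc) || is.null(ff) || cc <= 0) {
    stop("hydraulic coefficients must include c > 0 and f")
  }
  out <- ifelse(!is.na(Q) & Q > 0, cc * Q^ff, NA_real_)
  out
}

#' Daily cross-section averaged velocity
#'
#' Divides daily mean discharge by the cross-sectional area predicted from
#' the area rating at the daily mean gage height, converted to m/day.
#'
#' @param Q_daily daily mean discharge, m3/s
#' @param area_curve an area [fit_rating()] result
#' @param gage_height_daily daily mean gage height, m
#' @return velocity, m/day (NA where predicted area `<= 0`)
#' @export
velocity_series <- function(Q_daily, area_curve, gage_height_daily) {
  stopifnot(identical(area_curve$target, "area"))
  A <- predict_series(area_curve, gage_height_daily)$value
  v <- ifelse(!is.na(A) & A > 0, Q_daily / A * 86400, NA_real_)
  v
}

#' Read hydraulic-geometry coefficients
#'
#' Whitespace-delimited table with columns `site_no`, `a`, `b`, `c`, `f`
#' for the width (`B = a Q^b`) and depth (`h = c Q^f`) power laws.
#'
#' @param path file path
#' @return tibble of coefficients keyed by site
#' @export
read_hydraulic_coeffs <- function(path) {
  x <- utils::read.table(path, header = TRUE, comment.char = "#",
                         colClasses = c(site_no = "character"))
  tibble::as_tibble(x)
}
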