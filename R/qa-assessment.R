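# Daily quality flags, censoring, metabolism reach-length screening, the
# five-criterion site confidence rubric with its combination rule, and
# site/basin summaries.

#' Metabolism reach length
#'
#' Upstream distance over which 80% of water-column oxygen turns over by
#' gas exchange: `-ln(1 - 0.8) * v / K_O2` = `1.6094 * v / K_O2`.
#'
#' @param v cross-section averaged velocity, m/day
#' @param K_O2 oxygen-specific gas-exchange coefficient, 1/day (from daily
#'   K600 and temperature via [k600_to_kgas()])
#' @return reach length, m (NA where `K_O2 <= 0`)
#' @export
reach_length <- function(v, K_O2) {
  if (any(v < 0, na.rm = TRUE)) stop("velocity must be >= 0")
  ifelse(!is.na(K_O2) & K_O2 > 0, -log(1 - 0.8) * v / K_O2, NA_real_)
}

#' Apply the four daily quality flags
#'
#' Flag 1 (low signal-to-noise): active only when the site's 15th
#' percentile of daily R2_det is negative, in which case days below that
#' percentile are flagged. Flag 2: GPP < -0.5. Flag 3: ER > +0.5.
#' Flag 4: K600 > 20.
#'
#' @param daily tibble with `GPP`, `ER`, `K600`, and `R2_det` per day
#' @return tibble of logicals `flag1_low_snr`, `flag2_gpp`, `flag3_er`,
#'   `flag4_k600`, `any_flag`
#' @export
apply_flags <- function(daily) {
  if (nrow(daily) == 0) stop("empty daily record")
  r2 <- daily$R2_det
  q15 <- stats::quantile(r2, 0.15, na.rm = TRUE, names = FALSE)
  flag1 <- if (!is.na(q15) && q15 < 0) {
    !is.na(r2) & r2 < q15
  } else {
    rep(FALSE, nrow(daily))
  }
  flag2 <- !is.na(daily$GPP) & daily$GPP < -0.5
  flag3 <- !is.na(daily$ER) & daily$ER > 0.5
  flag4 <- !is.na(daily$K600) & daily$K600 > 20
  tibble::tibble(
    flag1_low_snr = flag1, flag2_gpp = flag2, flag3_er = flag3,
    flag4_k600 = flag4,
    any_flag = flag1 | flag2 | flag3 | flag4
  )
}

#' Censor flagged days
#'
#' Subset of the daily record with no flag set, in original order.
#'
#' @param daily daily metabolism tibble
#' @param flags output of [apply_flags()] aligned with `daily`
#' @return censored tibble (possibly empty)
#' @export
censor <- function(daily, flags) {
  stopifnot(nrow(daily) == nrow(flags))
  daily[!flags$any_flag, , drop = FALSE]
}

.rate_pct_bad <- function(pct) {
  if (is.na(pct)) return(NA_character_)
  if (pct < 25) "HIGH" else if (pct < 50) "MEDIUM" else "LOW"
}

#' Five-criterion site confidence assessment
#'
#' Criterion 1/2: percent of days with biologically unrealistic GPP
#' (< -0.5) / ER (> +0.5) — HIGH below 25%, MEDIUM in [25, 50), LOW at or
#' above 50%. Criterion 3: 90th-10th percentile range of K600 — HIGH below
#' 15, MEDIUM in [15, 50], LOW above 50. Criterion 4: HIGH when both the
#' process-error and K600 Gelman-Rubin statistics are below 1.2, else LOW
#' (no MEDIUM). Criterion 5: HIGH when the upstream flow-regulation
#' distance exceeds the daily metabolism reach length on more than 80% of
#' days, MEDIUM on more than 50% up to 80%, LOW otherwise. Overall rating:
#' HIGH only if all five are HIGH, LOW if any is LOW, else MEDIUM; a
#' missing criterion 5 caps the overall rating at MEDIUM.
#'
#' @param daily daily metabolism tibble (`GPP`, `ER`, `K600`)
#' @param diag a `fit_diagnostics` object (or list with
#'   `rhat_sigma_proc`, `rhat_sigma_K600`)
#' @param reach_lengths_m daily metabolism reach lengths, m
#' @param upstream_structure_distance_m static distance to the nearest
#'   upstream flow regulation, m (NA if unknown)
#' @return a `confidence_assessment` list with `c1_gpp_rating` ...
#'   `c5_reach_rating` and `overall`
#' @export
assess_confidence <- function(daily, diag, reach_lengths_m = NULL,
                              upstream_structure_distance_m = NA_real_) {
  n <- nrow(daily)
  if (n == 0) stop("empty daily record")
  c1 <- .rate_pct_bad(100 * mean(daily$GPP < -0.5, na.rm = TRUE))
  c2 <- .rate_pct_bad(100 * mean(daily$ER > 0.5, na.rm = TRUE))
  kr <- diff(stats::quantile(daily$K600, c(0.1, 0.9), na.rm = TRUE,
                             names = FALSE))
  c3 <- if (is.na(kr)) NA_character_ else if (kr < 15) "HIGH" else
    if (kr <= 50) "MEDIUM" else "LOW"
  c4 <- if (is.null(diag)) NA_character_ else {
    rh <- c(diag$rhat_sigma_proc, diag$rhat_sigma_K600)
    if (all(is.na(rh))) NA_character_ else
      if (all(rh < 1.2, na.rm = TRUE)) "HIGH" else "LOW"
  }
  c5 <- if (is.na(upstream_structure_distance_m) ||
            is.null(reach_lengths_m) || all(is.na(reach_lengths_m))) {
    NA_character_
  } else {
    pct_ok <- 100 * mean(upstream_structure_distance_m > reach_lengths_m,
                         na.rm = TRUE)
    if (pct_ok > 80) "HIGH" else if (pct_ok > 50) "MEDIUM" else "LOW"
  }
  ratings <- c(c1_gpp_rating = c1, c2_er_rating = c2,
               c3_k600_range_rating = c3, c4_convergence_rating = c4,
               c5_reach_rating = c5)
  overall <- if (any(ratings == "LOW", na.rm = TRUE)) {
    "LOW"
  } else if (!anyNA(ratings) && all(ratings == "HIGH")) {
    "HIGH"
  } else {
    "MEDIUM"  # mixed ratings, or a missing criterion caps at MEDIUM
  }
  structure(c(as.list(ratings), list(overall = overall)),
            class = "confidence_assessment")
}

#' @export
print.confidence_assessment <- function(x, ...) {
  cat(sprintf(
    "Confidence: overall %s (c1 %s, c2 %s, c3 %s, c4 %s, c5 %s)\n",
    x$overall, x$c1_gpp_rating, x$c2_er_rating, x$c3_k600_range_rating,
    x$c4_convergence_rating, x$c5_reach_rating))
  invisible(x)
}

#' Site-level metabolism summary
#'
#' Means and standard deviations of discharge, GPP, ER and NEP over the
#' unflagged days, and the percent of unflagged days that were autotrophic
#' (NEP > 0), rounded half-up to an integer.
#'
#' @param daily daily metabolism tibble (`GPP`, `ER`, `NEP`)
#' @param flags output of [apply_flags()]
#' @param discharge_daily daily mean discharge aligned with `daily`, m3/s
#' @return one-row tibble of summary statistics
#' @export
site_summary <- function(daily, flags, discharge_daily = NULL) {
  stopifnot(nrow(daily) == nrow(flags))
  keep <- !flags$any_flag
  d <- daily[keep, , drop = FALSE]
  q <- if (is.null(discharge_daily)) rep(NA_real_, nrow(daily)) else
    discharge_daily
  q <- q[keep]
  n_un <- nrow(d)
  if (n_un == 0) {
    return(tibble::tibble(
      n_days = nrow(daily), n_days_unflagged = 0L, pct_unflagged = 0,
      q_mean = NA_real_, q_sd = NA_real_, gpp_mean = NA_real_,
      gpp_sd = NA_real_, er_mean = NA_real_, er_sd = NA_real_,
      nep_mean = NA_real_, nep_sd = NA_real_,
      pct_autotrophic = NA_real_))
  }
  nep <- if (!is.null(d$NEP)) d$NEP else d$GPP + d$ER
  tibble::tibble(
    n_days = nrow(daily),
    n_days_unflagged = n_un,
    pct_unflagged = 100 * n_un / nrow(daily),
    q_mean = mean(q, na.rm = TRUE), q_sd = stats::sd(q[!is.na(q)]),
    gpp_mean = mean(d$GPP), gpp_sd = stats::sd(d$GPP),
    er_mean = mean(d$ER), er_sd = stats::sd(d$ER),
    nep_mean = mean(nep), nep_sd = stats::sd(nep),
    pct_autotrophic = round_half_up(100 * mean(nep > 0))
  )
}

#' Basin-level rollup of site summaries
#'
#' Unweighted across-site means of GPP, ER, NEP and flagged-day percentage,
#' group means of the percent-autotrophic column when a `river_group`
#' column is present, and a tally of overall confidence ratings when a
#' `confidence` column is present.
#'
#' @param summaries tibble of per-site rows with columns `gpp_mean`,
#'   `er_mean`, `nep_mean`, `pct_unflagged`, `pct_autotrophic`, and
#'   optionally `river_group` and `confidence`
#' @return list with `n_sites`, `mean_gpp`, `mean_er`, `mean_nep`,
#'   `mean_pct_flagged`, `pct_autotrophic_by_group` (named vector or NULL),
#'   `confidence_counts`, `pct_high_or_medium`
#' @export
basin_rollup <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  out <- list(
    n_sites = nrow(summaries),
    mean_gpp = mean(summaries$gpp_mean, na.rm = TRUE),
    mean_er = mean(summaries$er_mean, na.rm = TRUE),
    mean_nep = mean(summaries$nep_mean, na.rm = TRUE),
    mean_pct_flagged = mean(100 - summaries$pct_unflagged, na.rm = TRUE)
  )
  out$pct_autotrophic_by_group <- if (!is.null(summaries$river_group)) {
    grp <- split(summaries$pct_autotrophic, summaries$river_group)
    vapply(grp, function(x) round_half_up(mean(x, na.rm = TRUE)),
           numeric(1))
  } else NULL
  if (!is.null(summaries$confidence)) {
    conf <- toupper(summaries$confidence)
    out$confidence_counts <- table(factor(conf,
                                          levels = c("HIGH", "MEDIUM", "LOW")))
    out$pct_high_or_medium <- 100 * mean(conf %in% c("HIGH", "MEDIUM"))
  } else {
    out$confidence_counts <- NULL
    out$pct_high_or_medium <- NA_real_
  }
  out
}
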