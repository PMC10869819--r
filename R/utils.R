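# Small numerical helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used for the percent-autotrophic column of the site summaries.
#' Base `round()` rounds half to even, which would print 42.5% as 42.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Draw from a truncated normal by inverse-CDF
#'
#' One-sided truncation; `sd = 0` collapses to the mean (clamped to the
#' allowed side). Used for daily GPP (lower = 0) and ER (upper = 0) truth.
#'
#' @param n number of draws
#' @param mean,sd normal parameters
#' @param lower,upper truncation bounds (at most one finite)
#' @return numeric vector of draws
#' @keywords internal
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Piecewise-linear interpolation of ln(K600) on ln(Q)
#'
#' Linear between nodes, constant beyond the outermost nodes; a single node
#' gives a constant relation.
#'
#' @param lnQ numeric vector of log discharge values
#' @param nodes data.frame with columns `lnQ` and `lnK600`
#' @return interpolated lnK600 at `lnQ`
#' @export
piecewise_lnk600 <- function(lnQ, nodes) {
  if (is.null(nodes) || nrow(nodes) == 0) {
    stop("at least one (lnQ, lnK600) node is required")
  }
  if (any(!is.finite(nodes$lnK600))) stop("node lnK600 values must be finite")
  if (nrow(nodes) == 1) {
    return(rep(nodes$lnK600[1], length(lnQ)))
  }
  o <- order(nodes$lnQ)
  stats::approx(nodes$lnQ[o], nodes$lnK600[o], xout = lnQ, rule = 2)$y
}

#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed on chains split in half, the
#' diagnostic screened against the 1.1 (convergence) and 1.2 (confidence
#' rubric) thresholds.
#'
#' @param draws iterations x chains matrix
#' @return scalar R-hat (NA for degenerate input)
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  pieces <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(pieces)
  nn <- nrow(pieces)
  mu <- colMeans(pieces)
  va <- apply(pieces, 2, stats::var)
  W <- mean(va)
  B <- nn * stats::var(mu)
  if (!is.finite(W) || W <= 0) {
    # all chains constant and identical -> perfectly converged
    return(if (isTRUE(all.equal(B, 0)) || !is.finite(B)) 1 else Inf)
  }
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

# Metabolic-day assignment: solar timestamps before `day_start_hour` belong
# to the previous day's metabolic window (04:00 -> 28:00 by default).
metab_date <- function(solar_time, day_start_hour = 4) {
  as.Date(solar_time - day_start_hour * 3600, tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
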