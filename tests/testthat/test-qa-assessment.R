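# Daily flags, censoring, reach length, confidence rubric, summaries.

mk_daily <- function(GPP = 2, ER = -5, K600 = 3, R2_det = 0.8, n = NULL) {
  if (is.null(n)) n <- max(lengths(list(GPP, ER, K600, R2_det)))
  tibble::tibble(date = as.Date("2020-06-01") + seq_len(n) - 1,
                 GPP = rep_len(GPP, n), ER = rep_len(ER, n),
                 K600 = rep_len(K600, n), R2_det = rep_len(R2_det, n),
                 NEP = rep_len(GPP, n) + rep_len(ER, n))
}

test_that("metabolism reach length is -ln(0.2) v / K_O2", {
  expect_equal(reach_length(10000, 2), 8047.19, tolerance = 1e-4)
  expect_equal(reach_length(0, 2), 0)
  expect_equal(reach_length(20000, 2), 2 * reach_length(10000, 2))
  expect_true(is.na(reach_length(10000, 0)))
  expect_error(reach_length(-5, 2), "velocity")
})

test_that("daily flags apply the biological and physical thresholds", {
  d <- mk_daily(GPP = c(-0.6, -0.4, 2), ER = c(-5, -5, -5),
                K600 = c(3, 3, 3))
  fl <- apply_flags(d)
  expect_equal(fl$flag2_gpp, c(TRUE, FALSE, FALSE))

  d2 <- mk_daily(GPP = 2, ER = c(0.6, 0.5, -5), K600 = 3)
  expect_equal(apply_flags(d2)$flag3_er, c(TRUE, FALSE, FALSE))

  d3 <- mk_daily(GPP = 2, ER = -5, K600 = c(25, 20, 3))
  expect_equal(apply_flags(d3)$flag4_k600, c(TRUE, FALSE, FALSE))
  expect_equal(apply_flags(d3)$any_flag, c(TRUE, FALSE, FALSE))
})

test_that("flag 1 activates only when the R2 15th percentile is negative", {
  # healthy site: 15th percentile positive, no flag regardless of low days
  r2_good <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99)
  expect_false(any(apply_flags(mk_daily(R2_det = r2_good))$flag1_low_snr))
  # noisy site: negative 15th percentile flags the days below it
  r2_bad <- c(-0.9, -0.8, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  fl <- apply_flags(mk_daily(R2_det = r2_bad))
  q15 <- quantile(r2_bad, 0.15, names = FALSE)
  expect_lt(q15, 0)
  expect_equal(fl$flag1_low_snr, r2_bad < q15)
})

test_that("censoring removes exactly the flagged days in order", {
  d <- mk_daily(GPP = c(2, -0.6, 2, 2, -0.7, 2, 2, 2, 2, 2),
                K600 = c(3, 3, 25, 3, 3, 3, 3, 3, 3, 3))
  fl <- apply_flags(d)
  cen <- censor(d, fl)
  expect_equal(nrow(cen), 7)
  expect_identical(cen$date, d$date[!fl$any_flag])
  # no flags -> identity; all flagged -> empty, not an error
  clean <- mk_daily(n = 5)
  expect_identical(censor(clean, apply_flags(clean)), clean)
  allbad <- mk_daily(GPP = -1, n = 4)
  expect_equal(nrow(censor(allbad, apply_flags(allbad))), 0)
})

test_that("confidence criteria reproduce the rubric bins", {
  diag_ok <- list(rhat_sigma_proc = 1.0, rhat_sigma_K600 = 1.0)
  make_site <- function(pct_bad_gpp, n = 100) {
    nbad <- round(n * pct_bad_gpp / 100)
    mk_daily(GPP = c(rep(-0.6, nbad), rep(2, n - nbad)), n = n)
  }
  for (case in list(c(10, "HIGH"), c(30, "MEDIUM"), c(60, "LOW"),
                    c(25, "MEDIUM"), c(50, "LOW"))) {
    conf <- assess_confidence(make_site(as.numeric(case[1])), diag_ok,
                              reach_lengths_m = rep(100, 100),
                              upstream_structure_distance_m = 1e5)
    expect_equal(conf$c1_gpp_rating, case[2])
  }
  # K600 spread bins: < 15 HIGH, 15-50 MEDIUM (50 inclusive), > 50 LOW
  k_site <- function(spread) mk_daily(K600 = seq(1, 1 + spread,
                                                 length.out = 100), n = 100)
  args <- list(diag_ok, reach_lengths_m = rep(100, 100),
               upstream_structure_distance_m = 1e5)
  expect_equal(do.call(assess_confidence, c(list(k_site(10)), args))
               $c3_k600_range_rating, "HIGH")
  expect_equal(do.call(assess_confidence, c(list(k_site(40)), args))
               $c3_k600_range_rating, "MEDIUM")
  expect_equal(do.call(assess_confidence, c(list(k_site(80)), args))
               $c3_k600_range_rating, "LOW")
  # convergence criterion has no MEDIUM and uses the 1.2 threshold
  conf_bad <- assess_confidence(mk_daily(n = 10),
                                list(rhat_sigma_proc = 1.0,
                                     rhat_sigma_K600 = 1.25),
                                rep(100, 10), 1e5)
  expect_equal(conf_bad$c4_convergence_rating, "LOW")
  expect_equal(conf_bad$overall, "LOW")
  # reach criterion percent-of-days bins
  reach_site <- function(pct_ok) {
    r <- c(rep(10, pct_ok), rep(1e6, 100 - pct_ok))
    assess_confidence(mk_daily(n = 100), diag_ok, r,
                      upstream_structure_distance_m = 1000)$c5_reach_rating
  }
  expect_equal(reach_site(90), "HIGH")
  expect_equal(reach_site(70), "MEDIUM")
  expect_equal(reach_site(40), "LOW")
})

test_that("overall confidence follows the combination rule monotonically", {
  diag_for <- function(c4) list(rhat_sigma_proc = 1.0,
                                rhat_sigma_K600 = if (c4 == "HIGH") 1.0
                                else 1.3)
  # all HIGH -> HIGH; one MEDIUM -> MEDIUM; one LOW -> LOW
  all_high <- assess_confidence(mk_daily(n = 20), diag_for("HIGH"),
                                rep(10, 20), 1e5)
  expect_equal(unname(unlist(all_high[1:5])), rep("HIGH", 5))
  expect_equal(all_high$overall, "HIGH")
  one_med <- assess_confidence(
    mk_daily(GPP = c(rep(-0.6, 6), rep(2, 14)), n = 20),
    diag_for("HIGH"), rep(10, 20), 1e5)
  expect_equal(one_med$c1_gpp_rating, "MEDIUM")
  expect_equal(one_med$overall, "MEDIUM")
  one_low <- assess_confidence(mk_daily(n = 20), diag_for("LOW"),
                               rep(10, 20), 1e5)
  expect_equal(one_low$overall, "LOW")
  # upgrading a single criterion never downgrades the overall rating
  lv <- c(LOW = 1, MEDIUM = 2, HIGH = 3)
  expect_true(lv[[one_med$overall]] <= lv[[all_high$overall]])
  expect_true(lv[[one_low$overall]] <= lv[[one_med$overall]])
  # missing upstream distance caps the overall rating at MEDIUM
  missing5 <- assess_confidence(mk_daily(n = 20), diag_for("HIGH"),
                                rep(10, 20), NA)
  expect_true(is.na(missing5$c5_reach_rating))
  expect_equal(missing5$overall, "MEDIUM")
})

test_that("site summary averages unflagged days and counts autotrophy", {
  d <- mk_daily(GPP = c(2, 1), ER = c(-1, -2), n = 2)
  s <- site_summary(d, apply_flags(d), c(10, 20))
  expect_equal(s$pct_autotrophic, 50)  # NEP = +1 and -1
  expect_equal(s$q_mean, 15)
  d2 <- mk_daily(GPP = 1, ER = -2, n = 4)
  expect_equal(site_summary(d2, apply_flags(d2))$pct_autotrophic, 0)
  # flagged days are excluded from the averages
  d3 <- mk_daily(GPP = c(2, 2, -0.6), ER = -1, n = 3)
  s3 <- site_summary(d3, apply_flags(d3))
  expect_equal(s3$gpp_mean, 2)
  expect_equal(s3$n_days_unflagged, 2L)
  # censor-then-summarize consistency
  cen <- censor(d3, apply_flags(d3))
  expect_equal(mean(cen$GPP), s3$gpp_mean)
  # empty after censoring yields missing values, not an error
  allbad <- mk_daily(GPP = -1, n = 3)
  s0 <- site_summary(allbad, apply_flags(allbad))
  expect_true(is.na(s0$gpp_mean))
  expect_equal(s0$n_days_unflagged, 0L)
})

test_that("basin rollup averages sites and tallies confidence", {
  one <- tibble::tibble(gpp_mean = 2, er_mean = -5, nep_mean = -3,
                        pct_unflagged = 80, pct_autotrophic = 10,
                        river_group = "A", confidence = "HIGH")
  r1 <- basin_rollup(one)
  expect_equal(r1$mean_gpp, 2)
  expect_equal(r1$mean_pct_flagged, 20)
  expect_equal(r1$pct_high_or_medium, 100)
  two <- rbind(one, tibble::tibble(gpp_mean = 4, er_mean = -7,
                                   nep_mean = -3, pct_unflagged = 60,
                                   pct_autotrophic = 31, river_group = "A",
                                   confidence = "LOW"))
  r2 <- basin_rollup(two)
  expect_equal(r2$mean_gpp, 3)
  expect_equal(unname(r2$pct_autotrophic_by_group["A"]), 21)  # 20.5 up
  expect_equal(r2$pct_high_or_medium, 50)
})
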