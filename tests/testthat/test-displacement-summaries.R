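test_that("max_abs_displacement takes the per-axis maximum of |displacement|", {
  tr <- cohort_from_values(list(list(c(0, -3, 2))), axis = "AP")[1:3, ]
  expect_equal(unname(max_abs_displacement(tr)["AP"]), 3)
  zero <- cohort_from_values(list(list(c(0, 0, 0))))
  expect_equal(unname(max_abs_displacement(zero)), c(0, 0, 0))
  expect_error(max_abs_displacement(zero[0, ]), "Empty")
})

test_that("max_abs_displacement is sign-symmetric and monotone under subsetting", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    tr <- tibble::tibble(
      technique = "T", patient_id = "P01", fraction_id = "F01",
      time_s = (seq_len(n) - 1) / 4,
      si_mm = c(0, rnorm(n - 1)), ap_mm = c(0, rnorm(n - 1)),
      lr_mm = c(0, rnorm(n - 1)))
    flipped <- tr
    flipped[c("si_mm", "ap_mm", "lr_mm")] <-
      -flipped[c("si_mm", "ap_mm", "lr_mm")]
    expect_equal(max_abs_displacement(flipped), max_abs_displacement(tr))
    keep <- sort(sample(n, sample(2:n, 1)))
    expect_true(all(max_abs_displacement(tr[keep, ]) <=
                      max_abs_displacement(tr)))
  }
})

test_that("fraction and patient summaries follow the stated arithmetic", {
  ## three fractions whose AP maxima are 1, 2, 3 mm
  vals <- list(list(c(0, 1, -0.5), c(0, -2, 1), c(0, 3, 2)))
  co <- cohort_from_values(vals, axis = "AP")
  fr <- summarize_fractions(co)
  ap <- fr[fr$axis == "AP", ]
  expect_equal(ap$max_abs_mm, c(1, 2, 3))
  expect_equal(ap$signed_at_max_mm, c(1, -2, 3))
  expect_equal(ap$duration_s, rep(0.5, 3))
  expect_equal(ap$mean_mm, c(mean(c(0, 1, -0.5)), mean(c(0, -2, 1)),
                             mean(c(0, 3, 2))))
  expect_equal(ap$sd_mm, c(sd(c(0, 1, -0.5)), sd(c(0, -2, 1)),
                           sd(c(0, 3, 2))))

  pt <- summarize_patients(fr)
  pap <- pt[pt$axis == "AP", ]
  expect_equal(pap$n_fractions, 3L)
  expect_equal(pap$mean_of_max_mm, 2)
  expect_equal(pap$sd_of_max_mm, 1)

  ## single fraction: SD of maxima defined as 0
  one <- summarize_patients(cohort_from_values(list(list(c(0, 1)))))
  expect_equal(one$sd_of_max_mm, rep(0, 3))
})

test_that("known pulse schedules appear as the fraction maxima", {
  cfg <- sim_config(n_patients = 1, fractions_per_patient = 3,
                    duration_s = 40, overall_mean_mm = 0, sigma_pt_mm = 0,
                    sigma_fr_mm = 0, sigma_intra_mm = 0, seed = 2)
  co <- simulate_cohort(cfg)
  peaks <- c(2.5, 9.7, 4.1)
  traces <- split(co, co$fraction_id)
  bumped <- dplyr::bind_rows(lapply(1:3, function(i)
    inject_gas_event(traces[[i]], onset_s = 10, amplitude_mm = peaks[i],
                     duration_s = 10)))
  fr <- summarize_fractions(bumped)
  expect_equal(fr$max_abs_mm[fr$axis == "AP"], peaks)
})

test_that("mean_abs_curve averages |displacement| over active fractions", {
  ## zero cohort -> zero curve
  zero <- simulate_cohort(sim_config(n_patients = 2,
                                     fractions_per_patient = 1,
                                     duration_s = 5, overall_mean_mm = 0,
                                     sigma_pt_mm = 0, sigma_fr_mm = 0,
                                     sigma_intra_mm = 0, seed = 1))
  cv <- mean_abs_curve(zero)
  expect_true(all(cv$mean_abs_mm == 0))

  ## constant 1 mm trace (after the zero reference sample) -> curve of the
  ## within-bin mean; bins past the first hold exactly 1
  tr <- tibble::tibble(technique = "T", patient_id = "P01",
                       fraction_id = "F01", time_s = seq(0, 9.75, by = 0.25),
                       si_mm = 0, ap_mm = c(0, rep(1, 39)), lr_mm = 0)
  cv <- mean_abs_curve(tr, bin_s = 1)
  ap <- cv[cv$axis == "AP", ]
  expect_equal(ap$mean_abs_mm[-1], rep(1, 9))
  expect_equal(ap$mean_abs_mm[1], 3 / 4)

  ## 60 s and 120 s traces: bins after 60 s only see the long one
  mk <- function(id, dur, val) tibble::tibble(
    technique = "T", patient_id = id, fraction_id = "F01",
    time_s = seq(0, dur, by = 0.25), si_mm = 0,
    ap_mm = c(0, rep(val, dur * 4)), lr_mm = 0)
  co <- dplyr::bind_rows(mk("P01", 60, 2), mk("P02", 120, 4))
  cv <- mean_abs_curve(co, bin_s = 1)
  ap <- cv[cv$axis == "AP", ]
  expect_equal(ap$mean_abs_mm[ap$time_bin_s == 30], 3)       # both active
  expect_equal(ap$n_fractions[ap$time_bin_s == 30], 2L)
  expect_equal(ap$mean_abs_mm[ap$time_bin_s == 90], 4)       # only the long
  expect_equal(ap$n_fractions[ap$time_bin_s == 90], 1L)
  ## direct recomputation of one shared bin
  manual <- mean(abs(co$ap_mm[co$time_s >= 10 & co$time_s < 11]))
  expect_equal(ap$mean_abs_mm[ap$time_bin_s == 10], manual)

  expect_error(mean_abs_curve(co, bin_s = 0), "bin_s")
})

test_that("wilcoxon_compare matches exact enumeration and handles edge cases", {
  res <- wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)   # 2/20 rank assignments as extreme
  expect_equal(res$statistic, 0)

  expect_warning(res <- wilcoxon_compare(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(res$p_value, 1)

  ## exact path agrees with wilcox.test's exact p when there are no ties
  set.seed(32)
  for (i in 1:5) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    ours <- wilcoxon_compare(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("two-sided rank-sum p is symmetric in its arguments", {
  set.seed(33)
  small_a <- rnorm(6); small_b <- rnorm(7) + 0.5
  large_a <- rnorm(30); large_b <- rnorm(25) + 0.3
  for (pair in list(list(small_a, small_b), list(large_a, large_b))) {
    p1 <- wilcoxon_compare(pair[[1]], pair[[2]])$p_value
    p2 <- wilcoxon_compare(pair[[2]], pair[[1]])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("a large simulated shift is detected between techniques", {
  a <- simulate_cohort(sim_config(n_patients = 3, fractions_per_patient = 10,
                                  duration_s = 30, overall_mean_mm = 0,
                                  sigma_pt_mm = 0, sigma_fr_mm = 0.2,
                                  sigma_intra_mm = 0.2,
                                  technique = "SS-IMRT", seed = 34))
  b <- simulate_cohort(sim_config(n_patients = 3, fractions_per_patient = 10,
                                  duration_s = 30,
                                  overall_mean_mm = c(0, 3, 0),
                                  sigma_pt_mm = 0, sigma_fr_mm = 0.2,
                                  sigma_intra_mm = 0.2,
                                  technique = "VMAT", seed = 35))
  b$patient_id <- paste0("V", b$patient_id)
  cmp <- compare_techniques(dplyr::bind_rows(a, b))
  expect_lt(cmp$p_value[cmp$axis == "AP"], 0.05)
  expect_equal(cmp$n_a, rep(30L, 3))
})
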