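test_that("moment estimators reproduce hand arithmetic", {
  ## 2 patients x 1 fraction x 2 samples: {0,2} and {4,6}
  co <- cohort_from_values(list(list(c(0, 2)), list(c(4, 6))), axis = "AP")
  mo <- moment_components(co, axes = "AP")
  expect_equal(mo$sigma_pt_mm, sd(c(1, 5)))          # 2*sqrt(2)
  expect_equal(mo$sigma_pt_mm, 2 * sqrt(2))
  expect_equal(mo$sigma_intra_mm, sqrt(2))           # RMS of {sqrt2, sqrt2}
  expect_equal(mo$sigma_fr_mm, 0)                    # no replicate fractions
  expect_equal(mo$overall_mean_mm, 3)

  ## constant per-patient offsets: random components 0, Sigma = SD of offsets
  co2 <- cohort_from_values(list(list(rep(1, 3), rep(1, 3)),
                                 list(rep(-2, 3), rep(-2, 3)),
                                 list(rep(4, 3), rep(4, 3))), axis = "SI")
  mo2 <- moment_components(co2, axes = "SI")
  expect_equal(mo2$sigma_pt_mm, sd(c(1, -2, 4)))
  expect_equal(mo2$sigma_fr_mm, 0)
  expect_equal(mo2$sigma_intra_mm, 0)

  expect_error(moment_components(cohort_from_values(list(list(c(0, 1))))),
               "2 patients")
})

test_that("sufficient-statistics REML equals the dense-covariance oracle", {
  set.seed(41)
  for (rep in 1:6) {
    n_pt <- sample(2:3, 1)
    vals <- lapply(seq_len(n_pt), function(p) {
      lapply(seq_len(sample(2:3, 1)), function(f) rnorm(sample(2:4, 1), 0, 2))
    })
    co <- cohort_from_values(vals, axis = "AP")
    expect_lte(nrow(co), 30)
    for (k in 1:3) {
      th <- c(runif(1, 0, 1.5), runif(1, 0.05, 1.5), runif(1, 0.1, 1.5))
      m <- rnorm(1)
      ours <- reml_loglik(co, "AP", th[1], th[2], th[3], mean = m)
      oracle <- dense_reml_loglik(co, "AP", th[1], th[2], th[3], m = m)
      expect_equal(ours, oracle, tolerance = 1e-8)
      ## profiled-mean path too
      expect_equal(reml_loglik(co, "AP", th[1], th[2], th[3]),
                   dense_reml_loglik(co, "AP", th[1], th[2], th[3]),
                   tolerance = 1e-8)
    }
  }
})

test_that("with no patient/fraction components REML collapses to the i.i.d. case", {
  set.seed(42)
  co <- cohort_from_values(list(list(rnorm(5), rnorm(4)), list(rnorm(6))),
                           axis = "SI")
  y <- co$si_mm
  N <- length(y)
  s <- 0.8
  m <- 0.3
  closed_form <- -0.5 * ((N - 1) * log(2 * pi * s^2) +
                           sum((y - m)^2) / s^2 + log(N))
  expect_equal(reml_loglik(co, "SI", 0, 0, s, mean = m), closed_form,
               tolerance = 1e-10)
})

test_that("adding a constant shifts the profiled mean and not the maximized loglik", {
  co <- simulate_cohort(sim_config(n_patients = 4, fractions_per_patient = 5,
                                   duration_s = 30, sigma_pt_mm = 0.3,
                                   sigma_fr_mm = 0.5, sigma_intra_mm = 0.4,
                                   overall_mean_mm = 0.1, seed = 43))
  shifted <- co
  shifted$ap_mm <- shifted$ap_mm + 2.5
  f0 <- reml_fit(co, axes = "AP", compute_ci = FALSE)
  f1 <- reml_fit(shifted, axes = "AP", compute_ci = FALSE)
  expect_equal(f1$overall_mean_mm, f0$overall_mean_mm + 2.5,
               tolerance = 1e-6)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6)
  expect_equal(f1$sigma_fr_mm, f0$sigma_fr_mm, tolerance = 1e-6)
})

test_that("balanced designs with interior optima match closed-form nested ANOVA", {
  co <- simulate_cohort(sim_config(n_patients = 6, fractions_per_patient = 5,
                                   duration_s = 5,
                                   overall_mean_mm = c(0.2, -0.1, 0),
                                   sigma_pt_mm = 0.6, sigma_fr_mm = 0.5,
                                   sigma_intra_mm = 0.3, seed = 44))
  for (ax in c("SI", "AP")) {
    an <- balanced_anova_components(co, ax)
    expect_gt(an$sigma_pt, 0.05)  # interior on this draw
    expect_gt(an$sigma_fr, 0.05)
    fit <- reml_fit(co, axes = ax, compute_ci = FALSE)
    expect_equal(fit$sigma_pt_mm, an$sigma_pt, tolerance = 1e-6)
    expect_equal(fit$sigma_fr_mm, an$sigma_fr, tolerance = 1e-6)
    expect_equal(fit$sigma_intra_mm, an$sigma_intra, tolerance = 1e-6)
    expect_equal(fit$overall_mean_mm, an$mean, tolerance = 1e-6)
  }
})

test_that("REML point estimates and loglik agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  co <- simulate_cohort(sim_config(n_patients = 6, fractions_per_patient = 8,
                                   duration_s = 60,
                                   sigma_pt_mm = c(0.2, 0.3, 0.1),
                                   sigma_fr_mm = c(0.4, 0.8, 0.3),
                                   sigma_intra_mm = c(0.34, 0.69, 0.23),
                                   seed = 42))
  df <- data.frame(y = co$ap_mm, pt = co$patient_id,
                   fr = paste(co$patient_id, co$fraction_id))
  ref <- lme4::lmer(y ~ 1 + (1 | pt) + (1 | fr), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))
  ref_sd <- setNames(vc$sdcor, vc$grp)
  fit <- reml_fit(co, axes = "AP", compute_ci = FALSE)
  expect_equal(fit$sigma_pt_mm, unname(ref_sd["pt"]), tolerance = 1e-3)
  expect_equal(fit$sigma_fr_mm, unname(ref_sd["fr"]), tolerance = 1e-3)
  expect_equal(fit$sigma_intra_mm, unname(ref_sd["Residual"]),
               tolerance = 1e-4)
  expect_equal(fit$overall_mean_mm, unname(lme4::fixef(ref)[1]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("REML fits are scale-equivariant including profile intervals", {
  co <- simulate_cohort(sim_config(n_patients = 4, fractions_per_patient = 6,
                                   duration_s = 30, sigma_pt_mm = 0.3,
                                   sigma_fr_mm = 0.5, sigma_intra_mm = 0.4,
                                   seed = 45))
  k <- 3.7
  scaled <- co
  scaled$ap_mm <- scaled$ap_mm * k
  f0 <- reml_fit(co, axes = "AP")
  f1 <- reml_fit(scaled, axes = "AP")
  cols <- c("sigma_pt_mm", "sigma_pt_lo", "sigma_pt_hi", "sigma_fr_mm",
            "sigma_fr_lo", "sigma_fr_hi", "sigma_intra_mm",
            "sigma_intra_lo", "sigma_intra_hi", "overall_mean_mm",
            "mean_lo", "mean_hi")
  for (cl in cols) {
    ## absolute band: CI endpoints are located to ~1e-4 mm by root-finding,
    ## and some endpoints sit arbitrarily close to zero
    expect_lt(abs(f1[[cl]] - k * f0[[cl]]), 5e-3, label = cl)
  }
})

test_that("a zero patient component is estimated at the boundary with CI lower bound 0", {
  co <- simulate_cohort(sim_config(n_patients = 10,
                                   fractions_per_patient = 12,
                                   duration_s = 60, sigma_pt_mm = 0,
                                   sigma_fr_mm = 0.4, sigma_intra_mm = 0.34,
                                   seed = 46))
  fit <- reml_fit(co, axes = "SI")
  ## "near the boundary": small against the inter-fraction SD
  expect_lt(fit$sigma_pt_mm, 0.25 * fit$sigma_fr_mm)
  expect_equal(fit$sigma_pt_lo, 0)
  expect_gt(fit$sigma_pt_hi, fit$sigma_pt_mm)
})

test_that("profile intervals contain the estimate and respect ordering", {
  co <- simulate_cohort(sim_config(n_patients = 5, fractions_per_patient = 6,
                                   duration_s = 30, sigma_pt_mm = 0.4,
                                   sigma_fr_mm = 0.5, sigma_intra_mm = 0.4,
                                   seed = 47))
  fit <- reml_fit(co, axes = "AP")
  expect_lte(fit$sigma_pt_lo, fit$sigma_pt_mm)
  expect_gte(fit$sigma_pt_hi, fit$sigma_pt_mm)
  expect_lte(fit$sigma_fr_lo, fit$sigma_fr_mm)
  expect_gte(fit$sigma_fr_hi, fit$sigma_fr_mm)
  expect_lte(fit$sigma_intra_lo, fit$sigma_intra_mm)
  expect_gte(fit$sigma_intra_hi, fit$sigma_intra_mm)
  expect_lt(fit$mean_lo, fit$overall_mean_mm)
  expect_gt(fit$mean_hi, fit$overall_mean_mm)
  ## wider level -> wider interval
  fit90 <- reml_fit(co, axes = "AP", ci_level = 0.90)
  expect_gt(fit$sigma_fr_hi, fit90$sigma_fr_hi)
  expect_lt(fit$sigma_fr_lo, fit90$sigma_fr_lo)
})

test_that("thinning strides the samples as documented", {
  co <- simulate_cohort(sim_config(n_patients = 3, fractions_per_patient = 4,
                                   duration_s = 30, seed = 48))
  thinned <- co |>
    dplyr::group_by(patient_id, fraction_id) |>
    dplyr::filter((dplyr::row_number() - 1) %% 3 == 0) |>
    dplyr::ungroup()
  expect_equal(reml_loglik(co, "AP", 0.1, 0.4, 0.3, thin = 3),
               reml_loglik(thinned, "AP", 0.1, 0.4, 0.3))
})

test_that("degenerate inputs are rejected", {
  one_pt <- cohort_from_values(list(list(c(0, 1, 2), c(1, 2, 0))))
  expect_error(reml_fit(one_pt), "2 patients")
  single_sample <- cohort_from_values(list(list(0), list(1)))
  expect_error(reml_fit(single_sample), "fractions|samples")
  expect_error(reml_loglik(one_pt, "AP", -0.1, 0.2, 0.3), "sigma")
  expect_error(reml_loglik(one_pt, "AP", 0.1, 0.2, 0), "sigma")
})

test_that("tidy and glance expose the broom-style views", {
  co <- simulate_cohort(sim_config(n_patients = 3, fractions_per_patient = 3,
                                   duration_s = 20, seed = 49))
  mo <- moment_components(co)
  td <- tidy(mo)
  expect_equal(nrow(td), 12)  # 3 axes x 4 terms
  expect_named(td, c("axis", "term", "estimate", "conf.low", "conf.high",
                     "estimator"))
  gl <- glance(mo)
  expect_equal(gl$n_patients, rep(3L, 3))
})
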