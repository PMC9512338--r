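#' Configure a synthetic motion cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()].  The
#' generator is the generative twin of the nested random-effects model used
#' for estimation: on each axis a patient offset `a_p ~ N(0, sigma_pt^2)`,
#' a fraction offset `b_pf ~ N(0, sigma_fr^2)` and a stationary
#' intra-fraction noise process with SD `sigma_intra` (white by default,
#' AR(1) when `ar_corr_time_s > 0`), plus an optional random linear baseline
#' drift and rare transient "rectal gas" excursions modelled as half-sine
#' pulses on the AP axis.
#'
#' All SD-like parameters are 3-vectors in the fixed axis order SI, AP, LR
#' (scalars are recycled).  Displacements are in millimetres.
#'
#' @param n_patients Number of patients.
#' @param fractions_per_patient Integer vector of monitored fractions per
#'   patient (length `n_patients`, or a scalar recycled to all patients).
#' @param duration_s Monitored duration of each fraction, seconds.
#' @param sample_rate_hz Sampling rate of the position monitor (default 4).
#' @param overall_mean_mm Population mean displacement per axis.
#' @param sigma_pt_mm Inter-patient SD per axis.
#' @param sigma_fr_mm Inter-fraction SD per axis.
#' @param sigma_intra_mm Intra-fraction (residual) SD per axis.
#' @param drift_rate_mm_per_min Scale of the random per-fraction linear
#'   baseline drift: each fraction draws a slope `N(0, rate^2)` mm/min per
#'   axis.  0 disables drift.
#' @param gas_event_rate_per_fraction Expected number of transient gas
#'   excursions per fraction (Poisson).  0 disables them.
#' @param gas_event_amplitude_mm Half-normal scale of the excursion peak.
#' @param gas_event_duration_s Duration of each excursion pulse.
#' @param ar_corr_time_s Correlation time of the intra-fraction AR(1)
#'   process, seconds; 0 gives white noise.
#' @param technique Technique label stamped on the cohort.
#' @param seed Integer seed; identical configurations give bit-identical
#'   cohorts.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 5, fractions_per_patient = 37,
#'                   duration_s = 490, sigma_intra_mm = c(0.34, 0.69, 0.23))
#' @export
sim_config <- function(n_patients = 5,
                       fractions_per_patient = 37,
                       duration_s = 490,
                       sample_rate_hz = 4,
                       overall_mean_mm = c(0.05, -0.10, 0.03),
                       sigma_pt_mm = c(0.00, 0.10, 0.00),
                       sigma_fr_mm = c(0.41, 0.80, 0.31),
                       sigma_intra_mm = c(0.34, 0.69, 0.23),
                       drift_rate_mm_per_min = c(0, 0, 0),
                       gas_event_rate_per_fraction = 0,
                       gas_event_amplitude_mm = 3,
                       gas_event_duration_s = 10,
                       ar_corr_time_s = 0,
                       technique = "SS-IMRT",
                       seed = 1L) {
  .check_count <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      abort(paste0("Field ", name, " must be a single integer >= 1."))
    }
  }
  .check_pos <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(paste0("Field ", name, " must be a single positive number."))
    }
  }
  .check_vec3 <- function(x, name, nonneg = TRUE) {
    if (length(x) == 1) x <- rep(x, 3)
    if (length(x) != 3 || any(!is.finite(x))) {
      abort(paste0("Field ", name, " must be a finite 3-vector (SI, AP, LR)."))
    }
    if (nonneg && any(x < 0)) {
      abort(paste0("Field ", name, " must be nonnegative."))
    }
    setNames(x, .axes)
  }
  .check_count(n_patients, "n_patients")
  if (length(fractions_per_patient) == 1) {
    fractions_per_patient <- rep(fractions_per_patient, n_patients)
  }
  if (length(fractions_per_patient) != n_patients) {
    abort("Field fractions_per_patient must have one entry per patient.")
  }
  if (any(!is.finite(fractions_per_patient)) ||
      any(fractions_per_patient < 1) ||
      any(fractions_per_patient != round(fractions_per_patient))) {
    abort("Field fractions_per_patient must contain integers >= 1.")
  }
  .check_pos(duration_s, "duration_s")
  .check_pos(sample_rate_hz, "sample_rate_hz")
  if (length(gas_event_rate_per_fraction) != 1 ||
      !is.finite(gas_event_rate_per_fraction) ||
      gas_event_rate_per_fraction < 0) {
    abort("Field gas_event_rate_per_fraction must be a nonnegative rate.")
  }
  .check_pos(gas_event_amplitude_mm, "gas_event_amplitude_mm")
  .check_pos(gas_event_duration_s, "gas_event_duration_s")
  if (length(ar_corr_time_s) != 1 || !is.finite(ar_corr_time_s) ||
      ar_corr_time_s < 0) {
    abort("Field ar_corr_time_s must be a nonnegative time.")
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    abort("Field seed must be a single integer.")
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    fractions_per_patient = as.integer(fractions_per_patient),
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    overall_mean_mm = .check_vec3(overall_mean_mm, "overall_mean_mm",
                                  nonneg = FALSE),
    sigma_pt_mm = .check_vec3(sigma_pt_mm, "sigma_pt_mm"),
    sigma_fr_mm = .check_vec3(sigma_fr_mm, "sigma_fr_mm"),
    sigma_intra_mm = .check_vec3(sigma_intra_mm, "sigma_intra_mm"),
    drift_rate_mm_per_min = .check_vec3(drift_rate_mm_per_min,
                                        "drift_rate_mm_per_min"),
    gas_event_rate_per_fraction = gas_event_rate_per_fraction,
    gas_event_amplitude_mm = gas_event_amplitude_mm,
    gas_event_duration_s = gas_event_duration_s,
    ar_corr_time_s = ar_corr_time_s,
    technique = as.character(technique),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients,",
      paste(range(x$fractions_per_patient), collapse = "-"),
      "fractions/patient,", x$duration_s, "s at", x$sample_rate_hz, "Hz\n")
  invisible(x)
}

## Stationary AR(1) draw: e_1 ~ N(0, s^2), e_t = phi e_{t-1} + innovation.
.ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  if (phi == 0) return(rnorm(n, 0, sd))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (t in seq_len(n - 1)) e[t + 1] <- phi * e[t] + innov[t]
  e
}

## Half-sine unipolar pulse evaluated at times t.
.gas_pulse <- function(times, onset_s, amplitude_mm, duration_s) {
  inside <- times >= onset_s & times <= onset_s + duration_s
  pulse <- numeric(length(times))
  pulse[inside] <- amplitude_mm *
    sin(pi * (times[inside] - onset_s) / duration_s)
  pulse
}

#' Simulate a cohort of intra-fractional motion traces
#'
#' Draws a full synthetic cohort under the nested patient/fraction/sample
#' model described in [sim_config()].  The first sample of every fraction is
#' the zero reference position (displacement identically zero), mirroring the
#' clinical zeroing of the tracking system at the monitoring start; all later
#' samples carry the patient and fraction offsets, drift, noise and any gas
#' excursions.
#'
#' @param config A [sim_config()] object.
#' @return A [motion cohort][as_motion_cohort] tibble.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2,
#'                                      fractions_per_patient = 3,
#'                                      duration_s = 30, seed = 7))
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  dt <- 1 / config$sample_rate_hz
  times <- seq(0, config$duration_s, by = dt)
  n_t <- length(times)
  phi <- if (config$ar_corr_time_s > 0) exp(-dt / config$ar_corr_time_s) else 0
  pt_ids <- sprintf("P%02d", seq_len(config$n_patients))

  out <- vector("list", sum(config$fractions_per_patient))
  k <- 0
  for (p in seq_len(config$n_patients)) {
    a_p <- rnorm(3, 0, config$sigma_pt_mm)
    for (f in seq_len(config$fractions_per_patient[p])) {
      b_pf <- rnorm(3, 0, config$sigma_fr_mm)
      slope <- rnorm(3, 0, config$drift_rate_mm_per_min)
      disp <- matrix(0, n_t, 3)
      for (ax in 1:3) {
        level <- config$overall_mean_mm[ax] + a_p[ax] + b_pf[ax]
        disp[, ax] <- level + slope[ax] * times / 60 +
          .ar1_noise(n_t, config$sigma_intra_mm[ax], phi)
      }
      ## gas excursions: Poisson count, half-normal peak, AP axis
      if (config$gas_event_rate_per_fraction > 0) {
        n_ev <- rpois(1, config$gas_event_rate_per_fraction)
        for (ev in seq_len(n_ev)) {
          onset <- runif(1, 0, max(config$duration_s -
                                     config$gas_event_duration_s, 0))
          amp <- abs(rnorm(1, 0, config$gas_event_amplitude_mm))
          disp[, 2] <- disp[, 2] +
            .gas_pulse(times, onset, amp, config$gas_event_duration_s)
        }
      }
      disp[1, ] <- 0  # zero reference at monitoring start
      k <- k + 1
      out[[k]] <- tibble::tibble(
        technique = config$technique,
        patient_id = pt_ids[p],
        fraction_id = sprintf("F%02d", f),
        time_s = times,
        si_mm = disp[, 1], ap_mm = disp[, 2], lr_mm = disp[, 3])
    }
  }
  cohort <- dplyr::bind_rows(out)
  class(cohort) <- c("motion_cohort", class(tibble::tibble()))
  cohort
}

#' Add a transient gas excursion to a trace
#'
#' Superimposes a smooth unipolar half-sine pulse on one axis of a single
#' fraction's trace, emulating the sudden anterior-posterior prostate shifts
#' caused by moving rectal gas.  Samples outside `[onset_s, onset_s +
#' duration_s]` are unchanged; the pulse is zero at its endpoints, so a pulse
#' starting at time 0 still leaves the zero reference sample intact.
#'
#' @param trace A single fraction's samples (a motion-cohort tibble holding
#'   exactly one `patient_id`/`fraction_id` combination).
#' @param onset_s Pulse onset, seconds; must lie within the trace.
#' @param amplitude_mm Signed peak displacement of the pulse.
#' @param duration_s Pulse duration, seconds.
#' @param axis Axis label: `"SI"`, `"AP"` (default) or `"LR"`.
#' @return The trace with the pulse added.
#' @examples
#' cfg <- sim_config(n_patients = 1, fractions_per_patient = 1,
#'                   duration_s = 60, sigma_intra_mm = 0,
#'                   sigma_fr_mm = 0, sigma_pt_mm = 0,
#'                   overall_mean_mm = 0, seed = 1)
#' tr <- simulate_cohort(cfg)
#' bumped <- inject_gas_event(tr, onset_s = 10, amplitude_mm = 9.7,
#'                            duration_s = 10)
#' max_abs_displacement(bumped)
#' @export
inject_gas_event <- function(trace, onset_s, amplitude_mm, duration_s,
                             axis = "AP") {
  axis <- .match_axes(axis)
  if (length(axis) != 1) abort("axis must be a single axis label.")
  if (nrow(dplyr::distinct(trace, trace$patient_id, trace$fraction_id)) != 1) {
    abort("inject_gas_event() expects a single fraction's trace.")
  }
  t_end <- max(trace$time_s)
  if (length(onset_s) != 1 || onset_s < 0 || onset_s >= t_end) {
    abort(paste0("onset_s must lie in [0, ", t_end, ") for this trace."))
  }
  if (duration_s <= 0) abort("duration_s must be positive.")
  col <- .axis_cols[[axis]]
  trace[[col]] <- trace[[col]] +
    .gas_pulse(trace$time_s, onset_s, amplitude_mm, duration_s)
  trace
}
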