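#' Hand-entered component and effective-error tables
#'
#' Constructors for injecting externally reported values (e.g. a published
#' components table) into the margin chain without refitting.
#' `make_components()` builds a minimal `variance_components` table from
#' per-axis SDs; `make_effective_errors()` builds an `effective_errors`
#' table directly.
#'
#' @param axis Axis labels (recycled against the SD vectors).
#' @param sigma_pt_mm,sigma_fr_mm,sigma_intra_mm Component SDs, mm.
#' @param overall_mean_mm Overall mean displacement, mm.
#' @param estimator Estimator tag recorded in the lineage.
#' @return A `variance_components` tibble.
#' @examples
#' make_components(c("SI", "AP", "LR"),
#'                 sigma_pt_mm = c(0.00, 0.10, 0.00),
#'                 sigma_fr_mm = c(0.41, 0.80, 0.31),
#'                 sigma_intra_mm = c(0.34, 0.69, 0.23))
#' @export
make_components <- function(axis, sigma_pt_mm, sigma_fr_mm, sigma_intra_mm,
                            overall_mean_mm = 0, estimator = "manual") {
  axis <- .match_axes(axis)
  if (any(c(sigma_pt_mm, sigma_fr_mm, sigma_intra_mm) < 0)) {
    abort("Component SDs must be nonnegative.")
  }
  rows <- tibble::tibble(
    axis = factor(axis, levels = .axes), estimator = estimator,
    sigma_pt_mm = sigma_pt_mm, sigma_pt_lo = NA_real_, sigma_pt_hi = NA_real_,
    sigma_fr_mm = sigma_fr_mm, sigma_fr_lo = NA_real_, sigma_fr_hi = NA_real_,
    sigma_intra_mm = sigma_intra_mm, sigma_intra_lo = NA_real_,
    sigma_intra_hi = NA_real_,
    overall_mean_mm = overall_mean_mm, mean_lo = NA_real_, mean_hi = NA_real_,
    ci_level = NA_real_, loglik = NA_real_, convergence = NA_integer_,
    n_patients = NA_integer_, n_fractions = NA_integer_,
    n_samples = NA_integer_)
  class(rows) <- c("variance_components", class(tibble::tibble()))
  rows
}

#' @rdname make_components
#' @param sigma_eff_mm,sigma_rand_eff_mm Effective systematic and random
#'   errors, mm.
#' @param n_fractions Fraction count the effective errors refer to.
#' @param source Lineage tag.
#' @export
make_effective_errors <- function(axis, sigma_eff_mm, sigma_rand_eff_mm,
                                  n_fractions = NA_integer_,
                                  source = "manual") {
  axis <- .match_axes(axis)
  if (any(c(sigma_eff_mm, sigma_rand_eff_mm) < 0)) {
    abort("Effective errors must be nonnegative.")
  }
  out <- tibble::tibble(axis = factor(axis, levels = .axes),
                        sigma_eff_mm = sigma_eff_mm,
                        sigma_rand_eff_mm = sigma_rand_eff_mm,
                        n_fractions = n_fractions, source = source)
  class(out) <- c("effective_errors", class(tibble::tibble()))
  out
}

#' Effective systematic and random errors for a finite fraction count
#'
#' Converts nested variance components into the effective errors entering
#' the margin recipe for a course of `N` fractions:
#' \deqn{\Sigma_{eff}^2 = \Sigma_{pt}^2 + \sigma_{fr}^2 / N, \qquad
#'       \sigma_{eff}^2 = (1 - 1/N)\,\sigma_{fr}^2 + \sigma_{intra}^2.}
#' With finitely many fractions a share \eqn{\sigma_{fr}^2/N} of the
#' day-to-day variation does not average out over the course and therefore
#' acts systematically; the remainder stays random.
#'
#' With `method = "raw"` the classic pathway is used instead: the systematic
#' column is taken as-is and the random error is the intra-fraction (RMS of
#' within-fraction SDs) column — the convention of the classic moment
#' ("van Herk") table, whose \eqn{\Sigma} already absorbs the finite-N
#' share.
#'
#' @param components A `variance_components` table.
#' @param n_fractions Fraction count `N` (single integer >= 1).  Default:
#'   chosen by `n_policy` from the cohort the components were fitted to.
#' @param n_policy How to pick `N` for unbalanced cohorts when
#'   `n_fractions` is `NULL`: the largest per-patient fraction count
#'   (`"max"`, default) or the harmonic mean (`"harmonic"`).
#' @param method `"effective"` (finite-N corrections, default) or `"raw"`.
#' @return An `effective_errors` tibble, one row per axis.
#' @examples
#' comps <- make_components("AP", 0.10, 0.80, 0.69)
#' effective_errors(comps, n_fractions = 37)
#' @export
effective_errors <- function(components, n_fractions = NULL,
                             n_policy = c("max", "harmonic"),
                             method = c("effective", "raw")) {
  method <- match.arg(method)
  n_policy <- match.arg(n_policy)
  if (is.null(n_fractions)) {
    fpp <- attr(components, "fractions_per_patient")
    if (is.null(fpp)) {
      abort(paste0("n_fractions not given and the components table has no ",
                   "cohort lineage; pass n_fractions explicitly."))
    }
    n_fractions <- switch(n_policy,
                          max = max(fpp),
                          harmonic = length(fpp) / sum(1 / fpp))
  }
  if (length(n_fractions) != 1 || !is.finite(n_fractions) ||
      n_fractions < 1) {
    abort("n_fractions must be a single value >= 1.")
  }
  N <- n_fractions
  if (method == "effective") {
    sig_eff <- sqrt(components$sigma_pt_mm^2 + components$sigma_fr_mm^2 / N)
    rand_eff <- sqrt((1 - 1 / N) * components$sigma_fr_mm^2 +
                       components$sigma_intra_mm^2)
  } else {
    sig_eff <- components$sigma_pt_mm
    rand_eff <- components$sigma_intra_mm
  }
  make_effective_errors(as.character(components$axis), sig_eff, rand_eff,
                        n_fractions = N,
                        source = paste(components$estimator, method,
                                       sep = "/"))
}

#' Internal margin from effective errors
#'
#' The population margin recipe \eqn{IM = 2.5\,\Sigma_{eff} +
#' 0.7\,\sigma_{eff}}, whose default coefficients are derived to guarantee a
#' 95% minimum target dose for 90% of patients.
#'
#' @param eff An `effective_errors` table (see [effective_errors()] /
#'   [make_effective_errors()]).
#' @param coefficients Length-2 vector `(systematic, random)`; default
#'   `c(2.5, 0.7)`.
#' @return A `margin_result` tibble with the margin `im_mm` per axis and
#'   the coefficient/lineage columns.
#' @examples
#' margin(make_effective_errors("AP", 0.30, 2.26))  # 2.33 mm
#' @export
margin <- function(eff, coefficients = c(2.5, 0.7)) {
  if (length(coefficients) != 2 || any(!is.finite(coefficients))) {
    abort("coefficients must be a finite length-2 vector.")
  }
  out <- tibble::tibble(
    axis = eff$axis,
    sigma_eff_mm = eff$sigma_eff_mm,
    sigma_rand_eff_mm = eff$sigma_rand_eff_mm,
    im_mm = coefficients[1] * eff$sigma_eff_mm +
      coefficients[2] * eff$sigma_rand_eff_mm,
    coef_systematic = coefficients[1], coef_random = coefficients[2],
    n_fractions = eff$n_fractions, source = eff$source)
  class(out) <- c("margin_result", class(tibble::tibble()))
  out
}

#' End-to-end margin table for a cohort
#'
#' Runs the full chain components -> effective errors -> internal margin on
#' one cohort and returns a per-axis table carrying the whole lineage
#' (component estimates, effective errors, margin, estimator, `N`).  The
#' REML estimator uses the finite-N effective pathway; the moment estimator
#' defaults to the classic raw pathway (`pathway = "auto"`), matching how
#' the two conventions are tabulated side by side in margin studies.
#'
#' @param cohort A motion cohort.
#' @param estimator `"reml"` (default) or `"moment"`.
#' @param n_fractions Fraction count `N`; default via `n_policy`.
#' @param n_policy See [effective_errors()].
#' @param coefficients Margin coefficients, default `c(2.5, 0.7)`.
#' @param pathway `"auto"` (raw for moment, effective for REML),
#'   `"effective"`, or `"raw"`.
#' @param ci_level Level for REML profile intervals.
#' @param compute_ci Compute REML profile intervals (default `FALSE`; the
#'   margin chain itself only needs point estimates).
#' @param thin Optional sample stride.
#' @return A tibble, one row per axis: component estimates, effective
#'   errors, `im_mm`, coefficients and lineage.
#' @export
margin_table <- function(cohort, estimator = c("reml", "moment"),
                         n_fractions = NULL, n_policy = c("max", "harmonic"),
                         coefficients = c(2.5, 0.7),
                         pathway = c("auto", "effective", "raw"),
                         ci_level = 0.95, compute_ci = FALSE, thin = 1) {
  estimator <- match.arg(estimator)
  pathway <- match.arg(pathway)
  n_policy <- match.arg(n_policy)
  comps <- switch(estimator,
                  reml = reml_fit(cohort, ci_level = ci_level, thin = thin,
                                  compute_ci = compute_ci),
                  moment = moment_components(cohort, thin = thin))
  method <- if (pathway == "auto") {
    if (estimator == "moment") "raw" else "effective"
  } else pathway
  eff <- effective_errors(comps, n_fractions = n_fractions,
                          n_policy = n_policy, method = method)
  mar <- margin(eff, coefficients)
  dplyr::left_join(
    dplyr::select(tibble::as_tibble(comps), "axis", "estimator",
                  "sigma_pt_mm", "sigma_fr_mm", "sigma_intra_mm",
                  "overall_mean_mm"),
    tibble::as_tibble(mar), by = "axis")
}
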