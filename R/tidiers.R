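#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a variance-components table
#'
#' Pivots a `variance_components` table into the broom convention: one row
#' per axis and term, with `estimate`, `conf.low`, `conf.high`.
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return A tibble with columns `axis, term, estimate, conf.low,
#'   conf.high, estimator`.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  terms <- list(
    sigma_pt = c("sigma_pt_mm", "sigma_pt_lo", "sigma_pt_hi"),
    sigma_fr = c("sigma_fr_mm", "sigma_fr_lo", "sigma_fr_hi"),
    sigma_intra = c("sigma_intra_mm", "sigma_intra_lo", "sigma_intra_hi"),
    overall_mean = c("overall_mean_mm", "mean_lo", "mean_hi"))
  purrr::map_dfr(names(terms), function(tm) {
    cols <- terms[[tm]]
    tibble::tibble(axis = x$axis, term = tm,
                   estimate = x[[cols[1]]],
                   conf.low = x[[cols[2]]], conf.high = x[[cols[3]]],
                   estimator = x$estimator)
  }) |>
    dplyr::arrange(.data$axis)
}

#' Glance at a variance-components fit
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return A one-row-per-axis tibble with fit-level metadata (sizes,
#'   estimator, log-likelihood, CI level).
#' @export
glance.variance_components <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "axis", "estimator", "loglik",
                "ci_level", "convergence", "n_patients", "n_fractions",
                "n_samples")
}
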