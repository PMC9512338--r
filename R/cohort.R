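#' Motion cohorts
#'
#' A motion cohort is a long-format tibble holding every displacement sample
#' of every monitored treatment fraction, nested patient -> fraction -> time.
#' Columns are `technique` (delivery technique label, e.g. `"SS-IMRT"` or
#' `"VMAT"`), `patient_id`, `fraction_id`, `time_s` (seconds from the start
#' of ultrasound monitoring) and the three signed displacement components
#' `si_mm`, `ap_mm`, `lr_mm` (millimetres; positive = superior / anterior /
#' left).  Displacements are measured from the prostate position at the
#' monitoring start, so the first sample of every fraction is exactly zero
#' on all three axes.
#'
#' `as_motion_cohort()` validates a data frame against these rules (sorting
#' samples by time within fraction first) and attaches the
#' `motion_cohort` class; violations are rejected with an informative error,
#' never silently repaired.
#'
#' @param x A data frame with the columns listed above.
#' @return A tibble of class `motion_cohort`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2,
#'                                      fractions_per_patient = 2,
#'                                      duration_s = 10, seed = 1))
#' as_motion_cohort(as.data.frame(cohort))
#' @export
as_motion_cohort <- function(x) {
  cols <- c("technique", "patient_id", "fraction_id", "time_s", .axis_cols)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[cols]
  x$technique <- as.character(x$technique)
  x$patient_id <- as.character(x$patient_id)
  x$fraction_id <- as.character(x$fraction_id)
  for (col in c("time_s", .axis_cols)) {
    if (!is.numeric(x[[col]])) {
      abort(paste0("Column ", col, " must be numeric."))
    }
    if (any(!is.finite(x[[col]]))) {
      row <- which(!is.finite(x[[col]]))[1]
      abort(paste0("Non-finite value in column ", col, " at row ", row, "."))
    }
  }
  ## A patient belongs to exactly one technique.
  tech_per_pt <- dplyr::distinct(x, .data$technique, .data$patient_id)
  dup <- tech_per_pt$patient_id[duplicated(tech_per_pt$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("patient_id ", dup[1],
                 " appears under more than one technique."))
  }
  x <- dplyr::arrange(x, .data$technique, .data$patient_id,
                      .data$fraction_id, .data$time_s)
  grp <- dplyr::group_by(x, .data$patient_id, .data$fraction_id)
  check <- dplyr::summarise(
    grp,
    n_dup_t = sum(duplicated(.data$time_s)),
    t0 = dplyr::first(.data$time_s),
    d0 = max(abs(c(dplyr::first(.data$si_mm), dplyr::first(.data$ap_mm),
                   dplyr::first(.data$lr_mm)))),
    .groups = "drop")
  bad <- check[check$n_dup_t > 0, ]
  if (nrow(bad) > 0) {
    abort(paste0("Duplicated time_s within patient ", bad$patient_id[1],
                 " fraction ", bad$fraction_id[1],
                 ": times must be strictly increasing."))
  }
  bad <- check[check$t0 != 0, ]
  if (nrow(bad) > 0) {
    abort(paste0("First time sample of patient ", bad$patient_id[1],
                 " fraction ", bad$fraction_id[1], " is ", bad$t0[1],
                 ", not 0."))
  }
  bad <- check[check$d0 != 0, ]
  if (nrow(bad) > 0) {
    abort(paste0("Displacement at time 0 of patient ", bad$patient_id[1],
                 " fraction ", bad$fraction_id[1],
                 " is nonzero; traces are measured from the zeroed start ",
                 "position."))
  }
  class(x) <- c("motion_cohort", class(tibble::tibble()))
  x
}

#' @export
print.motion_cohort <- function(x, ...) {
  n_pt <- dplyr::n_distinct(x$patient_id)
  n_fr <- nrow(dplyr::distinct(x, .data$patient_id, .data$fraction_id))
  cat(sprintf(
    "<motion_cohort> %s technique(s), %d patient(s), %d fraction(s), %d samples\n",
    paste(unique(x$technique), collapse = "/"), n_pt, n_fr, nrow(x)))
  NextMethod()
}

## Keep the class through dplyr verbs used internally.
#' @export
`[.motion_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- setdiff(class(out), "motion_cohort")
  out
}

## One fraction's samples, in time order, as a plain tibble.
.split_fractions <- function(cohort) {
  dplyr::group_split(dplyr::group_by(cohort, .data$patient_id,
                                     .data$fraction_id))
}
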