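#' Maximum absolute displacement of one trace
#'
#' The per-axis maximum of the absolute displacement from the zeroed start
#' position over all samples of one fraction — the quantity summarized per
#' patient in clinical motion reports.
#'
#' @param trace A single fraction's samples.
#' @return Named numeric vector `c(SI=, AP=, LR=)`, millimetres.
#' @export
max_abs_displacement <- function(trace) {
  if (nrow(trace) == 0) abort("Empty trace: no samples.")
  vapply(.axis_cols, function(col) max(abs(trace[[col]])), numeric(1))
}

#' Per-fraction displacement summaries
#'
#' One row per fraction and axis: monitored duration, the maximum absolute
#' displacement, the signed displacement at which that maximum was attained
#' (first occurrence on ties), and the mean and sample SD (n-1 denominator;
#' 0 for a single-sample trace) of the signed displacement.
#'
#' @param cohort A motion cohort.
#' @return A tibble with columns `technique, patient_id, fraction_id,
#'   duration_s, axis, max_abs_mm, signed_at_max_mm, mean_mm, sd_mm`.
#' @export
summarize_fractions <- function(cohort) {
  if (nrow(cohort) == 0) abort("Empty cohort.")
  long <- tidyr::pivot_longer(cohort, cols = dplyr::all_of(unname(.axis_cols)),
                              names_to = "axis", values_to = "disp_mm")
  long$axis <- names(.axis_cols)[match(long$axis, .axis_cols)]
  out <- long |>
    dplyr::group_by(.data$technique, .data$patient_id, .data$fraction_id,
                    .data$axis) |>
    dplyr::summarise(
      duration_s = max(.data$time_s),
      max_abs_mm = max(abs(.data$disp_mm)),
      signed_at_max_mm = .data$disp_mm[which.max(abs(.data$disp_mm))],
      mean_mm = mean(.data$disp_mm),
      sd_mm = if (dplyr::n() > 1) sd(.data$disp_mm) else 0,
      .groups = "drop")
  out$axis <- factor(out$axis, levels = .axes)
  dplyr::arrange(out, .data$technique, .data$patient_id, .data$fraction_id,
                 .data$axis)
}

#' Per-patient summaries of fraction maxima
#'
#' For each patient and axis, the mean and sample SD (n-1; 0 for a single
#' fraction) of the per-fraction maximum absolute displacements.
#'
#' @param x A motion cohort, or a table from [summarize_fractions()].
#' @return A tibble with columns `technique, patient_id, axis, n_fractions,
#'   mean_of_max_mm, sd_of_max_mm`.
#' @export
summarize_patients <- function(x) {
  fr <- if (all(c("max_abs_mm", "axis") %in% names(x))) x
        else summarize_fractions(x)
  fr |>
    dplyr::group_by(.data$technique, .data$patient_id, .data$axis) |>
    dplyr::summarise(
      n_fractions = dplyr::n(),
      mean_of_max_mm = mean(.data$max_abs_mm),
      sd_of_max_mm = if (dplyr::n() > 1) sd(.data$max_abs_mm) else 0,
      .groups = "drop")
}

#' Time-resolved mean absolute displacement
#'
#' Bins all samples of all fractions by time from the monitoring start and
#' averages the absolute displacement per axis within each bin.  A fraction
#' contributes to a bin only while it is still being monitored, so late bins
#' average over the (longer) fractions that reach them.
#'
#' @param cohort A motion cohort.
#' @param bin_s Bin width in seconds (default 1).
#' @return A tibble with columns `time_bin_s` (left bin edge), `axis`,
#'   `mean_abs_mm`, `n_fractions` (fractions contributing), `n_samples`.
#' @export
mean_abs_curve <- function(cohort, bin_s = 1) {
  if (nrow(cohort) == 0) abort("Empty cohort.")
  if (length(bin_s) != 1 || !is.finite(bin_s) || bin_s <= 0) {
    abort("bin_s must be a single positive number.")
  }
  long <- tidyr::pivot_longer(cohort, cols = dplyr::all_of(unname(.axis_cols)),
                              names_to = "axis", values_to = "disp_mm")
  long$axis <- factor(names(.axis_cols)[match(long$axis, .axis_cols)],
                      levels = .axes)
  long$time_bin_s <- floor(long$time_s / bin_s) * bin_s
  long |>
    dplyr::group_by(.data$axis, .data$time_bin_s) |>
    dplyr::summarise(
      mean_abs_mm = mean(abs(.data$disp_mm)),
      n_fractions = dplyr::n_distinct(paste(.data$patient_id,
                                            .data$fraction_id)),
      n_samples = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$axis, .data$time_bin_s)
}

## Exact two-sided permutation p for the rank-sum statistic; midranks for
## ties.  Enumerates all C(n, n_a) group assignments, so only used for small
## combined n.
.wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2  # Mann-Whitney U
  mu <- n_a * length(b) / 2
  combs <- combn(length(pooled), n_a)
  w_all <- colSums(matrix(r[combs], nrow = n_a)) - n_a * (n_a + 1) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  list(statistic = w_obs, p_value = p, method = "exact enumeration")
}

#' Rank-sum comparison of two displacement samples
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test.  For combined sample
#' sizes up to 20 the null distribution is enumerated exactly over all group
#' assignments (valid under ties, via midranks); for larger samples the
#' normal approximation with tie and continuity correction is used.  The
#' statistic reported is the Mann-Whitney U of the first sample.
#'
#' @param values_a,values_b Numeric vectors (e.g. per-fraction maximum
#'   absolute displacements of two delivery techniques).
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @examples
#' wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
wilcoxon_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("Both groups must be nonempty.")
  }
  if (length(unique(c(values_a, values_b))) == 1) {
    warn("All values identical across both groups; p = 1.")
    return(tibble::tibble(statistic = length(values_a) * length(values_b) / 2,
                          p_value = 1, method = "degenerate"))
  }
  if (length(values_a) + length(values_b) <= 20) {
    res <- .wilcoxon_exact(values_a, values_b)
  } else {
    ht <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "normal approximation, tie-corrected")
  }
  tibble::tibble(statistic = res$statistic, p_value = res$p_value,
                 method = res$method)
}

#' Compare per-fraction maxima between two techniques
#'
#' Pools the per-fraction maximum absolute displacements by technique and
#' runs [wilcoxon_compare()] per axis — the fraction-level between-technique
#' comparison used for delivery-technique motion studies.
#'
#' @param cohort A motion cohort containing exactly two technique labels.
#' @return A tibble with one row per axis: `axis, n_a, n_b, statistic,
#'   p_value, method` (group a is the alphabetically first technique).
#' @export
compare_techniques <- function(cohort) {
  fr <- summarize_fractions(cohort)
  techs <- sort(unique(fr$technique))
  if (length(techs) != 2) {
    abort("compare_techniques() needs a cohort with exactly two techniques.")
  }
  purrr::map_dfr(.axes, function(ax) {
    a <- fr$max_abs_mm[fr$axis == ax & fr$technique == techs[1]]
    b <- fr$max_abs_mm[fr$axis == ax & fr$technique == techs[2]]
    res <- wilcoxon_compare(a, b)
    tibble::tibble(axis = factor(ax, levels = .axes),
                   technique_a = techs[1], technique_b = techs[2],
                   n_a = length(a), n_b = length(b),
                   statistic = res$statistic, p_value = res$p_value,
                   method = res$method)
  })
}
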