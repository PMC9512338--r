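## Plain-text interchange for motion cohorts.
##
## One long-format comma-separated table per cohort, preceded by '#' comment
## lines declaring the dialect (axis order and sign conventions, units).
## Numbers are serialized with 6 decimals so write -> read -> write is
## byte-stable.

.cohort_header <- c(
  "# motionmargins cohort v1",
  "# columns: technique,patient_id,fraction_id,time_s,si_mm,ap_mm,lr_mm",
  "# units: displacement mm, time s from monitoring start",
  "# sign convention: positive = superior (SI), anterior (AP), left (LR)")

#' Write a motion cohort to a delimited text file
#'
#' Serializes a cohort to the package's documented long-format CSV dialect:
#' comment lines (`#`) with the sign conventions, a header row, then one row
#' per time sample with columns `technique, patient_id, fraction_id, time_s,
#' si_mm, ap_mm, lr_mm`.  Rows are written in canonical order (technique,
#' patient, fraction, time) and numbers with 6 decimals, so the format
#' round-trips losslessly through [read_cohort()] and repeated write/read
#' cycles are byte-identical.
#'
#' @param cohort A motion cohort (see [as_motion_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_motion_cohort(cohort)
  body <- sprintf("%s,%s,%s,%s,%s,%s,%s",
                  cohort$technique, cohort$patient_id, cohort$fraction_id,
                  sprintf("%.6f", cohort$time_s),
                  sprintf("%.6f", cohort$si_mm),
                  sprintf("%.6f", cohort$ap_mm),
                  sprintf("%.6f", cohort$lr_mm))
  lines <- c(.cohort_header,
             "technique,patient_id,fraction_id,time_s,si_mm,ap_mm,lr_mm",
             body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

## Special case: a cohort with zero rows still gets header lines.

#' Read a motion cohort from a delimited text file
#'
#' Parses the dialect written by [write_cohort()] and validates the result:
#' required columns present, numeric cells well formed, samples re-sorted by
#' time within fraction, times strictly increasing from 0, and the first
#' displacement sample of every fraction exactly zero.  Violations raise an
#' error naming the offending file line or fraction rather than being
#' silently repaired.  Row order in the file is immaterial.
#'
#' @param path Path to a cohort file.
#' @return A validated motion-cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such cohort file: ", path))
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  content_idx <- which(!is_comment)
  if (length(content_idx) == 0) {
    abort("Cohort file has no header row.")
  }
  header_line <- content_idx[1]
  header <- strsplit(lines[header_line], ",", fixed = TRUE)[[1]]
  expected <- c("technique", "patient_id", "fraction_id", "time_s",
                "si_mm", "ap_mm", "lr_mm")
  missing_cols <- setdiff(expected, header)
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data_idx <- content_idx[-1]
  data_idx <- data_idx[nzchar(trimws(lines[data_idx]))]
  if (length(data_idx) == 0) {
    return(as_motion_cohort(tibble::tibble(
      technique = character(), patient_id = character(),
      fraction_id = character(), time_s = numeric(),
      si_mm = numeric(), ap_mm = numeric(), lr_mm = numeric())))
  }
  fields <- strsplit(lines[data_idx], ",", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != length(header))) {
    bad <- which(n_fields != length(header))[1]
    abort(paste0("Line ", data_idx[bad], ": expected ", length(header),
                 " fields, found ", n_fields[bad], "."))
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  num_cols <- c("time_s", "si_mm", "ap_mm", "lr_mm")
  parsed <- lapply(num_cols, function(col) {
    vals <- suppressWarnings(as.numeric(mat[, col]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0) {
      abort(paste0("Line ", data_idx[bad[1]], ": malformed numeric value \"",
                   mat[bad[1], col], "\" in column ", col, "."))
    }
    vals
  })
  names(parsed) <- num_cols
  as_motion_cohort(tibble::tibble(
    technique = mat[, "technique"],
    patient_id = mat[, "patient_id"],
    fraction_id = mat[, "fraction_id"],
    time_s = parsed$time_s,
    si_mm = parsed$si_mm,
    ap_mm = parsed$ap_mm,
    lr_mm = parsed$lr_mm))
}
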