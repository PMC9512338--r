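# Independent oracles and small fixture builders used across the suite.

# Build a cohort tibble directly from a list of per-fraction sample vectors:
# values[[patient]][[fraction]] = numeric vector placed on one axis (other
# axes zero).  Times on a 4 Hz grid.  Bypasses trace validation on purpose so
# estimation tests can use arbitrary hand-picked numbers.
cohort_from_values <- function(values, axis = "AP", technique = "SS-IMRT") {
  col <- c(SI = "si_mm", AP = "ap_mm", LR = "lr_mm")[[axis]]
  rows <- list()
  for (p in seq_along(values)) {
    for (f in seq_along(values[[p]])) {
      y <- values[[p]][[f]]
      row <- tibble::tibble(
        technique = technique,
        patient_id = sprintf("P%02d", p),
        fraction_id = sprintf("F%02d", f),
        time_s = (seq_along(y) - 1) / 4,
        si_mm = 0, ap_mm = 0, lr_mm = 0)
      row[[col]] <- y
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

# Brute-force restricted log-likelihood with an explicit dense covariance
# matrix V = sigma_pt^2 Zp Zp' + sigma_fr^2 Zf Zf' + sigma_intra^2 I and
# generalized least squares, for cohorts small enough to enumerate.
dense_reml_loglik <- function(cohort, axis, sigma_pt, sigma_fr, sigma_intra,
                              m = NULL) {
  col <- c(SI = "si_mm", AP = "ap_mm", LR = "lr_mm")[[axis]]
  y <- cohort[[col]]
  pt <- cohort$patient_id
  fr <- paste(cohort$patient_id, cohort$fraction_id)
  N <- length(y)
  Zp <- outer(pt, unique(pt), `==`) * 1
  Zf <- outer(fr, unique(fr), `==`) * 1
  V <- sigma_pt^2 * tcrossprod(Zp) + sigma_fr^2 * tcrossprod(Zf) +
    sigma_intra^2 * diag(N)
  Vi <- solve(V)
  x <- rep(1, N)
  xvx <- drop(t(x) %*% Vi %*% x)
  mhat <- drop(t(x) %*% Vi %*% y) / xvx
  if (is.null(m)) m <- mhat
  r <- y - m
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * ((N - 1) * log(2 * pi) + ld + log(xvx) + drop(t(r) %*% Vi %*% r))
}

# Closed-form nested-ANOVA (expected-mean-squares) estimators for a balanced
# design: a patients x b fractions x n samples.
balanced_anova_components <- function(cohort, axis) {
  col <- c(SI = "si_mm", AP = "ap_mm", LR = "lr_mm")[[axis]]
  df <- tibble::tibble(y = cohort[[col]], pt = cohort$patient_id,
                       fr = paste(cohort$patient_id, cohort$fraction_id))
  a <- length(unique(df$pt))
  b <- length(unique(df$fr)) / a
  n <- nrow(df) / (a * b)
  stopifnot(b == round(b), n == round(n))
  gm <- mean(df$y)
  pm <- tapply(df$y, df$pt, mean)
  fm <- tapply(df$y, df$fr, mean)
  fr_pt <- tapply(df$pt, df$fr, function(z) z[1])
  ms_p <- b * n * sum((pm - gm)^2) / (a - 1)
  ms_f <- n * sum((fm - pm[fr_pt])^2) / (a * (b - 1))
  ms_e <- sum((df$y - fm[df$fr])^2) / (a * b * (n - 1))
  list(sigma_pt = sqrt(max((ms_p - ms_f) / (b * n), 0)),
       sigma_fr = sqrt(max((ms_f - ms_e) / n, 0)),
       sigma_intra = sqrt(ms_e),
       mean = gm)
}
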