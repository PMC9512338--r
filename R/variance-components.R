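## Variance-component estimation for the nested fraction-within-patient
## model of intra-fractional motion:
##
##   y_pft = m + a_p + b_pf + e_pft,
##   a_p ~ N(0, sigma_pt^2), b_pf ~ N(0, sigma_fr^2), e_pft ~ N(0, sigma_intra^2)
##
## The restricted likelihood is evaluated from per-fraction sufficient
## statistics (sample count, mean, within-fraction sum of squares): an
## orthonormal rotation of each fraction's samples separates (n-1)
## i.i.d. N(0, sigma_intra^2) contrasts from the scaled fraction mean
## u_pf = sqrt(n) ybar_pf, and the per-patient covariance of the u's is
## diag(sigma_intra^2 + n sigma_fr^2) + sigma_pt^2 q q', q = sqrt(n) —
## inverted in closed form by Sherman-Morrison.  Cost per evaluation is
## linear in the number of fractions, independent of the samples behind the
## sufficient statistics.

## Per-fraction sufficient statistics for one axis.
.suff_stats <- function(cohort, axis, thin = 1) {
  col <- .axis_cols[[.match_axes(axis)]]
  if (length(thin) != 1 || !is.finite(thin) || thin < 1 ||
      thin != round(thin)) {
    abort("thin must be a single integer stride >= 1.")
  }
  df <- tibble::tibble(pt = cohort$patient_id,
                       fr = paste(cohort$patient_id, cohort$fraction_id),
                       y = cohort[[col]])
  if (thin > 1) {
    df <- df |>
      dplyr::group_by(.data$fr) |>
      dplyr::filter((dplyr::row_number() - 1) %% thin == 0) |>
      dplyr::ungroup()
  }
  st <- df |>
    dplyr::group_by(.data$pt, .data$fr) |>
    dplyr::summarise(n = dplyr::n(), ybar = mean(.data$y),
                     sse = sum((.data$y - mean(.data$y))^2),
                     .groups = "drop")
  pt_f <- factor(st$pt)
  list(n = st$n, ybar = st$ybar, sse = st$sse,
       pt = as.integer(pt_f), patient_ids = levels(pt_f),
       N = sum(st$n), F = nrow(st), P = nlevels(pt_f),
       fractions_per_patient = as.integer(table(pt_f)))
}

## -2 * restricted log-likelihood at raw variances (sp2, sf2 may be 0).
## m = NULL profiles the mean by generalized least squares.
.reml_crit <- function(ss, sp2, sf2, se2, m = NULL) {
  if (se2 <= 0) return(list(m2l = Inf, mhat = NA_real_, xvx = NA_real_))
  n <- ss$n
  d <- se2 + n * sf2                       # Var(sqrt(n) ybar | a_p) per fraction
  s1 <- as.vector(rowsum(n / d, ss$pt))    # q' D^-1 q per patient
  cp <- 1 + sp2 * s1
  w <- as.vector(rowsum(n * ss$ybar / d, ss$pt))
  xvx <- sum(s1 / cp)                      # x' V^-1 x
  mhat <- sum(w / cp) / xvx
  mm <- if (is.null(m)) mhat else m
  dev <- ss$ybar - mm
  g <- as.vector(rowsum(n * dev / d, ss$pt))
  quad <- sum(n * dev^2 / d) - sp2 * sum(g^2 / cp)
  m2l <- (ss$N - 1) * log(2 * pi) +
    (ss$N - ss$F) * log(se2) + sum(ss$sse) / se2 +
    sum(log(d)) + sum(log(cp)) + quad + log(xvx)
  list(m2l = m2l, mhat = mhat, xvx = xvx)
}

#' Restricted log-likelihood of the nested motion model
#'
#' Evaluates the restricted (REML) log-likelihood of the nested
#' fraction-within-patient random-effects model at the given component SDs
#' and mean, for one axis of a cohort.  The criterion is
#' \eqn{-\tfrac12 [(N-1)\log 2\pi + \log|V| + \log(x'V^{-1}x) +
#' (y - xm)'V^{-1}(y - xm)]}, computed from per-fraction sufficient
#' statistics in time linear in the number of fractions; at the
#' generalized-least-squares mean it equals the usual REML log-likelihood.
#'
#' @param data A motion cohort.
#' @param axis Axis label (`"SI"`, `"AP"`, `"LR"`).
#' @param sigma_pt,sigma_fr Inter-patient and inter-fraction SDs, mm
#'   (nonnegative; 0 allowed).
#' @param sigma_intra Intra-fraction SD, mm (strictly positive).
#' @param mean Overall mean displacement, mm.  `NULL` profiles it out by
#'   generalized least squares.
#' @param thin Optional sample stride for autocorrelation sensitivity checks.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(data, axis, sigma_pt, sigma_fr, sigma_intra,
                        mean = NULL, thin = 1) {
  if (any(c(sigma_pt, sigma_fr) < 0) || sigma_intra <= 0) {
    abort("SDs must satisfy sigma_pt, sigma_fr >= 0 and sigma_intra > 0.")
  }
  ss <- .suff_stats(data, axis, thin)
  if (ss$N < 2) abort("Degenerate dataset: need at least 2 samples.")
  -0.5 * .reml_crit(ss, sigma_pt^2, sigma_fr^2, sigma_intra^2, mean)$m2l
}

## Moment estimates from sufficient statistics (starting values + hints).
.moment_from_ss <- function(ss) {
  pt_mean <- as.vector(rowsum(ss$n * ss$ybar, ss$pt)) /
    as.vector(rowsum(ss$n, ss$pt))
  Sigma <- if (ss$P > 1) sd(pt_mean) else NA_real_
  fbar_p <- as.vector(rowsum(ss$ybar, ss$pt)) / ss$fractions_per_patient
  ssq <- sum((ss$ybar - fbar_p[ss$pt])^2)
  df_fr <- sum(pmax(ss$fractions_per_patient - 1, 0))
  sigma_fr <- if (df_fr > 0) sqrt(ssq / df_fr) else 0
  sd2_fr <- ss$sse / pmax(ss$n - 1, 1)
  sigma_intra <- sqrt(mean(sd2_fr))
  list(Sigma = Sigma, sigma_fr = sigma_fr, sigma_intra = sigma_intra,
       pt_mean = pt_mean,
       overall_mean = mean(ss$ybar))
}

#' Classic moment variance components
#'
#' The conventional margin-recipe definitions: the systematic error
#' \eqn{\Sigma} is the sample SD over patients of each patient's mean
#' displacement (all samples pooled within patient), and the random error is
#' the root mean square over fractions of the within-fraction sample SDs.
#' The same decomposition additionally reports the pooled within-patient SD
#' of fraction means (`sigma_fr_mm`) so the moment components can be pushed
#' through the finite-N effective-error corrections for comparison with the
#' REML fit.  The overall mean is the unweighted mean of fraction means.
#'
#' Because each patient's mean is estimated from finitely many fractions,
#' \eqn{\Sigma} absorbs part of the inter-fraction variance (approximately
#' \eqn{\sigma_{fr}^2/N}) — the overestimation of systematic errors that the
#' nested REML fit avoids.
#'
#' @param cohort A motion cohort (at least 2 patients).
#' @param axes Axis labels, or `"all"` (default).
#' @param thin Optional sample stride.
#' @return A `variance_components` tibble, one row per axis, with
#'   `estimator = "moment"`.  Confidence-interval columns are `NA` (profile
#'   intervals are only defined for the likelihood-based fit).
#' @export
moment_components <- function(cohort, axes = "all", thin = 1) {
  axes <- .match_axes(axes)
  rows <- purrr::map_dfr(axes, function(ax) {
    ss <- .suff_stats(cohort, ax, thin)
    if (ss$P < 2) {
      abort("moment_components() needs >= 2 patients (Sigma undefined).")
    }
    mo <- .moment_from_ss(ss)
    tibble::tibble(
      axis = factor(ax, levels = .axes), estimator = "moment",
      sigma_pt_mm = mo$Sigma, sigma_pt_lo = NA_real_, sigma_pt_hi = NA_real_,
      sigma_fr_mm = mo$sigma_fr, sigma_fr_lo = NA_real_,
      sigma_fr_hi = NA_real_,
      sigma_intra_mm = mo$sigma_intra, sigma_intra_lo = NA_real_,
      sigma_intra_hi = NA_real_,
      overall_mean_mm = mo$overall_mean, mean_lo = NA_real_,
      mean_hi = NA_real_,
      ci_level = NA_real_, loglik = NA_real_, convergence = NA_integer_,
      n_patients = ss$P, n_fractions = ss$F, n_samples = ss$N)
  })
  .new_variance_components(rows, cohort)
}

.new_variance_components <- function(rows, cohort) {
  fpp <- dplyr::distinct(cohort, .data$patient_id, .data$fraction_id) |>
    dplyr::count(.data$patient_id)
  attr(rows, "fractions_per_patient") <- setNames(fpp$n, fpp$patient_id)
  class(rows) <- c("variance_components", class(tibble::tibble()))
  rows
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> estimator:",
      paste(unique(x$estimator), collapse = "/"), "\n")
  NextMethod()
}

## ---- REML fit -------------------------------------------------------------

## Minimize the criterion over log-variances with fixed multi-starts from the
## moment estimates; then test the sigma_pt = 0 / sigma_fr = 0 boundaries
## explicitly and keep an exact zero when the boundary is at least as good.
.reml_optimize <- function(ss, reltol = 1e-10) {
  mo <- .moment_from_ss(ss)
  base <- log(pmax(c(mo$Sigma^2, mo$sigma_fr^2, mo$sigma_intra^2), 1e-8))
  starts <- list(base,
                 base + c(log(4), 0, 0),
                 base + c(-8, 0, 0),
                 base + c(0, log(4), 0),
                 base + c(log(0.25), log(0.25), 0))
  obj <- function(par) {
    .reml_crit(ss, exp(par[1]), exp(par[2]), exp(par[3]))$m2l
  }
  best <- NULL
  for (s in starts) {
    opt <- optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 2000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## polish: alternate simplex restarts and quasi-Newton steps (fine
  ## finite-difference step: the criterion is analytic and cheap) until the
  ## objective stops improving
  for (i in 1:6) {
    prev <- best$value
    nm <- optim(best$par, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 3000))
    if (nm$value <= best$value) best <- nm
    bf <- tryCatch(
      optim(best$par, obj, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 500,
                           ndeps = rep(1e-6, length(best$par)))),
      error = function(e) NULL)
    if (!is.null(bf) && is.finite(bf$value) && bf$value <= best$value) {
      best <- bf
    }
    if (prev - best$value < 1e-10) break
  }
  best$convergence <- 0
  v <- exp(best$par)
  m2l <- best$value
  conv <- best$convergence
  ## boundary refits: drop a component to exactly zero when warranted
  for (k in 1:2) {
    if (sqrt(v[k]) < 1e-3) {
      free <- setdiff(1:2, k)
      obj_b <- function(par) {
        vb <- numeric(3)
        vb[k] <- 0
        vb[free] <- exp(par[1])
        vb[3] <- exp(par[2])
        .reml_crit(ss, vb[1], vb[2], vb[3])$m2l
      }
      opt_b <- optim(log(pmax(v[c(setdiff(1:2, k), 3)], 1e-10)), obj_b,
                     method = "Nelder-Mead",
                     control = list(reltol = reltol, maxit = 2000))
      polish_b <- tryCatch(
        optim(opt_b$par, obj_b, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 500,
                             ndeps = rep(1e-6, length(opt_b$par)))),
        error = function(e) NULL)
      if (!is.null(polish_b) && is.finite(polish_b$value) &&
          polish_b$value <= opt_b$value) {
        opt_b <- polish_b
        opt_b$convergence <- 0
      }
      if (opt_b$value <= m2l + 1e-6) {
        v[k] <- 0
        v[setdiff(1:2, k)] <- exp(opt_b$par[1])
        v[3] <- exp(opt_b$par[2])
        m2l <- min(m2l, opt_b$value)
        conv <- opt_b$convergence
      }
    }
  }
  if (conv != 0) {
    abort(paste0("REML optimization did not converge (code ", conv,
                 "); best -2*loglik = ", format(m2l), "."))
  }
  fit <- .reml_crit(ss, v[1], v[2], v[3])
  list(v = v, m2l = m2l, mhat = fit$mhat, xvx = fit$xvx,
       convergence = conv)
}

## Profile of the criterion with SD component k (1 = pt, 2 = fr, 3 = intra)
## fixed at `value`; inner maximization over the other two on log scale.
.pl_sd <- function(ss, k, value, start_v) {
  free <- setdiff(1:3, k)
  obj <- function(par) {
    v <- numeric(3)
    v[k] <- value^2
    v[free] <- exp(par)
    .reml_crit(ss, v[1], v[2], v[3])$m2l
  }
  opt <- optim(log(pmax(start_v[free], 1e-10)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-9, maxit = 600))
  -0.5 * opt$value
}

## Profile with the mean fixed; inner maximization over all three variances.
.pl_mean <- function(ss, value, start_v) {
  obj <- function(par) {
    .reml_crit(ss, exp(par[1]), exp(par[2]), exp(par[3]), m = value)$m2l
  }
  opt <- optim(log(pmax(start_v, 1e-10)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-9, maxit = 600))
  -0.5 * opt$value
}

## Profile-likelihood interval for SD component k, truncated at 0.
.ci_sd <- function(ss, k, est, lmax, cutoff, start_v, hint) {
  target <- function(th) .pl_sd(ss, k, th, start_v) - (lmax - cutoff)
  floor_k <- if (k == 3) max(est * 1e-3, 1e-6) else 0
  if (est <= floor_k) {
    lo <- floor_k
  } else if (target(floor_k) >= 0) {
    lo <- if (k == 3) floor_k else 0
  } else {
    lo <- uniroot(target, c(floor_k, est), tol = 1e-4)$root
  }
  hi <- max(est * 1.2, hint, 1e-3)
  tries <- 0
  while (target(hi) >= 0 && tries < 60) {
    hi <- hi * 1.5
    tries <- tries + 1
  }
  hi <- uniroot(target, c(max(est, 1e-8), hi), tol = 1e-4)$root
  c(lo, hi)
}

.ci_mean <- function(ss, mhat, lmax, cutoff, start_v, se_wald) {
  target <- function(m) .pl_mean(ss, m, start_v) - (lmax - cutoff)
  bound <- function(dir) {
    step <- max(se_wald, 1e-4)
    hi <- mhat + dir * step
    tries <- 0
    while (target(hi) >= 0 && tries < 60) {
      hi <- hi + dir * step
      tries <- tries + 1
    }
    uniroot(target, sort(c(mhat, hi)), tol = 1e-5)$root
  }
  c(bound(-1), bound(1))
}

#' REML fit of the nested motion model
#'
#' Maximizes the restricted likelihood of the nested
#' fraction-within-patient model over the three component SDs (boundary
#' estimates of exactly 0 are permitted for the patient and fraction
#' components), profiles the overall mean by generalized least squares, and
#' computes profile-likelihood confidence intervals for every component and
#' for the mean using the \eqn{\chi^2_1} cutoff, truncated below at 0 for
#' the SDs.  Optimization is derivative-free (Nelder-Mead on log variances)
#' with fixed multi-starts from the moment estimates, so the fit is
#' deterministic given the data.
#'
#' @param cohort A motion cohort (at least 2 patients, at least one patient
#'   with 2 fractions, fractions with at least 2 samples).
#' @param axes Axis labels, or `"all"` (default).
#' @param ci_level Confidence level for the profile intervals (default 0.95).
#' @param thin Optional sample stride for autocorrelation sensitivity checks.
#' @param compute_ci Set `FALSE` to skip the (more expensive) profile
#'   intervals.
#' @return A `variance_components` tibble, one row per axis, with
#'   `estimator = "reml"`, point estimates, profile CIs and the restricted
#'   log-likelihood at the optimum.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 4,
#'                                      fractions_per_patient = 6,
#'                                      duration_s = 60, seed = 2))
#' fit <- reml_fit(cohort, axes = "SI", compute_ci = FALSE)
#' @export
reml_fit <- function(cohort, axes = "all", ci_level = 0.95, thin = 1,
                     compute_ci = TRUE) {
  axes <- .match_axes(axes)
  if (length(ci_level) != 1 || ci_level <= 0 || ci_level >= 1) {
    abort("ci_level must be in (0, 1).")
  }
  cutoff <- qchisq(ci_level, df = 1) / 2
  rows <- purrr::map_dfr(axes, function(ax) {
    ss <- .suff_stats(cohort, ax, thin)
    if (ss$P < 2) abort("reml_fit() needs >= 2 patients.")
    if (max(ss$fractions_per_patient) < 2) {
      abort("reml_fit() needs >= 2 fractions for at least one patient.")
    }
    if (ss$N <= ss$F) {
      abort("reml_fit() needs >= 2 samples per fraction (no residual df).")
    }
    opt <- .reml_optimize(ss)
    est <- sqrt(opt$v)
    lmax <- -0.5 * opt$m2l
    mo <- .moment_from_ss(ss)
    hints <- c(max(mo$Sigma, 0.05, na.rm = TRUE), mo$sigma_fr * 2 + 0.05,
               mo$sigma_intra * 1.5)
    if (compute_ci) {
      cis <- lapply(1:3, function(k)
        .ci_sd(ss, k, est[k], lmax, cutoff, opt$v, hints[k]))
      se_wald <- sqrt(1 / opt$xvx)
      ci_m <- .ci_mean(ss, opt$mhat, lmax, cutoff, opt$v, se_wald)
    } else {
      cis <- rep(list(c(NA_real_, NA_real_)), 3)
      ci_m <- c(NA_real_, NA_real_)
    }
    tibble::tibble(
      axis = factor(ax, levels = .axes), estimator = "reml",
      sigma_pt_mm = est[1], sigma_pt_lo = cis[[1]][1],
      sigma_pt_hi = cis[[1]][2],
      sigma_fr_mm = est[2], sigma_fr_lo = cis[[2]][1],
      sigma_fr_hi = cis[[2]][2],
      sigma_intra_mm = est[3], sigma_intra_lo = cis[[3]][1],
      sigma_intra_hi = cis[[3]][2],
      overall_mean_mm = opt$mhat, mean_lo = ci_m[1], mean_hi = ci_m[2],
      ci_level = ci_level, loglik = lmax, convergence = opt$convergence,
      n_patients = ss$P, n_fractions = ss$F, n_samples = ss$N)
  })
  .new_variance_components(rows, cohort)
}
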