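Z975 <- 1.959963985

mr_estimate_row <- function(method, beta, se, pval, k_used,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_pval = NA_real_,
                            n_boot = NA_integer_,
                            note = NA_character_) {
  to_or(tibble::tibble(
    method = method, beta = beta, se = se,
    ci_low = NA_real_, ci_high = NA_real_,
    or = NA_real_, or_low = NA_real_, or_high = NA_real_,
    pval = pval, k_used = as.integer(k_used),
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval,
    n_boot = as.integer(n_boot), note = note
  ))
}

not_computable <- function(method, k, need) {
  mr_estimate_row(method, NA_real_, NA_real_, NA_real_, k,
                  note = sprintf("not_computable: k = %d < %d", k, need))
}

#' Attach 95% confidence intervals and odds-ratio scale to an estimate
#'
#' Fills `ci_low`/`ci_high` as `beta +/- 1.959963985 * se` (the normal 97.5%
#' quantile, matching the 95% CI convention) and the odds-ratio triple as
#' the elementwise exponential, so a log-odds causal estimate reads as an
#' OR. Idempotent: the intervals are always recomputed from `beta` and
#' `se`.
#'
#' @param est A one-or-more-row estimates tibble with `beta` and `se`.
#' @return The tibble with `ci_low`, `ci_high`, `or`, `or_low`, `or_high`
#'   filled.
#' @export
to_or <- function(est) {
  stopifnot(is.data.frame(est), all(c("beta", "se") %in% names(est)))
  est$ci_low <- est$beta - Z975 * est$se
  est$ci_high <- est$beta + Z975 * est$se
  est$or <- exp(est$beta)
  est$or_low <- exp(est$ci_low)
  est$or_high <- exp(est$ci_high)
  est
}

# ---- numeric kernels (vectors in, numbers out) ------------------------------

ivw_kernel <- function(b_x, b_y, s_y) {
  w <- b_x^2 / s_y^2
  ratio <- b_y / b_x
  beta <- sum(w * ratio) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  list(beta = beta, se_fe = se_fe, Q = Q, k = length(b_x))
}

egger_kernel <- function(b_x, b_y, s_y) {
  # Egger regression is not orientation-invariant: fix orientation b_x >= 0
  sgn <- ifelse(b_x < 0, -1, 1)
  x <- b_x * sgn
  y <- b_y * sgn
  w <- 1 / s_y^2
  k <- length(x)
  # weighted normal equations for y ~ 1 + x
  X <- cbind(intercept = 1, x = x)
  A <- crossprod(X, w * X)
  coefs <- drop(solve(A, crossprod(X, w * y)))
  r <- y - drop(X %*% coefs)
  rss_w <- sum(w * r^2)
  sigma2 <- rss_w / (k - 2)
  # multiplicative overdispersion, floored at 1 so homogeneity never
  # shrinks the SEs below the known-variance ones
  se_unscaled <- sqrt(diag(solve(A)))
  se <- se_unscaled * sqrt(max(1, sigma2))
  list(slope = coefs[["x"]], slope_se = se[["x"]],
       slope_p = 2 * stats::pt(-abs(coefs[["x"]] / se[["x"]]), df = k - 2),
       intercept = coefs[["intercept"]], intercept_se = se[["intercept"]],
       intercept_p = 2 * stats::pt(-abs(coefs[["intercept"]] /
                                          se[["intercept"]]), df = k - 2),
       rss_w = rss_w, k = k)
}

wme_kernel <- function(b_x, b_y, s_y) {
  ratio <- b_y / b_x
  w <- b_x^2 / s_y^2
  w <- w / sum(w)
  ord <- order(ratio)
  r <- ratio[ord]
  q <- cumsum(w[ord]) - w[ord] / 2
  if (q[1] >= 0.5) return(r[1])
  if (q[length(q)] <= 0.5) return(r[length(r)])
  stats::approx(q, r, xout = 0.5, ties = "ordered")$y
}

# ---- user-facing estimators -------------------------------------------------

#' Wald ratio causal estimate from a single SNP
#'
#' `beta = b_y / b_x`, `se = s_y / |b_x|` (first-order delta method,
#' treating the exposure effect as fixed); two-sided normal p-value.
#'
#' @param dat A harmonized tibble (or `instrument_set`) with exactly the
#'   SNP(s) to use; with several rows, the first is used.
#' @return A one-row estimates tibble (see [mr_ivw()] for columns).
#' @export
mr_wald <- function(dat) {
  d <- harmonized_data(dat)
  stopifnot(nrow(d) >= 1L)
  d <- d[1L, ]
  if (d$b_x == 0) stop("mr_wald: exposure effect is zero", call. = FALSE)
  beta <- d$b_y / d$b_x
  se <- d$s_y / abs(d$b_x)
  mr_estimate_row("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with weights
#' `w_j = b_x^2 / s_y^2` — algebraically the weighted least-squares slope
#' of the outcome effects on the exposure effects through the origin with
#' weights `1/s_y^2`. The fixed-effects standard error is
#' `(sum w)^(-1/2)`; the multiplicative random-effects model inflates it by
#' `sqrt(max(1, Q/(k-1)))` where Q is Cochran's heterogeneity statistic, so
#' heterogeneity widens the interval but homogeneity never narrows it below
#' the fixed-effects one. P-values are two-sided normal.
#'
#' @param dat Harmonized tibble or `instrument_set` (k >= 2; with k = 1 the
#'   function falls back to the Wald ratio with a note).
#' @param model `"random"` (default) or `"fixed"`.
#' @return A one-row tibble: `method`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `or`, `or_low`, `or_high`, `pval`, `k_used`, Egger-intercept columns
#'   (NA here), `n_boot`, `note`.
#' @export
mr_ivw <- function(dat, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- harmonized_data(dat)
  k <- nrow(d)
  if (k < 1L) return(not_computable(paste0("ivw_", substr(model, 1, 2)), k, 1L))
  if (k < 2L) {
    est <- mr_wald(d)
    est$note <- "k = 1: fell back to Wald ratio"
    return(est)
  }
  fit <- ivw_kernel(d$b_x, d$b_y, d$s_y)
  se <- if (model == "fixed") fit$se_fe
        else fit$se_fe * sqrt(max(1, fit$Q / (k - 1)))
  mr_estimate_row(paste0("ivw_", substr(model, 1, 2)), fit$beta, se,
                  2 * stats::pnorm(-abs(fit$beta / se)), k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' unconstrained intercept (weights `1/s_y^2`), each SNP oriented so its
#' exposure effect is non-negative. The slope is a pleiotropy-adjusted
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect. Standard errors carry a multiplicative
#' overdispersion factor `sqrt(max(1, RSS_w/(k-2)))` and p-values use the t
#' distribution with k-2 degrees of freedom.
#'
#' @param dat Harmonized tibble or `instrument_set`; needs k >= 3 (returns
#'   a not-computable marker row otherwise, so pipelines can still report
#'   the other estimators).
#' @return A one-row estimates tibble with the intercept triple in
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`.
#' @export
mr_egger <- function(dat) {
  d <- harmonized_data(dat)
  k <- nrow(d)
  if (k < 3L) return(not_computable("egger", k, 3L))
  fit <- egger_kernel(d$b_x, d$b_y, d$s_y)
  mr_estimate_row("egger", fit$slope, fit$slope_se, fit$slope_p, k,
                  egger_intercept = fit$intercept,
                  egger_intercept_se = fit$intercept_se,
                  egger_intercept_pval = fit$intercept_p)
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios (weights
#' `b_x^2/s_y^2` normalized to sum 1): ratios are sorted, cumulative
#' midpoint weights `q_j = sum(w_(1..j)) - w_j/2` computed, and the
#' estimate is the linear interpolation of the sorted ratios against `q` at
#' `q = 0.5`. Consistent as long as at least half the weight comes from
#' valid instruments. The standard error is the SD of the estimate over
#' `n_boot` parametric-bootstrap replicates (effects resampled from their
#' reported normal sampling distributions); the p-value is two-sided
#' normal.
#'
#' @param dat Harmonized tibble or `instrument_set`; needs k >= 3.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (local RNG; global state untouched).
#' @return A one-row estimates tibble.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000L, seed = 1L) {
  d <- harmonized_data(dat)
  k <- nrow(d)
  if (k < 3L) return(not_computable("wme", k, 3L))
  beta <- wme_kernel(d$b_x, d$b_y, d$s_y)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, d$b_x, d$s_x)
      by <- stats::rnorm(k, d$b_y, d$s_y)
      wme_kernel(bx, by, d$s_y)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate_row("wme", beta, se, 2 * stats::pnorm(-abs(beta / se)), k,
                  n_boot = n_boot)
}

#' Run all causal estimators and the sensitivity battery on one exposure
#'
#' Convenience fit object for a single harmonized exposure-outcome pair:
#' computes fixed- and random-effects IVW, MR-Egger, the weighted median,
#' Cochran's Q for the IVW and Egger models, the Egger intercept test,
#' MR-PRESSO, the leave-one-out series and the Steiger directionality
#' test. Use [generics::tidy()] for the estimates table,
#' [generics::glance()] for the one-row diagnostic summary, and
#' `ggplot2::autoplot()` for the scatter plot with fitted lines.
#'
#' @param dat Harmonized tibble or `instrument_set`.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param seed Seed for the bootstrap and MR-PRESSO.
#' @param exposure Label for reports.
#' @return An object of class `mr_fit`.
#' @export
fit_mr <- function(dat, n_boot = 1000L, presso_n_sim = 1000L, seed = 1L,
                   exposure = NULL) {
  iset <- if (inherits(dat, "instrument_set")) dat else NULL
  d <- harmonized_data(dat)
  exposure <- exposure %||% (if (!is.null(iset)) iset$exposure else "exposure")
  estimates <- dplyr::bind_rows(
    mr_ivw(d, "fixed"), mr_ivw(d, "random"), mr_egger(d),
    mr_weighted_median(d, n_boot = n_boot, seed = seed)
  )
  sens <- list(
    q_ivw = cochran_q(d, "ivw"),
    q_egger = cochran_q(d, "egger"),
    egger_intercept = egger_intercept_test(d),
    presso = if (nrow(d) >= 4L)
      mr_presso(d, n_sim = presso_n_sim, seed = seed) else NULL,
    loo = if (nrow(d) >= 3L) leave_one_out(d) else NULL,
    steiger = steiger_test(d)
  )
  structure(list(exposure = exposure, data = d, instrument_set = iset,
                 estimates = estimates, sensitivity = sens),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s (k = %d instruments)\n", x$exposure, nrow(x$data)))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    if (!is.na(est$beta[i])) {
      cat(sprintf("  %-7s OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                  est$method[i], est$or[i], est$or_low[i], est$or_high[i],
                  est$pval[i]))
    } else {
      cat(sprintf("  %-7s %s\n", est$method[i], est$note[i]))
    }
  }
  invisible(x)
}

#' @rdname fit_mr
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(exposure = x$exposure), x$estimates)
}

#' @rdname fit_mr
#' @exportS3Method generics::glance
glance.mr_fit <- function(x, ...) {
  est <- x$estimates
  pick <- function(m, col) {
    v <- est[[col]][est$method == m]
    if (length(v) == 0L) NA_real_ else v
  }
  s <- x$sensitivity
  tibble::tibble(
    exposure = x$exposure,
    k = nrow(x$data),
    R2 = if (!is.null(x$instrument_set)) x$instrument_set$R2 else NA_real_,
    F_overall = if (!is.null(x$instrument_set)) x$instrument_set$F_overall
                else NA_real_,
    beta_ivw = pick("ivw_ra", "beta"), p_ivw = pick("ivw_ra", "pval"),
    q_ivw_pval = s$q_ivw$pval, q_egger_pval = s$q_egger$pval,
    egger_intercept = s$egger_intercept$intercept,
    egger_intercept_pval = s$egger_intercept$pval,
    presso_global_pval = if (!is.null(s$presso)) s$presso$global_pval
                         else NA_real_,
    presso_n_outliers = if (!is.null(s$presso))
      length(s$presso$outlier_snps) else NA_integer_,
    steiger_direction_ok = s$steiger$direction_ok,
    steiger_pval = s$steiger$pval
  )
}
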