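#' Cochran's Q heterogeneity test
#'
#' For the IVW model, `Q = sum(w_j (ratio_j - beta_ivw)^2)` with
#' `w_j = b_x^2/s_y^2` and `beta_ivw` the fixed-effects estimate, referred
#' to a chi-square with k-1 degrees of freedom. For the Egger model, Q is
#' the weighted residual sum of squares of the Egger fit (weights
#' `1/s_y^2`) on k-2 degrees of freedom. Excess Q signals per-SNP effect
#' heterogeneity — pleiotropy, outliers, or mismatched populations.
#'
#' @param dat Harmonized tibble or `instrument_set`.
#' @param method `"ivw"` (needs k >= 2) or `"egger"` (k >= 3).
#' @return A one-row tibble: `method`, `Q`, `df`, `pval` (NA row with a
#'   note when k is too small).
#' @export
cochran_q <- function(dat, method = c("ivw", "egger")) {
  method <- match.arg(method)
  d <- harmonized_data(dat)
  k <- nrow(d)
  need <- if (method == "ivw") 2L else 3L
  if (k < need) {
    return(tibble::tibble(method = method, Q = NA_real_, df = NA_integer_,
                          pval = NA_real_,
                          note = sprintf("not_computable: k = %d < %d",
                                         k, need)))
  }
  if (method == "ivw") {
    fit <- ivw_kernel(d$b_x, d$b_y, d$s_y)
    Q <- fit$Q
    df <- k - 1L
  } else {
    fit <- egger_kernel(d$b_x, d$b_y, d$s_y)
    Q <- fit$rss_w
    df <- k - 2L
  }
  tibble::tibble(method = method, Q = Q, df = df,
                 pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 note = NA_character_)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept triple from the Egger regression
#' ([mr_egger()]). An intercept near zero means little average directional
#' pleiotropy; by the conventional rule, pleiotropy is declared absent when
#' the intercept p-value exceeds 0.05.
#'
#' @param dat Harmonized tibble or `instrument_set` (k >= 3).
#' @return A one-row tibble: `intercept`, `se`, `pval`,
#'   `pleiotropy_absent` (`pval > 0.05`).
#' @export
egger_intercept_test <- function(dat) {
  est <- mr_egger(dat)
  tibble::tibble(intercept = est$egger_intercept,
                 se = est$egger_intercept_se,
                 pval = est$egger_intercept_pval,
                 pleiotropy_absent = ifelse(is.na(est$egger_intercept_pval),
                                            NA, est$egger_intercept_pval > 0.05))
}

# leave-one-out IVW fixed-effect slopes for every j at once
loo_slopes <- function(b_x, b_y, s_y) {
  wxy <- b_x * b_y / s_y^2
  wxx <- b_x^2 / s_y^2
  (sum(wxy) - wxy) / (sum(wxx) - wxx)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based residual-sum-of-squares framework for detecting
#' horizontally pleiotropic outlier SNPs. For each SNP j the observed
#' residual is `e_j = b_y,j - beta_(-j) * b_x,j`, where `beta_(-j)` is the
#' leave-j-out fixed-effects IVW slope; the observed RSS is
#' `sum(e_j^2 / s_y,j^2)`. The null distribution comes from `n_sim`
#' parametric replicates (`b*_x,j ~ N(b_x,j, s_x,j^2)`,
#' `b*_y,j ~ N(beta_(-j) b_x,j, s_y,j^2)`), each processed identically.
#' The global p-value is the +1-corrected upper-tail empirical p of the
#' RSS; per-SNP outlier p-values compare each weighted squared residual
#' with its simulated counterparts and are Bonferroni-multiplied by k;
#' when outliers are found, the distortion test compares the
#' outlier-removed IVW estimate with the distribution of estimates under
#' random same-size removals (two-sided empirical p).
#'
#' @param dat Harmonized tibble or `instrument_set`; needs k >= 4.
#' @param n_sim Simulation replicates (default 1000); the smallest
#'   attainable p-value is `1/(n_sim + 1)`.
#' @param seed Local RNG seed; identical data + seed give bit-identical
#'   results.
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-value for calling an outlier (default 0.05).
#' @return An object of class `mr_presso`: a list with `rss_observed`,
#'   `global_pval`, `outlier_table` (tibble: snp_id, pval, pval_adjusted,
#'   outlier), `outlier_snps`, `distortion_pval` (NA when no outliers),
#'   `beta_raw`, `beta_outlier_corrected`, `n_sim`, `seed`.
#' @export
mr_presso <- function(dat, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  d <- harmonized_data(dat)
  k <- nrow(d)
  if (k < 4L) {
    return(structure(list(rss_observed = NA_real_, global_pval = NA_real_,
                          outlier_table = NULL, outlier_snps = character(),
                          distortion_pval = NA_real_, beta_raw = NA_real_,
                          beta_outlier_corrected = NA_real_,
                          n_sim = as.integer(n_sim), seed = as.integer(seed),
                          note = sprintf("not_computable: k = %d < 4", k)),
                     class = "mr_presso"))
  }
  w <- 1 / d$s_y^2
  beta_mj <- loo_slopes(d$b_x, d$b_y, d$s_y)
  e_obs <- d$b_y - beta_mj * d$b_x
  rss_obs <- sum(e_obs^2 * w)
  wr_obs <- e_obs^2 * w

  withr::with_seed(as.integer(seed), {
    # n_sim x k matrices; each row is one simulated dataset
    bx_s <- matrix(stats::rnorm(n_sim * k, mean = rep(d$b_x, each = n_sim),
                                sd = rep(d$s_x, each = n_sim)), n_sim, k)
    by_s <- matrix(stats::rnorm(n_sim * k,
                                mean = rep(beta_mj * d$b_x, each = n_sim),
                                sd = rep(d$s_y, each = n_sim)), n_sim, k)
    wm <- matrix(w, n_sim, k, byrow = TRUE)
    wxy <- bx_s * by_s * wm
    wxx <- bx_s^2 * wm
    beta_mj_s <- (rowSums(wxy) - wxy) / (rowSums(wxx) - wxx)
    e_s <- by_s - beta_mj_s * bx_s
    wr_s <- e_s^2 * wm
    rss_s <- rowSums(wr_s)

    global_pval <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
    p_snp <- (1 + colSums(wr_s >= matrix(wr_obs, n_sim, k, byrow = TRUE))) /
      (n_sim + 1)
    p_adj <- pmin(1, p_snp * k)
    is_out <- p_adj < outlier_alpha

    beta_raw <- ivw_kernel(d$b_x, d$b_y, d$s_y)$beta
    outlier_snps <- d$snp_id[is_out]
    beta_corr <- NA_real_
    distortion_pval <- NA_real_
    n_out <- sum(is_out)
    if (n_out > 0L && n_out < k - 1L) {
      keep <- !is_out
      beta_corr <- ivw_kernel(d$b_x[keep], d$b_y[keep], d$s_y[keep])$beta
      beta_rand <- vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(k, n_out)
        ivw_kernel(d$b_x[-drop], d$b_y[-drop], d$s_y[-drop])$beta
      }, numeric(1))
      lo <- (1 + sum(beta_rand <= beta_corr)) / (n_sim + 1)
      hi <- (1 + sum(beta_rand >= beta_corr)) / (n_sim + 1)
      distortion_pval <- min(1, 2 * min(lo, hi))
    }
  })

  structure(list(
    rss_observed = rss_obs, global_pval = global_pval,
    outlier_table = tibble::tibble(snp_id = d$snp_id, pval = p_snp,
                                   pval_adjusted = p_adj, outlier = is_out),
    outlier_snps = outlier_snps, distortion_pval = distortion_pval,
    beta_raw = beta_raw, beta_outlier_corrected = beta_corr,
    n_sim = as.integer(n_sim), seed = as.integer(seed), note = NA_character_
  ), class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  if (!is.na(x$note %||% NA)) {
    cat("<mr_presso>", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("<mr_presso> RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_observed, x$global_pval, x$n_sim))
  if (length(x$outlier_snps) > 0L) {
    cat("  outliers:", paste(x$outlier_snps, collapse = ", "),
        sprintf("| beta %.4g -> %.4g (distortion p = %.3g)\n",
                x$beta_raw, x$beta_outlier_corrected, x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' @rdname mr_presso
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_presso <- function(x, ...) {
  x$outlier_table %||%
    tibble::tibble(snp_id = character(), pval = double(),
                   pval_adjusted = double(), outlier = logical())
}

#' @rdname mr_presso
#' @exportS3Method generics::glance
glance.mr_presso <- function(x, ...) {
  tibble::tibble(rss_observed = x$rss_observed, global_pval = x$global_pval,
                 n_outliers = length(x$outlier_snps),
                 distortion_pval = x$distortion_pval,
                 beta_raw = x$beta_raw,
                 beta_outlier_corrected = x$beta_outlier_corrected,
                 n_sim = x$n_sim)
}

#' Leave-one-out influence series
#'
#' Repeats the random-effects IVW estimate with each SNP omitted in turn,
#' plus the all-SNP row, and flags omissions that flip the sign of the
#' estimate or move it across the p = 0.05 line relative to the full set —
#' the signature of a single influential variant.
#'
#' @param dat Harmonized tibble or `instrument_set`; needs k >= 3.
#' @return A tibble of k + 1 rows: `snp_omitted` (`"(none)"` for the full
#'   set, last row), `beta`, `se`, `pval`, `sign_change`,
#'   `crosses_alpha`.
#' @export
leave_one_out <- function(dat) {
  d <- harmonized_data(dat)
  k <- nrow(d)
  if (k < 3L) stop("leave_one_out: need k >= 3", call. = FALSE)
  rows <- lapply(seq_len(k), function(j) {
    est <- mr_ivw(d[-j, , drop = FALSE], "random")
    tibble::tibble(snp_omitted = d$snp_id[j], beta = est$beta, se = est$se,
                   pval = est$pval)
  })
  full <- mr_ivw(d, "random")
  out <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble::tibble(snp_omitted = "(none)", beta = full$beta, se = full$se,
                   pval = full$pval)
  )
  out$sign_change <- sign(out$beta) != sign(full$beta)
  out$crosses_alpha <- (out$pval < 0.05) != (full$pval < 0.05)
  out
}

#' Steiger directionality test
#'
#' Checks that the instruments explain more variance in the exposure than
#' in the outcome, as they must if causation runs exposure to outcome.
#' Per-SNP variance explained on each trait is recovered from the
#' t-statistic (`t^2/(t^2 + n - 2)`) and summed over instruments (clipped
#' below 1). The z statistic compares the Fisher-transformed multiple
#' correlations, `z = (atanh(sqrt(R2_x)) - atanh(sqrt(R2_y))) /
#' sqrt(1/(n_x - 3) + 1/(n_y - 3))` — the independent-samples form, since
#' the exposure and outcome GWAS come from non-overlapping cohorts in
#' two-sample MR.
#'
#' @param dat Harmonized tibble or `instrument_set` with `n_x` and `n_y`.
#' @return A one-row tibble: `r2_exposure`, `r2_outcome`, `direction_ok`,
#'   `steiger_z`, `pval`.
#' @export
steiger_test <- function(dat) {
  d <- harmonized_data(dat)
  stopifnot(nrow(d) >= 1L)
  if (!all(c("n_x", "n_y") %in% names(d)) || anyNA(d$n_x) || anyNA(d$n_y)) {
    stop("steiger_test: exposure and outcome sample sizes are required",
         call. = FALSE)
  }
  n_x <- stats::median(d$n_x)
  n_y <- stats::median(d$n_y)
  t2x <- (d$b_x / d$s_x)^2
  t2y <- (d$b_y / d$s_y)^2
  r2x <- min(sum(t2x / (t2x + n_x - 2)), 1 - 1e-12)
  r2y <- min(sum(t2y / (t2y + n_y - 2)), 1 - 1e-12)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  tibble::tibble(r2_exposure = r2x, r2_outcome = r2y,
                 direction_ok = r2x > r2y, steiger_z = z,
                 pval = 2 * stats::pnorm(-abs(z)))
}
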