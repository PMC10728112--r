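#' Scatter plot of per-SNP effects with fitted causal slopes
#'
#' One point per instrument (outcome effect against exposure effect, with
#' +/- 1 SE error bars) and one line per estimator: IVW through the origin,
#' MR-Egger with its intercept, and the weighted median. Divergent slopes
#' are the visual signature of pleiotropy.
#'
#' @param object An `mr_fit` from [fit_mr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_fit <- function(object, ...) {
  d <- object$data
  est <- object$estimates
  g <- function(m, col) {
    v <- est[[col]][est$method == m]
    if (length(v) == 0L) NA_real_ else v
  }
  lines <- tibble::tibble(
    method = c("IVW (random)", "MR-Egger", "Weighted median"),
    slope = c(g("ivw_ra", "beta"), g("egger", "beta"), g("wme", "beta")),
    intercept = c(0, g("egger", "egger_intercept"), 0)
  )
  lines <- lines[!is.na(lines$slope), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b_x, y = .data$b_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b_y - .data$s_y,
                                        ymax = .data$b_y + .data$s_y),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$b_x - .data$s_x,
                                         xmax = .data$b_x + .data$s_x),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = NULL, title = object$exposure) +
    ggplot2::theme_minimal()
}

#' Forest plot of a leave-one-out series
#'
#' @param loo A tibble from [leave_one_out()] (optionally with an
#'   `exposure` column, ignored).
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  stopifnot(is.data.frame(loo), all(c("snp_omitted", "beta", "se") %in%
                                      names(loo)))
  loo$snp_omitted <- factor(loo$snp_omitted,
                            levels = rev(unique(loo$snp_omitted)))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$snp_omitted)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.959963985 * .data$se,
                   xmax = .data$beta + 1.959963985 * .data$se),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate (log OR) with SNP omitted",
                  y = "Omitted SNP") +
    ggplot2::theme_minimal()
}

#' Forest plot of significant screen hits
#'
#' Odds ratios with 95% confidence intervals for every exposure passing the
#' significance rule (or all exposures when none do).
#'
#' @param object An `mr_screen` from [mr_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_screen <- function(object, ...) {
  res <- object$results
  if (any(res$significant)) res <- res[res$significant, , drop = FALSE]
  res$exposure <- factor(res$exposure, levels = rev(res$exposure))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$or_ivw, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low_ivw,
                                         xmax = .data$or_high_ivw),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI), IVW", y = NULL) +
    ggplot2::theme_minimal()
}
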