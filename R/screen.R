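# deterministic 31-bit string hash so per-exposure seeds depend only on the
# base seed and the exposure label, never on processing order
string_seed <- function(label, base_seed) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

#' Run the full MR pipeline for one exposure-outcome pair
#'
#' Applies, in order: the p-value relevance filter, the confounder
#' exclusion list, greedy LD clumping, allele harmonization, the
#' F-statistic weak-instrument filter, then all estimators and the
#' sensitivity battery on the post-filter instrument set.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param ld Pairwise LD tibble (`snp_a`, `snp_b`, `r2`) or `NULL`.
#' @param exclude Character vector (or one-id-per-line file) of SNPs to
#'   exclude as confounder-associated.
#' @param pval_threshold,clump_r2,clump_kb,f_min Selection thresholds; the
#'   defaults (1e-5, 0.001, 10000 kb, 10) are the standard screening
#'   settings.
#' @param palindrome_policy Passed to [harmonize()].
#' @param n_boot,presso_n_sim,seed Passed to the estimators and MR-PRESSO.
#' @param label Exposure label for reports.
#' @return An `mr_fit` (see [fit_mr()]) whose `instrument_set` carries the
#'   per-stage selection log, or an object of class `mr_skip` when no
#'   instrument survives.
#' @export
mr_pipeline <- function(exposure, outcome, ld = NULL, exclude = character(),
                        pval_threshold = 1e-5, clump_r2 = 0.001,
                        clump_kb = 10000, f_min = 10,
                        palindrome_policy = "drop",
                        n_boot = 1000L, presso_n_sim = 1000L, seed = 1L,
                        label = "exposure") {
  stages <- list()
  x <- filter_pvalue(exposure, pval_threshold)
  stages$filter_pvalue <- load_report(x)
  x <- exclude_snps(x, exclude)
  stages$exclude_snps <- load_report(x)
  x <- clump_instruments(x, ld, r2_max = clump_r2, window_kb = clump_kb)
  stages$clump <- load_report(x)
  h <- harmonize(x, outcome, palindrome_policy = palindrome_policy)
  stages$harmonize <- load_report(h)
  iset <- filter_weak(h, f_min = f_min, exposure = label)
  stages$filter_weak <- iset$log
  iset$log <- stages
  if (!iset$analyzable || iset$k == 0L) {
    return(structure(list(exposure = label, instrument_set = iset,
                          reason = "no instruments after weak-instrument filter"),
                     class = "mr_skip"))
  }
  fit <- fit_mr(iset, n_boot = n_boot, presso_n_sim = presso_n_sim,
                seed = seed, exposure = label)
  fit
}

#' Screen many exposures against one outcome
#'
#' Runs [mr_pipeline()] independently for every exposure (results are
#' identical whatever the processing order: each exposure's stochastic
#' steps are seeded from the base seed and the exposure label alone) and
#' assembles one row per analyzable exposure, sorted by IVW p-value.
#' Significance is called at nominal `alpha` on the selected IVW model with
#' no multiplicity correction — the convention of hypothesis-generating
#' metabolome-wide screens — but Bonferroni- and FDR-adjusted columns are
#' emitted alongside so stricter rules can be applied downstream.
#'
#' @param exposures Named list of exposure summary-statistics tibbles, or a
#'   character vector of file paths (names default to file names).
#' @param outcome Outcome summary-statistics tibble or file path.
#' @param colmap [column_map()] used when reading file paths.
#' @param ld LD tibble or 3-column TSV path.
#' @param exclude Confounder exclusion list (vector or file).
#' @param pval_threshold,clump_r2,clump_kb,f_min,alpha Thresholds.
#' @param ivw_model IVW model used for the significance call: `"random"`
#'   (default, robust to heterogeneity) or `"fixed"`.
#' @param palindrome_policy Passed to [harmonize()].
#' @param n_boot,presso_n_sim Monte-Carlo sizes.
#' @param seed Base seed.
#' @return An object of class `mr_screen`: list with `results` (tibble, one
#'   row per analyzable exposure), `fits` (named list of `mr_fit`),
#'   `skipped` (tibble of exposures with no usable instruments) and
#'   `manifest` (thresholds, seeds, counts, file hashes).
#' @export
mr_screen <- function(exposures, outcome, colmap = column_map(), ld = NULL,
                      exclude = character(),
                      pval_threshold = 1e-5, clump_r2 = 0.001,
                      clump_kb = 10000, f_min = 10, alpha = 0.05,
                      ivw_model = c("random", "fixed"),
                      palindrome_policy = "drop",
                      n_boot = 1000L, presso_n_sim = 1000L, seed = 1L) {
  ivw_model <- match.arg(ivw_model)
  file_hashes <- character()
  if (is.character(exposures)) {
    paths <- exposures
    nm <- names(paths) %||% basename(paths)
    nm[!nzchar(nm)] <- basename(paths)[!nzchar(nm)]
    file_hashes <- c(file_hashes, stats::setNames(tools::md5sum(paths), nm))
    exposures <- stats::setNames(lapply(paths, read_summary_stats, colmap = colmap), nm)
  }
  if (is.character(outcome)) {
    file_hashes <- c(file_hashes,
                     stats::setNames(tools::md5sum(outcome), "outcome"))
    outcome <- read_summary_stats(outcome, colmap = colmap)
  }
  if (is.character(ld) && length(ld) == 1L) ld <- read_mr_table(ld)
  if (length(exposures) == 0L) {
    warning("mr_screen: no exposures supplied", call. = FALSE)
    return(structure(list(results = empty_screen_rows(),
                          fits = list(), skipped = tibble::tibble(
                            exposure = character(), reason = character()),
                          manifest = list()), class = "mr_screen"))
  }
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- sprintf("exposure_%03d", seq_along(exposures))
  }

  fits <- list()
  skipped <- list()
  for (label in names(exposures)) {
    res <- tryCatch(
      mr_pipeline(exposures[[label]], outcome, ld = ld, exclude = exclude,
                  pval_threshold = pval_threshold, clump_r2 = clump_r2,
                  clump_kb = clump_kb, f_min = f_min,
                  palindrome_policy = palindrome_policy,
                  n_boot = n_boot, presso_n_sim = presso_n_sim,
                  seed = string_seed(label, seed), label = label),
      error = function(e) {
        structure(list(exposure = label, reason = conditionMessage(e)),
                  class = "mr_skip")
      }
    )
    if (inherits(res, "mr_skip")) {
      skipped[[label]] <- tibble::tibble(exposure = label,
                                         reason = res$reason)
    } else {
      fits[[label]] <- res
    }
  }

  results <- dplyr::bind_rows(lapply(fits, screen_row,
                                     ivw_model = ivw_model, alpha = alpha))
  if (nrow(results) > 0L) {
    results <- dplyr::arrange(results, .data$p_ivw)
    results$p_ivw_bonferroni <- pmin(1, results$p_ivw * nrow(results))
    results$p_ivw_fdr <- stats::p.adjust(results$p_ivw, method = "BH")
  } else {
    results <- empty_screen_rows()
  }

  manifest <- list(
    pval_threshold = pval_threshold, clump_r2 = clump_r2,
    clump_kb = clump_kb, f_min = f_min, alpha = alpha,
    ivw_model = ivw_model, palindrome_policy = palindrome_policy,
    n_boot = n_boot, presso_n_sim = presso_n_sim, seed = seed,
    n_exposures = length(exposures), n_analyzable = length(fits),
    n_skipped = length(skipped),
    file_hashes = as.list(file_hashes),
    stage_counts = lapply(fits, function(f) f$instrument_set$log)
  )
  structure(list(results = results, fits = fits,
                 skipped = dplyr::bind_rows(skipped) %||%
                   tibble::tibble(exposure = character(),
                                  reason = character()),
                 manifest = manifest),
            class = "mr_screen")
}

screen_row <- function(fit, ivw_model, alpha) {
  est <- fit$estimates
  g <- function(m, col) {
    v <- est[[col]][est$method == m]
    if (length(v) == 0L) NA_real_ else v
  }
  sel <- if (ivw_model == "random") "ivw_ra" else "ivw_fi"
  s <- fit$sensitivity
  iset <- fit$instrument_set
  signs <- sign(c(g(sel, "beta"), g("egger", "beta"), g("wme", "beta")))
  tibble::tibble(
    exposure = fit$exposure,
    k = nrow(fit$data),
    R2 = if (!is.null(iset)) iset$R2 else NA_real_,
    F_overall = if (!is.null(iset)) iset$F_overall else NA_real_,
    beta_ivw = g(sel, "beta"), se_ivw = g(sel, "se"), p_ivw = g(sel, "pval"),
    or_ivw = g(sel, "or"), or_low_ivw = g(sel, "or_low"),
    or_high_ivw = g(sel, "or_high"),
    ivw_model = ivw_model,
    beta_ivw_fe = g("ivw_fi", "beta"), p_ivw_fe = g("ivw_fi", "pval"),
    beta_ivw_re = g("ivw_ra", "beta"), p_ivw_re = g("ivw_ra", "pval"),
    beta_egger = g("egger", "beta"), p_egger = g("egger", "pval"),
    beta_wme = g("wme", "beta"), p_wme = g("wme", "pval"),
    q_ivw_pval = s$q_ivw$pval, q_egger_pval = s$q_egger$pval,
    egger_intercept = s$egger_intercept$intercept,
    egger_intercept_pval = s$egger_intercept$pval,
    presso_global_pval = if (!is.null(s$presso)) s$presso$global_pval
                         else NA_real_,
    presso_n_outliers = if (!is.null(s$presso))
      length(s$presso$outlier_snps) else NA_integer_,
    steiger_direction_ok = s$steiger$direction_ok,
    steiger_pval = s$steiger$pval,
    significant = !is.na(g(sel, "pval")) && g(sel, "pval") < alpha &&
      nrow(fit$data) >= 1L,
    consistent_sign = length(unique(signs[!is.na(signs)])) == 1L &&
      !anyNA(signs)
  )
}

empty_screen_rows <- function() {
  tibble::tibble(exposure = character(), k = integer(), R2 = double(),
                 F_overall = double(), beta_ivw = double(),
                 se_ivw = double(), p_ivw = double(), or_ivw = double(),
                 or_low_ivw = double(), or_high_ivw = double(),
                 ivw_model = character(), beta_ivw_fe = double(),
                 p_ivw_fe = double(), beta_ivw_re = double(),
                 p_ivw_re = double(), beta_egger = double(),
                 p_egger = double(), beta_wme = double(), p_wme = double(),
                 q_ivw_pval = double(), q_egger_pval = double(),
                 egger_intercept = double(),
                 egger_intercept_pval = double(),
                 presso_global_pval = double(),
                 presso_n_outliers = integer(),
                 steiger_direction_ok = logical(), steiger_pval = double(),
                 significant = logical(), consistent_sign = logical(),
                 p_ivw_bonferroni = double(), p_ivw_fdr = double())
}

#' @rdname mr_screen
#' @param x An `mr_screen` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_screen <- function(x, ...) x$results

#' @rdname mr_screen
#' @exportS3Method generics::glance
glance.mr_screen <- function(x, ...) {
  tibble::tibble(n_exposures = x$manifest$n_exposures %||% 0L,
                 n_analyzable = nrow(x$results),
                 n_skipped = nrow(x$skipped),
                 n_significant = sum(x$results$significant),
                 alpha = x$manifest$alpha %||% NA_real_,
                 ivw_model = x$manifest$ivw_model %||% NA_character_)
}

#' @export
print.mr_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mr_screen> %d exposures: %d analyzable, %d skipped, %d significant at alpha = %g (%s-effects IVW)\n",
              g$n_exposures, g$n_analyzable, g$n_skipped, g$n_significant,
              g$alpha, g$ivw_model))
  invisible(x)
}

#' Write all screen result files to a directory
#'
#' Emits `screen.tsv` (one row per analyzable exposure), `significant.tsv`
#' (the rows passing the significance rule), `estimates.tsv` (one row per
#' exposure x method), `sensitivity.tsv` (Q, Egger intercept, MR-PRESSO,
#' Steiger columns), `loo.tsv` (all leave-one-out series), `skipped.tsv`,
#' per-significant-exposure scatter data (`scatter_<exposure>.tsv`:
#' per-SNP effects and the fitted slopes of each method, ready for external
#' plotting) and `manifest.yaml`. All tables go through [write_mr_table()];
#' re-running an identical screen reproduces every TSV byte for byte.
#'
#' @param screen An `mr_screen` object.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(screen, out_dir) {
  stopifnot(inherits(screen, "mr_screen"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_mr_table(x, p)
    files <<- c(files, p)
  }
  emit(screen$results, "screen.tsv")
  emit(screen$results[screen$results$significant, , drop = FALSE],
       "significant.tsv")
  est <- dplyr::bind_rows(lapply(screen$fits, tidy))
  emit(est %||% tibble::tibble(), "estimates.tsv")
  sens_cols <- c("exposure", "k", "q_ivw_pval", "q_egger_pval",
                 "egger_intercept", "egger_intercept_pval",
                 "presso_global_pval", "presso_n_outliers",
                 "steiger_direction_ok", "steiger_pval")
  emit(screen$results[, intersect(sens_cols, names(screen$results)),
                      drop = FALSE], "sensitivity.tsv")
  loo <- dplyr::bind_rows(lapply(names(screen$fits), function(nm) {
    l <- screen$fits[[nm]]$sensitivity$loo
    if (is.null(l)) return(NULL)
    dplyr::bind_cols(tibble::tibble(exposure = nm), l)
  }))
  emit(loo %||% tibble::tibble(), "loo.tsv")
  emit(screen$skipped, "skipped.tsv")
  for (nm in screen$results$exposure[screen$results$significant]) {
    emit(scatter_data(screen$fits[[nm]]),
         sprintf("scatter_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", nm)))
  }
  manifest <- screen$manifest
  manifest$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$stage_counts <- NULL
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(files)
}

scatter_data <- function(fit) {
  est <- fit$estimates
  g <- function(m, col) {
    v <- est[[col]][est$method == m]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    exposure = fit$exposure,
    snp_id = fit$data$snp_id,
    b_x = fit$data$b_x, s_x = fit$data$s_x,
    b_y = fit$data$b_y, s_y = fit$data$s_y,
    slope_ivw_fe = g("ivw_fi", "beta"),
    slope_ivw_re = g("ivw_ra", "beta"),
    slope_egger = g("egger", "beta"),
    intercept_egger = g("egger", "egger_intercept"),
    slope_wme = g("wme", "beta")
  )
}

#' Run a screen from a YAML configuration file
#'
#' The configuration mirrors the [mr_screen()] arguments: `exposures`
#' (list of paths or a directory), `outcome` (path), optional `ld`,
#' `exclude`, `out_dir`, a `colmap` block (field = header pairs plus
#' `delimiter`), and any threshold (`pval_threshold`, `clump_r2`,
#' `clump_kb`, `f_min`, `alpha`, `ivw_model`, `palindrome_policy`,
#' `n_boot`, `presso_n_sim`, `seed`). Arguments passed directly override
#' the file.
#'
#' @param config Path to a YAML file.
#' @param ... Overrides for any [mr_screen()] argument.
#' @return The `mr_screen` object; results are also written to `out_dir`
#'   when the config names one.
#' @export
run_screen_config <- function(config, ...) {
  cfg <- yaml::read_yaml(config)
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  exposures <- cfg$exposures
  if (length(exposures) == 1L && dir.exists(exposures[[1L]])) {
    exposures <- list.files(exposures[[1L]], pattern = "\\.tsv$",
                            full.names = TRUE)
  }
  exposures <- unlist(exposures)
  cm_args <- cfg$colmap %||% list()
  colmap <- do.call(column_map, cm_args)
  args <- cfg[intersect(names(cfg),
                        c("pval_threshold", "clump_r2", "clump_kb", "f_min",
                          "alpha", "ivw_model", "palindrome_policy",
                          "n_boot", "presso_n_sim", "seed"))]
  scr <- do.call(mr_screen, c(list(exposures = exposures,
                                   outcome = cfg$outcome, colmap = colmap,
                                   ld = cfg$ld, exclude = cfg$exclude %||%
                                     character()), args))
  if (!is.null(cfg$out_dir)) render_report(scr, cfg$out_dir)
  scr
}
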