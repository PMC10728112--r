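#' Define a summary-level GWAS simulation scenario
#'
#' The simulator generates paired exposure/outcome GWAS summary statistics
#' under a known causal model, at the summary level: per-SNP true effects
#' plus Gaussian sampling noise on the betas, which is all a two-sample MR
#' pipeline ever observes. The exposure side mimics a metabolite GWAS in a
#' cohort of a few thousand; the outcome side a biobank case-control GWAS
#' on the log-odds scale, so that `exp(beta)` is an odds ratio.
#'
#' @param J Number of candidate SNPs.
#' @param n_x Exposure GWAS sample size. Default 7824, a metabolomics-scale
#'   European cohort.
#' @param n_y Outcome GWAS sample size. Default 213683 (538 cases +
#'   213145 controls, a biobank-scale case-control study; total n).
#' @param beta_causal True causal effect of the exposure on the outcome
#'   (log-odds per SD of exposure).
#' @param r2_exposure Total variance in the exposure explained by the `J`
#'   SNPs jointly, in (0, 1).
#' @param pi_pleio Fraction of SNPs with horizontal pleiotropy, in \[0, 1\].
#' @param mu_alpha Mean pleiotropic effect (0 = balanced, nonzero =
#'   directional pleiotropy).
#' @param sigma_alpha SD of pleiotropic effects, >= 0.
#' @param inside_violation If `TRUE`, pleiotropic effects gain a term equal
#'   to half the SNP's exposure effect, correlating instrument strength with
#'   direct effects (an InSIDE-assumption violation).
#' @param n_outliers Number of SNPs given an additional large outcome
#'   effect.
#' @param outlier_shift Magnitude added to the true outcome effect of each
#'   outlier SNP.
#' @param palindrome_frac Fraction of SNPs assigned A/T or G/C allele
#'   pairs. Default 1/6, the share of palindromic pairs among the six
#'   possible unordered biallelic SNV allele pairs.
#' @param ld_block_size SNPs per LD block (1 = all independent).
#' @param ld_r2_within Pairwise r-squared between SNPs inside a block.
#' @param seed Random seed; mandatory so every simulation is reproducible
#'   without touching global RNG state.
#'
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(J = 50L, n_x = 7824L, n_y = 213683L,
                         beta_causal = 0, r2_exposure = 0.05,
                         pi_pleio = 0, mu_alpha = 0, sigma_alpha = 0,
                         inside_violation = FALSE,
                         n_outliers = 0L, outlier_shift = 0,
                         palindrome_frac = 1 / 6,
                         ld_block_size = 1L, ld_r2_within = 0,
                         seed = 1L) {
  sc <- list(J = as.integer(J), n_x = as.integer(n_x), n_y = as.integer(n_y),
             beta_causal = beta_causal, r2_exposure = r2_exposure,
             pi_pleio = pi_pleio, mu_alpha = mu_alpha,
             sigma_alpha = sigma_alpha,
             inside_violation = isTRUE(inside_violation),
             n_outliers = as.integer(n_outliers),
             outlier_shift = outlier_shift,
             palindrome_frac = palindrome_frac,
             ld_block_size = as.integer(ld_block_size),
             ld_r2_within = ld_r2_within, seed = as.integer(seed))
  with(sc, {
    stopifnot(J >= 1L, n_x > 0L, n_y > 0L,
              r2_exposure > 0, r2_exposure < 1,
              pi_pleio >= 0, pi_pleio <= 1,
              sigma_alpha >= 0,
              n_outliers >= 0L, n_outliers <= J,
              palindrome_frac >= 0, palindrome_frac <= 1,
              ld_block_size >= 1L,
              ld_r2_within >= 0, ld_r2_within <= 1)
  })
  structure(sc, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat(sprintf("  J = %d SNPs, n_x = %d, n_y = %d, seed = %d\n",
              x$J, x$n_x, x$n_y, x$seed))
  cat(sprintf("  beta_causal = %g, r2_exposure = %g\n",
              x$beta_causal, x$r2_exposure))
  cat(sprintf("  pleiotropy: pi = %g, mu = %g, sigma = %g, InSIDE violated = %s\n",
              x$pi_pleio, x$mu_alpha, x$sigma_alpha, x$inside_violation))
  cat(sprintf("  outliers = %d (shift %g); palindrome_frac = %g; LD blocks of %d at r2 = %g\n",
              x$n_outliers, x$outlier_shift, x$palindrome_frac,
              x$ld_block_size, x$ld_r2_within))
  invisible(x)
}

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Deterministic given the scenario seed. The generative model:
#' \enumerate{
#'   \item MAF `p_j ~ Uniform(0.05, 0.5)`.
#'   \item Raw weights `u_j ~ |Normal(0,1)|`, scaled so that
#'     `sum(2 p_j (1-p_j) gamma_j^2) = r2_exposure`, giving the true
#'     per-allele exposure effects `gamma_j`.
#'   \item Pleiotropic effects `alpha_j = 0` except for a `pi_pleio`
#'     fraction of SNPs where `alpha_j ~ Normal(mu_alpha, sigma_alpha^2)`;
#'     under `inside_violation` each pleiotropic SNP additionally gains
#'     `gamma_j / 2`.
#'   \item True outcome effects `Gamma_j = beta_causal * gamma_j + alpha_j`,
#'     plus `outlier_shift` on the flagged outlier SNPs.
#'   \item Sampling noise: `s_xj = 1/sqrt(2 p_j (1-p_j) n_x)`,
#'     `s_yj = 1/sqrt(2 p_j (1-p_j) n_y)`;
#'     `b_xj ~ Normal(gamma_j, s_xj^2)`, `b_yj ~ Normal(Gamma_j, s_yj^2)`.
#'   \item Two-sided normal p-values from `b/s`.
#'   \item Alleles: a `palindrome_frac` share of SNPs get A/T or G/C pairs;
#'     positions are laid out 1 Mb apart across LD blocks and 1 kb apart
#'     within a block, all on one chromosome.
#' }
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `sim_gwas` with elements `exposure` and
#'   `outcome` (summary-statistics tibbles in the [read_summary_stats()]
#'   schema), `truth` (per-SNP tibble: `snp_id`, `gamma`, `alpha`,
#'   `gamma_outcome`, `outlier`, `palindromic`, `block`, `maf`), `ld`
#'   (pairwise LD tibble, see [ld_table()]) and `scenario`.
#' @export
simulate_gwas_pair <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  withr::with_seed(sc$seed, {
    J <- sc$J
    maf <- stats::runif(J, 0.05, 0.5)
    a2pq <- 2 * maf * (1 - maf)

    u <- abs(stats::rnorm(J))
    scale <- sqrt(sc$r2_exposure / sum(a2pq * u^2))
    gamma <- scale * u

    alpha <- numeric(J)
    n_pleio <- round(sc$pi_pleio * J)
    if (n_pleio > 0L) {
      idx <- sample.int(J, n_pleio)
      alpha[idx] <- stats::rnorm(n_pleio, sc$mu_alpha, sc$sigma_alpha)
      if (sc$inside_violation) alpha[idx] <- alpha[idx] + gamma[idx] / 2
    }

    outlier <- rep(FALSE, J)
    if (sc$n_outliers > 0L) outlier[sample.int(J, sc$n_outliers)] <- TRUE
    Gam <- sc$beta_causal * gamma + alpha + ifelse(outlier, sc$outlier_shift, 0)

    s_x <- 1 / sqrt(a2pq * sc$n_x)
    s_y <- 1 / sqrt(a2pq * sc$n_y)
    b_x <- stats::rnorm(J, gamma, s_x)
    b_y <- stats::rnorm(J, Gam, s_y)
    p_x <- pmax(2 * stats::pnorm(-abs(b_x / s_x)), .Machine$double.xmin)
    p_y <- pmax(2 * stats::pnorm(-abs(b_y / s_y)), .Machine$double.xmin)

    n_pal <- round(sc$palindrome_frac * J)
    palin <- rep(FALSE, J)
    if (n_pal > 0L) palin[sample.int(J, n_pal)] <- TRUE
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
    npal_pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                        c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
    pick_pal <- sample.int(4L, J, replace = TRUE)
    pick_npal <- sample.int(8L, J, replace = TRUE)
    ea <- ifelse(palin, pal_pairs[pick_pal, 1L], npal_pairs[pick_npal, 1L])
    oa <- ifelse(palin, pal_pairs[pick_pal, 2L], npal_pairs[pick_npal, 2L])

    block <- ((seq_len(J) - 1L) %/% sc$ld_block_size) + 1L
    within <- (seq_len(J) - 1L) %% sc$ld_block_size
    pos <- (block - 1L) * 1000000L + within * 1000L + 1L
    snp_id <- sprintf("rs%06d", seq_len(J))

    exposure <- tibble::tibble(
      snp_id = snp_id, chrom = "1", pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = b_x, se = s_x, pval = p_x, n = as.numeric(sc$n_x)
    )
    outcome <- tibble::tibble(
      snp_id = snp_id, chrom = "1", pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = b_y, se = s_y, pval = p_y, n = as.numeric(sc$n_y)
    )
    truth <- tibble::tibble(
      snp_id = snp_id, gamma = gamma, alpha = alpha, gamma_outcome = Gam,
      outlier = outlier, palindromic = palin, block = block, maf = maf
    )
    structure(list(exposure = exposure, outcome = outcome, truth = truth,
                   ld = ld_table_impl(snp_id, block, sc$ld_block_size,
                                      sc$ld_r2_within),
                   scenario = sc),
              class = "sim_gwas")
  })
}

#' @export
print.sim_gwas <- function(x, ...) {
  cat(sprintf("<sim_gwas> %d SNPs (seed %d): beta_causal = %g, %d pleiotropic, %d outliers\n",
              x$scenario$J, x$scenario$seed, x$scenario$beta_causal,
              sum(x$truth$alpha != 0), sum(x$truth$outlier)))
  invisible(x)
}

ld_table_impl <- function(snp_id, block, block_size, r2) {
  if (block_size <= 1L) {
    return(tibble::tibble(snp_a = character(), snp_b = character(),
                          r2 = double()))
  }
  pairs <- do.call(rbind, lapply(split(seq_along(snp_id), block), function(ix) {
    if (length(ix) < 2L) return(NULL)
    cmb <- utils::combn(ix, 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  }))
  tibble::tibble(snp_a = snp_id[pairs[, 1L]], snp_b = snp_id[pairs[, 2L]],
                 r2 = rep(r2, nrow(pairs)))
}

#' Pairwise LD table of a simulated GWAS
#'
#' Lists, for every pair of SNPs within the same LD block, the pairwise
#' r-squared. Self-pairs are omitted and each unordered pair appears once;
#' between-block pairs are implicitly r-squared = 0 and are not listed
#' (the clumping step treats absent pairs as independent).
#'
#' @param sim A `sim_gwas` object from [simulate_gwas_pair()].
#' @return A tibble with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_table <- function(sim) {
  stopifnot(inherits(sim, "sim_gwas"))
  sim$ld
}

#' Write a simulated GWAS pair to a directory
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `ld.tsv` and `truth.tsv` in the
#' tab-delimited dialect consumed by [read_summary_stats()] (with its
#' default [column_map()]).
#'
#' @param sim A `sim_gwas` object.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_sim_gwas <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_gwas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mr_table(sim$exposure, file.path(dir, "exposure.tsv"))
  write_mr_table(sim$outcome, file.path(dir, "outcome.tsv"))
  write_mr_table(sim$ld, file.path(dir, "ld.tsv"))
  write_mr_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
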