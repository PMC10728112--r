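# Shared fixtures and independent oracles.
#
# The oracles deliberately take a different computational route from the
# package (lm() fits, explicit loops, grid scans) so agreement is evidence,
# not tautology.

# random harmonized instrument table
random_harmonized <- function(k, seed, beta = 0.3, b_x_sd = 0.05,
                              s_y_range = c(0.01, 0.05),
                              s_x_range = c(0.005, 0.02),
                              noise = TRUE) {
  withr::with_seed(seed, {
    b_x <- rnorm(k, 0.1, b_x_sd)
    s_x <- runif(k, s_x_range[1], s_x_range[2])
    s_y <- runif(k, s_y_range[1], s_y_range[2])
    b_y <- beta * b_x + if (noise) rnorm(k, 0, s_y) else 0
    tibble::tibble(
      snp_id = sprintf("rs%04d", seq_len(k)),
      chrom = "1", pos = seq_len(k) * 1000L,
      effect_allele = "A", other_allele = "G",
      b_x = b_x, s_x = s_x, p_x = 2 * pnorm(-abs(b_x / s_x)),
      eaf_x = 0.3, n_x = 7824,
      b_y = b_y, s_y = s_y, p_y = 2 * pnorm(-abs(b_y / s_y)),
      eaf_y = 0.3, n_y = 213683,
      palindromic = FALSE, flipped = FALSE
    )
  })
}

# WLS-through-origin slope via lm(), the package uses the closed form
oracle_ivw_slope <- function(d) {
  unname(coef(lm(b_y ~ 0 + b_x, data = d, weights = 1 / d$s_y^2)))
}

# Egger via lm() on the b_x >= 0 orientation
oracle_egger <- function(d) {
  sgn <- ifelse(d$b_x < 0, -1, 1)
  fit <- lm(I(b_y * sgn) ~ I(b_x * sgn), weights = 1 / d$s_y^2, data = d)
  unname(coef(fit))  # c(intercept, slope)
}

# weighted median by dense grid scan for the interpolated crossing point;
# interpolation via findInterval, not stats::approx
oracle_wme_grid <- function(d, resolution = 1e-6) {
  ratio <- d$b_y / d$b_x
  w <- d$b_x^2 / d$s_y^2
  w <- w / sum(w)
  ord <- order(ratio)
  r <- ratio[ord]
  wo <- w[ord]
  q <- cumsum(wo) - wo / 2
  grid <- seq(min(r), max(r), by = resolution)
  j <- pmin(pmax(findInterval(grid, r), 1L), length(r) - 1L)
  qg <- q[j] + (q[j + 1] - q[j]) * (grid - r[j]) / (r[j + 1] - r[j])
  qg[grid <= r[1]] <- q[1]
  qg[grid >= r[length(r)]] <- q[length(q)]
  grid[which.min(abs(qg - 0.5))]
}

# one harmonized table straight from a simulated pair (all SNPs, no filters)
sim_harmonized <- function(scenario) {
  sim <- simulate_gwas_pair(scenario)
  harmonize(sim$exposure, sim$outcome, palindrome_policy = "keep")
}

# replicate seeds derived from one master seed
replicate_seeds <- function(master, n) {
  withr::with_seed(as.integer(master), sample.int(2^31 - 1, n))
}

write_stats_tsv <- function(d, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(d, path, progress = FALSE)
  path
}

# one outcome GWAS covering all exposures' (disjoint) instrument SNPs
make_screen_inputs <- function(n_exposures = 6, beta = 0, seed = 500,
                               J = 40, n_y = 50000) {
  seeds <- replicate_seeds(seed, n_exposures)
  exposures <- list()
  outcome_parts <- list()
  for (i in seq_len(n_exposures)) {
    sim <- simulate_gwas_pair(sim_scenario(J = J, beta_causal = beta,
                                           n_y = n_y, seed = seeds[i]))
    rename <- function(d) {
      d$snp_id <- sprintf("e%02d_%s", i, d$snp_id)
      d
    }
    exposures[[sprintf("met_%02d", i)]] <- rename(sim$exposure)
    outcome_parts[[i]] <- rename(sim$outcome)
  }
  list(exposures = exposures, outcome = dplyr::bind_rows(outcome_parts))
}
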