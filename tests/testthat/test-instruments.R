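make_exposure <- function(snp_id, chrom = "1", pos, pval,
                          ea = "A", oa = "G", beta = 0.1, se = 0.01) {
  n <- length(snp_id)
  tibble::tibble(snp_id = snp_id, chrom = rep_len(chrom, n),
                 pos = as.integer(pos),
                 effect_allele = rep_len(ea, n),
                 other_allele = rep_len(oa, n),
                 eaf = 0.3, beta = rep_len(beta, n), se = rep_len(se, n),
                 pval = pval, n = 7824)
}

test_that("the p-value filter is strict and order-preserving", {
  d <- make_exposure(c("rs1", "rs2", "rs3"), pos = c(100, 200, 300),
                     pval = c(1e-6, 1e-5, 1e-4))
  kept <- filter_pvalue(d, 1e-5)
  expect_equal(kept$snp_id, "rs1")          # 1e-5 itself excluded
  expect_equal(load_report(kept)$n_removed, 2L)

  expect_equal(nrow(filter_pvalue(d[0, ], 1e-5)), 0L)
  expect_equal(filter_pvalue(d, 1)$snp_id, d$snp_id)
})

test_that("confounder exclusion is a set difference by id", {
  d <- make_exposure(c("rs1", "rs2", "rs3"), pos = 1:3 * 100,
                     pval = rep(1e-6, 3))
  expect_equal(exclude_snps(d, character())$snp_id, d$snp_id)
  expect_equal(exclude_snps(d, "rs2")$snp_id, c("rs1", "rs3"))
  out <- exclude_snps(d, c("rs99", "rsX"))
  expect_equal(out$snp_id, d$snp_id)
  expect_equal(load_report(out)$n_removed, 0L)

  f <- tempfile()
  writeLines(c("rs1", "rs3"), f)
  expect_equal(exclude_snps(d, f)$snp_id, "rs2")
})

test_that("clumping keeps the best SNP of a linked pair whatever the order", {
  ld <- tibble::tibble(snp_a = "rsA", snp_b = "rsB", r2 = 0.8)
  for (ord in list(1:2, 2:1)) {
    d <- make_exposure(c("rsA", "rsB")[ord], pos = c(1000, 2000)[ord],
                       pval = c(1e-8, 1e-6)[ord])
    kept <- clump_instruments(d, ld)
    expect_equal(kept$snp_id, "rsA")
  }
})

test_that("clumping never spans chromosomes and follows the greedy chain rule", {
  # different chromosomes: both survive even at r2 = 1
  d2 <- make_exposure(c("rs1", "rs2"), chrom = c("1", "2"),
                      pos = c(1000, 1000), pval = c(1e-8, 1e-6))
  ld2 <- tibble::tibble(snp_a = "rs1", snp_b = "rs2", r2 = 1)
  expect_equal(nrow(clump_instruments(d2, ld2)), 2L)

  # chain A-B, B-C linked, A-C not: greedy keeps A then C
  d3 <- make_exposure(c("rsA", "rsB", "rsC"), pos = c(1000, 2000, 3000),
                      pval = c(1e-9, 1e-8, 1e-7))
  ld3 <- tibble::tibble(snp_a = c("rsA", "rsB"), snp_b = c("rsB", "rsC"),
                        r2 = c(0.5, 0.5))
  expect_equal(clump_instruments(d3, ld3)$snp_id, c("rsA", "rsC"))

  # beyond the window, LD is ignored
  d4 <- make_exposure(c("rs1", "rs2"), pos = c(1, 10000 * 1000 + 2000),
                      pval = c(1e-8, 1e-6))
  ld4 <- tibble::tibble(snp_a = "rs1", snp_b = "rs2", r2 = 0.9)
  expect_equal(nrow(clump_instruments(d4, ld4)), 2L)

  expect_error(clump_instruments(dplyr::mutate(d3, pos = NA_integer_), ld3),
               "pos")
})

test_that("clump output contains no linked pair within the window", {
  seeds <- replicate_seeds(15, 10)
  for (s in seeds) {
    sim <- simulate_gwas_pair(sim_scenario(J = 30, ld_block_size = 3,
                                           ld_r2_within = 0.5, seed = s))
    kept <- clump_instruments(sim$exposure, sim$ld, r2_max = 0.001,
                              window_kb = 10000)
    ids <- kept$snp_id
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        within <- abs(kept$pos[i] - kept$pos[j]) <= 10000 * 1000
        r2 <- sim$ld$r2[(sim$ld$snp_a == ids[i] & sim$ld$snp_b == ids[j]) |
                          (sim$ld$snp_a == ids[j] & sim$ld$snp_b == ids[i])]
        r2 <- if (length(r2) == 0) 0 else r2
        expect_false(within && r2 >= 0.001)
      }
    }
    # exactly one index SNP per block at r2 = 0.5 within one window
    expect_equal(nrow(kept), 10L)
  }
})

test_that("harmonization aligns, flips, complements and drops as specified", {
  ex <- make_exposure(c("rs1", "rs2", "rs3", "rs4"), pos = 1:4 * 1000,
                      pval = rep(1e-8, 4))
  # rs1: same orientation; rs2: swapped; rs3: complement-swapped;
  # rs4: irreconcilable
  out <- tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = 1:4 * 1000L,
    effect_allele = c("A", "G", "C", "A"),
    other_allele = c("G", "A", "T", "C"),
    eaf = c(0.3, 0.7, 0.7, 0.3),
    beta = c(0.2, 0.2, 0.2, 0.2), se = 0.05, pval = 1e-4, n = 213683
  )
  h <- harmonize(ex, out)
  expect_equal(h$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(h$b_y, c(0.2, -0.2, -0.2))
  expect_equal(h$flipped, c(FALSE, TRUE, TRUE))
  expect_equal(h$eaf_y, c(0.3, 0.3, 0.3))
  expect_equal(load_report(h)$allele_mismatch, 1L)

  # palindromic pairs: dropped by default, kept and flagged on request
  exp_pal <- make_exposure("rs9", pos = 900, pval = 1e-8, ea = "A", oa = "T")
  out_pal <- dplyr::mutate(exp_pal, beta = 0.3, se = 0.05, n = 213683)
  h_drop <- harmonize(exp_pal, out_pal)
  expect_equal(nrow(h_drop), 0L)
  expect_equal(load_report(h_drop)$palindromic_dropped, 1L)
  h_keep <- harmonize(exp_pal, out_pal, palindrome_policy = "keep")
  expect_true(h_keep$palindromic)

  expect_error(harmonize(dplyr::bind_rows(ex, ex[1, ]), out), "rs1")
})

test_that("Wald ratios are invariant under orientation flips of any SNP", {
  sim <- simulate_gwas_pair(sim_scenario(J = 12, beta_causal = 0.2,
                                         palindrome_frac = 0, seed = 31))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # flip both alleles (and betas, eafs) of every other outcome record
  flip <- seq(2, 12, by = 2)
  out2 <- sim$outcome
  out2$effect_allele[flip] <- sim$outcome$other_allele[flip]
  out2$other_allele[flip] <- sim$outcome$effect_allele[flip]
  out2$beta[flip] <- -out2$beta[flip]
  out2$eaf[flip] <- 1 - out2$eaf[flip]
  h2 <- harmonize(sim$exposure, out2)
  expect_equal(h2$b_y / h2$b_x, h1$b_y / h1$b_x, tolerance = 1e-12)
  for (m in list(mr_ivw, mr_egger)) {
    expect_equal(m(h2)$beta, m(h1)$beta, tolerance = 1e-12)
  }
})

test_that("clumping and harmonization commute", {
  sim <- simulate_gwas_pair(sim_scenario(J = 10, ld_block_size = 2,
                                         ld_r2_within = 0.7,
                                         palindrome_frac = 0.2, seed = 13))
  a <- harmonize(clump_instruments(sim$exposure, sim$ld), sim$outcome)
  pre <- harmonize(sim$exposure, sim$outcome)
  b <- clump_instruments(pre, sim$ld)
  expect_equal(b$snp_id, a$snp_id)
  expect_equal(b$b_y, a$b_y)
})

test_that("the F statistic matches direct formula substitution", {
  expect_equal(f_statistic(0.02, 7824, 10), 15.9448979591837,
               tolerance = 1e-10)
  expect_equal(f_statistic(0, 1000, 5), 0)
  expect_error(f_statistic(0.1, 11, 10), "n > k")

  # single SNP: per-SNP r2 = t2/(t2 + n - 2) and the overall F collapses to t2
  d <- random_harmonized(1, seed = 4)
  d$b_x <- 0.1; d$s_x <- 0.01; d$n_x <- 1000   # t2 = 100
  f <- compute_f(d, n = 1000)
  expect_equal(f$R2, 100 / 1098, tolerance = 1e-12)
  expect_equal(f$F_overall, 100, tolerance = 1e-10)
  expect_equal(unname(f$F_snp), 100)

  # random instances: R2 and F match independent substitution
  for (s in 1:5) {
    d <- random_harmonized(8, seed = s)
    f <- compute_f(d)
    n <- median(d$n_x)
    t2 <- (d$b_x / d$s_x)^2
    expect_equal(f$R2, sum(t2 / (t2 + n - 2)), tolerance = 1e-12)
    expect_equal(f$F_overall, f$R2 * (n - 8 - 1) / ((1 - f$R2) * 8),
                 tolerance = 1e-12)
  }
})

test_that("weak instruments are excluded and hopeless sets flagged", {
  d <- random_harmonized(2, seed = 7)
  d$b_x <- c(0.02, 0.1); d$s_x <- c(0.0089, 0.0141)  # F ~ {5, 50}
  iset <- filter_weak(d, n = 7824)
  expect_equal(iset$k, 1L)
  expect_equal(iset$data$snp_id, d$snp_id[2])
  expect_true(iset$analyzable)

  strong <- random_harmonized(5, seed = 8)
  strong$b_x <- rep(0.2, 5); strong$s_x <- rep(0.01, 5)
  expect_equal(filter_weak(strong, n = 7824)$k, 5L)

  weak <- random_harmonized(3, seed = 9)
  weak$b_x <- rep(0.01, 3); weak$s_x <- rep(0.01, 3)
  iset_w <- filter_weak(weak, n = 7824)
  expect_equal(iset_w$k, 0L)
  expect_false(iset_w$analyzable)
})
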