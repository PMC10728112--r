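test_that("the Wald ratio matches hand arithmetic and its symmetries", {
  d <- random_harmonized(1, seed = 1)
  d$b_x <- 0.1; d$b_y <- 0.2; d$s_y <- 0.05
  est <- mr_wald(d)
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.5)

  d0 <- d; d0$b_y <- 0
  est0 <- mr_wald(d0)
  expect_equal(est0$beta, 0)
  expect_equal(est0$pval, 1)

  dflip <- d; dflip$b_x <- -d$b_x; dflip$b_y <- -d$b_y
  expect_equal(mr_wald(dflip)$beta, est$beta)
  expect_equal(mr_wald(dflip)$se, est$se)

  dz <- d; dz$b_x <- 0
  expect_error(mr_wald(dz), "zero")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  for (s in 1:20) {
    k <- sample(3:50, 1)
    d <- random_harmonized(k, seed = 1000 + s)
    expect_equal(mr_ivw(d, "fixed")$beta, oracle_ivw_slope(d),
                 tolerance = 1e-10)
  }
})

test_that("IVW closed forms: homogeneity, single SNP, equal weights", {
  # identical Wald ratios: estimate exact, Q = 0, random = fixed
  d <- random_harmonized(2, seed = 2, noise = FALSE)
  d$b_y <- 0.3 * d$b_x
  fe <- mr_ivw(d, "fixed")
  re <- mr_ivw(d, "random")
  expect_equal(fe$beta, 0.3, tolerance = 1e-12)
  expect_equal(re$se, fe$se)
  expect_equal(cochran_q(d, "ivw")$Q, 0, tolerance = 1e-20)

  # k = 1 falls back to the Wald ratio with a note
  d1 <- random_harmonized(1, seed = 3)
  est1 <- mr_ivw(d1)
  expect_equal(est1$method, "wald")
  expect_match(est1$note, "Wald")
  expect_equal(est1$beta, d1$b_y / d1$b_x)

  # equal s_y and equal b_x: IVW reduces to the plain mean of ratios
  d2 <- random_harmonized(6, seed = 4)
  d2$b_x <- rep(0.1, 6); d2$s_y <- rep(0.02, 6)
  expect_equal(mr_ivw(d2, "fixed")$beta, mean(d2$b_y / d2$b_x),
               tolerance = 1e-12)
})

test_that("random-effects IVW inflates but never deflates the SE", {
  d <- random_harmonized(10, seed = 5)
  d$b_y <- d$b_y + c(rep(0, 9), 0.5)   # one discordant SNP
  expect_gt(mr_ivw(d, "random")$se, mr_ivw(d, "fixed")$se)
  dq <- random_harmonized(10, seed = 6, noise = FALSE)
  dq$b_y <- 0.2 * dq$b_x + withr::with_seed(6, rnorm(10, 0, 1e-6))  # Q << k-1
  expect_equal(mr_ivw(dq, "random")$se, mr_ivw(dq, "fixed")$se)
})

test_that("Egger matches the lm oracle and recovers exact-line data", {
  d <- random_harmonized(5, seed = 7, noise = FALSE)
  d$b_y <- 0.05 + 0.4 * d$b_x
  est <- mr_egger(d)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.05, tolerance = 1e-10)

  for (s in 1:10) {
    d <- random_harmonized(10, seed = 2000 + s, b_x_sd = 0.04)
    o <- oracle_egger(d)
    est <- mr_egger(d)
    expect_equal(est$egger_intercept, o[1], tolerance = 1e-10)
    expect_equal(est$beta, o[2], tolerance = 1e-10)
  }

  expect_match(mr_egger(random_harmonized(2, seed = 8))$note,
               "not_computable")
})

test_that("Egger with a zero intercept reproduces the IVW slope", {
  # constrained fit (no intercept, weights 1/s_y^2) is algebraically IVW;
  # verified through an independent lm route
  d <- random_harmonized(8, seed = 9)
  constrained <- unname(coef(lm(b_y ~ 0 + b_x, data = d,
                                weights = 1 / d$s_y^2)))
  expect_equal(mr_ivw(d, "fixed")$beta, constrained, tolerance = 1e-10)
})

test_that("the weighted median interpolates the midpoint weights", {
  # equal weights, ratios {1, 2, 9}: plain median
  d <- random_harmonized(3, seed = 10)
  d$b_x <- rep(0.1, 3); d$s_y <- rep(0.02, 3)
  d$b_y <- c(1, 2, 9) * 0.1
  expect_equal(mr_weighted_median(d, n_boot = 50, seed = 1)$beta, 2)

  # random instances against the grid-scan oracle
  for (s in 1:5) {
    d <- random_harmonized(7, seed = 3000 + s)
    est <- mr_weighted_median(d, n_boot = 50, seed = 1)
    expect_lt(abs(est$beta - oracle_wme_grid(d)), 1.5e-6)
  }

  expect_match(mr_weighted_median(random_harmonized(2, seed = 11))$note,
               "not_computable")
})

test_that("the weighted median bootstrap is seed-reproducible", {
  d <- random_harmonized(6, seed = 12)
  a <- mr_weighted_median(d, n_boot = 200, seed = 42)
  b <- mr_weighted_median(d, n_boot = 200, seed = 42)
  expect_identical(a, b)
  expect_gt(a$se, 0)
})

test_that("confidence intervals and odds ratios follow the normal convention", {
  d <- random_harmonized(1, seed = 13)
  d$b_x <- 1; d$b_y <- 0; d$s_y <- 1
  est <- mr_wald(d)     # beta = 0, se = 1
  expect_equal(est$or, 1.0)
  expect_equal(est$or_low, 0.140863494028428, tolerance = 1e-12)
  expect_equal(est$or_high, 7.099071387496523, tolerance = 1e-12)

  # applying to_or twice equals applying once
  expect_identical(to_or(est), est)

  # se -> 0 collapses the interval onto exp(beta)
  est2 <- est; est2$beta <- log(2); est2$se <- 1e-14
  est2 <- to_or(est2)
  expect_equal(est2$or, 2, tolerance = 1e-12)
  expect_equal(est2$or_low, 2, tolerance = 1e-10)
  expect_equal(est2$or_high, 2, tolerance = 1e-10)
})

test_that("estimators are invariant to SNP order and orientation flips", {
  d <- random_harmonized(9, seed = 14)
  perm <- withr::with_seed(1, sample(9))
  dp <- d[perm, ]
  flip <- c(1, 4, 7)
  df <- d; df$b_x[flip] <- -df$b_x[flip]; df$b_y[flip] <- -df$b_y[flip]
  for (f in list(function(x) mr_ivw(x, "fixed"),
                 function(x) mr_ivw(x, "random"),
                 mr_egger,
                 function(x) mr_weighted_median(x, n_boot = 50, seed = 5))) {
    base <- f(d)
    expect_equal(f(dp)$beta, base$beta, tolerance = 1e-12)
    expect_equal(f(df)$beta, base$beta, tolerance = 1e-12)
  }
})

test_that("fit_mr bundles estimates and sensitivity with tidy/glance access", {
  iset <- filter_weak(random_harmonized(8, seed = 15), n = 7824,
                      exposure = "met_1")
  fit <- fit_mr(iset, n_boot = 100, presso_n_sim = 200, seed = 1)
  td <- tidy(fit)
  expect_equal(td$exposure, rep("met_1", 4))
  expect_setequal(td$method, c("ivw_fi", "ivw_ra", "egger", "wme"))
  expect_true(all(td$or == exp(td$beta)))
  gl <- glance(fit)
  expect_equal(gl$k, iset$k)
  expect_true(gl$presso_global_pval > 0)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
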