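#' Keep SNPs passing the genome-wide suggestive significance threshold
#'
#' Instrument relevance filter: keeps exactly the rows with exposure
#' p-value strictly below the threshold (default 1e-5, the conventional
#' suggestive threshold used when metabolite GWAS yield few genome-wide
#' significant hits), preserving input order.
#'
#' @param dat Summary-statistics tibble (see [read_summary_stats()]).
#' @param threshold P-value threshold in (0, 1); strict inequality.
#' @return The surviving rows, with a `"filter_log"` attribute recording
#'   input/kept/removed counts.
#' @export
filter_pvalue <- function(dat, threshold = 1e-5) {
  stopifnot(is.data.frame(dat), threshold > 0, threshold <= 1)
  keep <- !is.na(dat$pval) & dat$pval < threshold
  out <- dat[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(stage = "filter_pvalue",
                                  n_in = nrow(dat), n_kept = nrow(out),
                                  n_removed = nrow(dat) - nrow(out))
  out
}

#' Remove SNPs on a user-supplied confounder exclusion list
#'
#' Set-difference by SNP identifier. In screening practice the list holds
#' variants known to act on the outcome through confounding traits (for
#' example from a phenome-wide lookup), which would violate the
#' independence assumption if kept as instruments.
#'
#' @param dat Summary-statistics tibble.
#' @param exclude Character vector of SNP ids to remove; may be empty, or a
#'   path to a text file with one id per line.
#' @return Surviving rows with a `"filter_log"` attribute.
#' @export
exclude_snps <- function(dat, exclude = character()) {
  stopifnot(is.data.frame(dat))
  if (length(exclude) == 1L && file.exists(exclude)) {
    exclude <- readLines(exclude, warn = FALSE)
    exclude <- exclude[nzchar(trimws(exclude))]
  }
  keep <- !(dat$snp_id %in% exclude)
  out <- dat[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(stage = "exclude_snps",
                                  n_in = nrow(dat), n_kept = nrow(out),
                                  n_removed = nrow(dat) - nrow(out))
  out
}

#' Greedy LD clumping to independent index SNPs
#'
#' Reduces a SNP list to mutually independent index variants: SNPs are
#' ranked by p-value (ties broken by smaller position, then lexicographic
#' SNP id, so the result is fully deterministic); the best remaining SNP is
#' taken as an index and every other SNP on the same chromosome within
#' `window_kb` kilobases AND with pairwise r-squared >= `r2_max` against
#' the index is removed; the survivors are the index SNPs. Pairs absent
#' from the LD table are treated as r-squared = 0 (independent).
#'
#' @param dat Tibble with at least `snp_id`, `chrom`, `pos` and a p-value
#'   column (`pval`, or `p_x` on harmonized data).
#' @param ld Pairwise LD tibble with columns `snp_a`, `snp_b`, `r2`
#'   (unordered pairs; either orientation accepted), or `NULL` for no
#'   listed LD.
#' @param r2_max Clumping r-squared threshold (default 0.001).
#' @param window_kb Clumping distance in kb (default 10000).
#' @return The index SNPs, in the original row order of `dat`, with a
#'   `"filter_log"` attribute.
#' @export
clump_instruments <- function(dat, ld = NULL, r2_max = 0.001,
                              window_kb = 10000) {
  stopifnot(is.data.frame(dat))
  pcol <- if ("pval" %in% names(dat)) "pval" else "p_x"
  if (!all(c("chrom", "pos", pcol) %in% names(dat)) ||
      anyNA(dat$pos) || anyNA(dat$chrom)) {
    stop("clump_instruments: records must carry chrom, pos and a p-value",
         call. = FALSE)
  }
  n <- nrow(dat)
  if (n == 0L) {
    attr(dat, "filter_log") <- list(stage = "clump", n_in = 0L, n_kept = 0L,
                                    n_removed = 0L)
    return(dat)
  }

  r2_lookup <- new.env(parent = emptyenv(), hash = TRUE)
  if (!is.null(ld) && nrow(ld) > 0L) {
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$snp_a[i], ld$snp_b[i], sep = "\r"), ld$r2[i], r2_lookup)
      assign(paste(ld$snp_b[i], ld$snp_a[i], sep = "\r"), ld$r2[i], r2_lookup)
    }
  }
  pair_r2 <- function(a, b) {
    v <- mget(paste(a, b, sep = "\r"), envir = r2_lookup,
              ifnotfound = list(0))
    unlist(v, use.names = FALSE)
  }

  ord <- order(dat[[pcol]], dat$pos, dat$snp_id)
  active <- rep(TRUE, n)
  index <- logical(n)
  for (i in ord) {
    if (!active[i]) next
    index[i] <- TRUE
    cand <- which(active & !index & dat$chrom == dat$chrom[i] &
                    abs(dat$pos - dat$pos[i]) <= window_kb * 1000)
    if (length(cand) > 0L) {
      hit <- pair_r2(dat$snp_id[i], dat$snp_id[cand]) >= r2_max
      active[cand[hit]] <- FALSE
    }
    active[i] <- FALSE
  }
  out <- dat[index, , drop = FALSE]
  attr(out, "filter_log") <- list(stage = "clump", n_in = n,
                                  n_kept = nrow(out),
                                  n_removed = n - nrow(out))
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' Inner-joins the two summary-statistics tables on SNP id and puts every
#' pair on the exposure's effect-allele orientation: outcome records whose
#' alleles are swapped relative to the exposure have their beta negated and
#' effect-allele frequency reflected (`flipped = TRUE`); outcome records
#' reported on the opposite strand are complemented first; irreconcilable
#' allele sets are dropped and logged. A/T and G/C (palindromic) variants
#' cannot be strand-resolved from alleles alone and are removed under the
#' default policy, the conservative choice against strand ambiguity.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param palindrome_policy `"drop"` (default) removes palindromic pairs;
#'   `"keep"` retains them (flagged) assuming both studies report the same
#'   strand.
#' @return A harmonized tibble, one row per retained SNP, with columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `b_x`,
#'   `s_x`, `p_x`, `eaf_x`, `n_x`, `b_y`, `s_y`, `p_y`, `eaf_y`, `n_y`,
#'   `palindromic`, `flipped`; plus a `"filter_log"` attribute with counts
#'   (matched, allele_mismatch, palindromic_dropped, kept).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  for (nm in c("exposure", "outcome")) {
    d <- get(nm)
    if (anyDuplicated(d$snp_id)) {
      stop("duplicate snp_id in ", nm, ": ",
           d$snp_id[duplicated(d$snp_id)][1L], call. = FALSE)
    }
  }
  m <- match(exposure$snp_id, outcome$snp_id)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  oc <- outcome[m[keep], , drop = FALSE]
  n_matched <- nrow(ex)

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- oc$effect_allele; oa_y <- oc$other_allele
  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  cea_y <- unname(COMPLEMENT[ea_y])
  coa_y <- unname(COMPLEMENT[oa_y])
  csame <- !same & !swap & cea_y == ea_x & coa_y == oa_x
  cswap <- !same & !swap & !csame & cea_y == oa_x & coa_y == ea_x
  mismatch <- !(same | swap | csame | cswap)
  flipped <- swap | cswap
  palindromic <- is_palindromic(ea_x, oa_x)

  out <- tibble::tibble(
    snp_id = ex$snp_id,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_x, other_allele = oa_x,
    b_x = ex$beta, s_x = ex$se, p_x = ex$pval,
    eaf_x = ex$eaf, n_x = ex$n,
    b_y = ifelse(flipped, -oc$beta, oc$beta),
    s_y = oc$se, p_y = oc$pval,
    eaf_y = ifelse(flipped, 1 - oc$eaf, oc$eaf),
    n_y = oc$n,
    palindromic = palindromic, flipped = flipped
  )

  drop <- mismatch
  n_mismatch <- sum(mismatch)
  n_pal_dropped <- 0L
  if (palindrome_policy == "drop") {
    n_pal_dropped <- sum(palindromic & !drop)
    drop <- drop | palindromic
  }
  out <- out[!drop, , drop = FALSE]
  attr(out, "filter_log") <- list(
    stage = "harmonize",
    n_exposure = nrow(exposure), n_outcome = nrow(outcome),
    n_matched = n_matched, allele_mismatch = n_mismatch,
    palindromic_dropped = n_pal_dropped, n_kept = nrow(out)
  )
  out
}

#' Overall F statistic from total variance explained
#'
#' `F = R2 (n - k - 1) / ((1 - R2) k)` for `k` instruments jointly
#' explaining a fraction `R2` of the exposure variance in a GWAS of `n`
#' individuals. F > 10 is the conventional bound below which weak-instrument
#' bias is a concern.
#'
#' @param R2 Variance explained, in \[0, 1).
#' @param n Exposure sample size.
#' @param k Number of instruments.
#' @return The F statistic.
#' @export
f_statistic <- function(R2, n, k) {
  stopifnot(R2 >= 0, R2 < 1, k >= 1)
  if (n <= k + 1) stop("f_statistic: need n > k + 1", call. = FALSE)
  R2 * (n - k - 1) / ((1 - R2) * k)
}

#' Instrument strength: variance explained and F statistics
#'
#' Per-SNP variance explained is recovered from the association
#' t-statistic, `r2_j = t_j^2 / (t_j^2 + n - 2)` with `t_j = b_x / s_x`,
#' which uses only fields guaranteed present (effect-allele frequency may
#' be missing in real files). `R2` is the sum over instruments, the overall
#' F comes from [f_statistic()], and the per-SNP F is `t_j^2`.
#'
#' @param dat Harmonized tibble (see [harmonize()]).
#' @param n Exposure GWAS sample size; defaults to the median of `n_x`.
#' @return A list with `R2`, `F_overall`, `F_snp` (per-SNP vector, named by
#'   snp_id), `k` and `n`.
#' @export
compute_f <- function(dat, n = NULL) {
  stopifnot(is.data.frame(dat), nrow(dat) >= 1L)
  if (is.null(n)) n <- stats::median(dat$n_x)
  k <- nrow(dat)
  if (is.na(n) || n <= k + 1) {
    stop("compute_f: need exposure sample size n > k + 1", call. = FALSE)
  }
  t2 <- (dat$b_x / dat$s_x)^2
  r2_snp <- t2 / (t2 + n - 2)
  R2 <- sum(r2_snp)
  list(R2 = R2, F_overall = f_statistic(min(R2, 1 - 1e-12), n, k),
       F_snp = stats::setNames(t2, dat$snp_id), k = k, n = n)
}

#' Drop weak instruments and assemble the final instrument set
#'
#' Removes SNPs whose per-SNP F statistic is not above `f_min` (default
#' 10), recomputes the variance explained and the overall F on the
#' survivors, and retains the set only when the overall F also exceeds
#' `f_min`; otherwise the exposure is flagged not analyzable (an empty set,
#' not an error). Downstream estimation always runs on the post-filter set.
#'
#' @param dat Harmonized tibble.
#' @param n Exposure sample size; defaults to the median of `n_x`.
#' @param f_min Weak-instrument threshold (strict: keep F > `f_min`).
#' @param exposure Label carried through to reports.
#' @return An object of class `instrument_set`: a list with `exposure`,
#'   `data` (the surviving harmonized tibble), `k`, `R2`, `F_overall`,
#'   `F_snp`, `n`, `analyzable` and `log`.
#' @export
filter_weak <- function(dat, n = NULL, f_min = 10, exposure = "exposure") {
  stopifnot(is.data.frame(dat))
  n_in <- nrow(dat)
  if (n_in == 0L) {
    return(new_instrument_set(exposure, dat, R2 = 0, F_overall = 0,
                              F_snp = numeric(0), n = n %||% NA_real_,
                              log = list(stage = "filter_weak", n_in = 0L,
                                         n_kept = 0L, n_removed = 0L)))
  }
  if (is.null(n)) n <- stats::median(dat$n_x)
  t2 <- (dat$b_x / dat$s_x)^2
  keep <- t2 > f_min
  out <- dat[keep, , drop = FALSE]
  log <- list(stage = "filter_weak", n_in = n_in, n_kept = nrow(out),
              n_removed = n_in - nrow(out))
  if (nrow(out) == 0L) {
    return(new_instrument_set(exposure, out, R2 = 0, F_overall = 0,
                              F_snp = numeric(0), n = n, log = log))
  }
  f <- compute_f(out, n = n)
  if (f$F_overall <= f_min) {
    log$overall_f_failed <- f$F_overall
    return(new_instrument_set(exposure, out[0, , drop = FALSE], R2 = f$R2,
                              F_overall = f$F_overall, F_snp = f$F_snp,
                              n = n, log = log, analyzable = FALSE))
  }
  new_instrument_set(exposure, out, R2 = f$R2, F_overall = f$F_overall,
                     F_snp = f$F_snp, n = n, log = log)
}

new_instrument_set <- function(exposure, data, R2, F_overall, F_snp, n, log,
                               analyzable = nrow(data) > 0L) {
  structure(list(exposure = exposure, data = data, k = nrow(data),
                 R2 = R2, F_overall = F_overall, F_snp = F_snp, n = n,
                 analyzable = analyzable, log = log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: k = %d, R2 = %.4g, F_overall = %.4g%s\n",
              x$exposure, x$k, x$R2, x$F_overall,
              if (x$analyzable) "" else " (not analyzable)"))
  invisible(x)
}

# Accept either an instrument_set or a bare harmonized tibble everywhere
# downstream.
harmonized_data <- function(x) {
  if (inherits(x, "instrument_set")) x$data else x
}
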