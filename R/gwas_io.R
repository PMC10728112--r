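#' Describe the column layout of a GWAS summary-statistics file
#'
#' GWAS summary statistics are distributed as delimited text with no fixed
#' header convention. A column map names, for each of the ten per-SNP fields
#' the pipeline consumes, the header under which a given file stores it,
#' together with the delimiter and the strings to treat as missing.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n
#'   Header names in the source file for the corresponding field.
#' @param delimiter Single field-separator character. Default tab.
#' @param na Character vector of missing-value sentinels.
#'
#' @return An object of class `column_map`.
#' @export
#' @examples
#' cm <- column_map(snp_id = "rsid", pval = "p_value")
column_map <- function(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                       effect_allele = "effect_allele",
                       other_allele = "other_allele",
                       eaf = "eaf", beta = "beta", se = "se",
                       pval = "pval", n = "n",
                       delimiter = "\t", na = c("NA", "", "NaN")) {
  fields <- list(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n
  )
  bad <- !vapply(fields, function(x) is.character(x) && length(x) == 1L && nzchar(x), logical(1))
  if (any(bad)) {
    stop("column_map: every field must map to a single non-empty header; bad: ",
         paste(names(fields)[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(unlist(fields))) {
    stop("column_map: all ten fields must map to distinct headers", call. = FALSE)
  }
  if (!is.character(delimiter) || nchar(delimiter) != 1L) {
    stop("column_map: delimiter must be a single character", call. = FALSE)
  }
  structure(list(fields = fields, delimiter = delimiter, na = na),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map> delimiter =", deparse(x$delimiter), "\n")
  for (f in names(x$fields)) cat(sprintf("  %-14s <- %s\n", f, x$fields[[f]]))
  invisible(x)
}

summary_stats_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                        "other_allele", "eaf", "beta", "se", "pval", "n")

#' Read GWAS summary statistics from delimited text
#'
#' Reads one row per SNP and applies exclusion-based quality control: rows
#' violating the per-record invariants (non-positive standard error,
#' alleles outside A/C/G/T or identical, multi-character indel alleles,
#' p-value outside (0, 1], non-positive position or sample size, missing
#' required values) are dropped, never coerced, and each drop is counted by
#' reason. Allele letters are uppercased on read. An out-of-range
#' effect-allele frequency is set to missing but the row is kept.
#'
#' @param path Path to a delimited text file with a header row.
#' @param colmap A [column_map()] describing the file layout.
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, in file order, with a
#'   `"load_report"` attribute (rows read / kept / dropped per reason),
#'   retrievable via [load_report()].
#' @export
read_summary_stats <- function(path, colmap = column_map()) {
  stopifnot(inherits(colmap, "column_map"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  raw <- readr::read_delim(
    path, delim = colmap$delimiter, na = colmap$na,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    warning("empty summary-statistics file: ", path, call. = FALSE)
    out <- empty_summary_stats()
    attr(out, "load_report") <- new_load_report(0L, 0L, integer(0))
    return(out)
  }

  missing_cols <- setdiff(unlist(colmap$fields), names(raw))
  if (length(missing_cols) > 0L) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  dat <- tibble::tibble(
    snp_id        = raw[[colmap$fields$snp_id]],
    chrom         = raw[[colmap$fields$chrom]],
    pos           = suppressWarnings(as.integer(raw[[colmap$fields$pos]])),
    effect_allele = toupper(raw[[colmap$fields$effect_allele]]),
    other_allele  = toupper(raw[[colmap$fields$other_allele]]),
    eaf           = suppressWarnings(as.numeric(raw[[colmap$fields$eaf]])),
    beta          = suppressWarnings(as.numeric(raw[[colmap$fields$beta]])),
    se            = suppressWarnings(as.numeric(raw[[colmap$fields$se]])),
    pval          = suppressWarnings(as.numeric(raw[[colmap$fields$pval]])),
    n             = suppressWarnings(as.numeric(raw[[colmap$fields$n]]))
  )

  nuc <- c("A", "C", "G", "T")
  reasons <- list(
    missing_value = is.na(dat$snp_id) | is.na(dat$beta) | is.na(dat$se) |
      is.na(dat$pval) | is.na(dat$effect_allele) | is.na(dat$other_allele),
    invalid_allele = !(dat$effect_allele %in% nuc) |
      !(dat$other_allele %in% nuc),
    allele_identical = !is.na(dat$effect_allele) & !is.na(dat$other_allele) &
      dat$effect_allele == dat$other_allele,
    nonpositive_se = !is.na(dat$se) & dat$se <= 0,
    pval_out_of_range = !is.na(dat$pval) & (dat$pval <= 0 | dat$pval > 1),
    bad_position = !is.na(dat$pos) & dat$pos < 1,
    bad_n = !is.na(dat$n) & dat$n <= 0
  )
  # first failing reason wins so each dropped row is counted exactly once
  drop_reason <- rep(NA_character_, nrow(dat))
  for (r in names(reasons)) {
    hit <- reasons[[r]] & is.na(drop_reason)
    hit[is.na(hit)] <- FALSE
    drop_reason[hit] <- r
  }
  keep <- is.na(drop_reason)

  out <- dat[keep, , drop = FALSE]
  out$eaf[!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)] <- NA_real_
  dropped <- table(factor(drop_reason[!keep], levels = names(reasons)))
  dropped <- stats::setNames(as.integer(dropped), names(reasons))
  attr(out, "load_report") <- new_load_report(nrow(dat), nrow(out),
                                              dropped[dropped > 0L])
  out
}

new_load_report <- function(read, kept, dropped) {
  list(rows_read = as.integer(read), rows_kept = as.integer(kept),
       dropped = dropped)
}

#' Retrieve the load/filter report attached to a pipeline table
#'
#' @param x A tibble returned by [read_summary_stats()], [filter_pvalue()]
#'   and friends.
#' @return The report (a named list), or `NULL` when none is attached.
#' @export
load_report <- function(x) {
  attr(x, "load_report") %||% attr(x, "filter_log")
}

empty_summary_stats <- function() {
  tibble::tibble(
    snp_id = character(), chrom = character(), pos = integer(),
    effect_allele = character(), other_allele = character(),
    eaf = double(), beta = double(), se = double(), pval = double(),
    n = double()
  )
}

#' Write a result table as tab-delimited UTF-8 text
#'
#' All pipeline outputs (instrument panels, estimates, sensitivity reports,
#' leave-one-out series) are written through this one function so that
#' every file shares a dialect: tab-delimited, header row, UTF-8, doubles
#' rendered with full round-trip precision (more than 10 significant
#' digits), so a read-back reproduces every value.
#'
#' @param x A data frame with a uniform schema.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_mr_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(x)
}

#' Read back a table written by [write_mr_table()]
#'
#' @param path File path.
#' @return A tibble with column types guessed from the content.
#' @export
read_mr_table <- function(path) {
  readr::read_tsv(path, na = "NA", progress = FALSE, show_col_types = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
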