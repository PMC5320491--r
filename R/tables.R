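#' Load a curated sex-specific result table
#'
#' The package ships curated machine-readable copies of the two published
#' result tables of the underlying cohort study: the 26 expression probes and
#' the 92 CpG sites whose significance rankings differ between the sexes
#' (p < 0.05 on the rank-difference statistic). Curation notes (thousands
#' separators, one corrected gene symbol, absolute values of the final
#' methylation column) are recorded in the fixture headers. Rows are
#' validated on load: positive integer ranks, effect ratios > 0, beta means
#' in [0, 100] %, and printed delta-beta / delta-delta-beta columns
#' consistent with the beta means within 0.02 (rounding slack).
#'
#' @param table `"table2"` (expression) or `"table3"` (methylation).
#' @return A validated data.frame; expression columns `probe_id`,
#'   `gene_symbol`, `rank_m`, `rank_f`, `p_rank_diff`, `effect_m`,
#'   `effect_f`; methylation columns `cpg_id`, `gene_symbol`, `rank_m`,
#'   `rank_f`, `p_rank_diff`, `beta_current_m`, `beta_never_m`,
#'   `delta_beta_m`, `beta_current_f`, `beta_never_f`, `delta_beta_f`,
#'   `abs_delta_delta_beta`.
#' @export
load_flagged_fixture <- function(table = c("table2", "table3")) {
  if (length(table) != 1 || !table %in% c("table2", "table3"))
    stopf("unknown table '%s'; use 'table2' or 'table3'",
          paste(table, collapse = ","))
  fname <- if (table == "table2") "table2_expression.tsv" else "table3_cpg.tsv"
  path <- system.file("extdata", fname, package = "sexspec")
  if (!nzchar(path)) stopf("fixture %s not installed", fname)
  rows <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  tol <- 0.02 + 1e-9
  chk_rank <- function(r) all(is.finite(r)) && all(r >= 1) && all(r == round(r))
  if (table == "table2") {
    if (!chk_rank(rows$rank_m) || !chk_rank(rows$rank_f))
      stopf("fixture ranks must be positive integers")
    if (any(rows$effect_m <= 0) || any(rows$effect_f <= 0))
      stopf("fixture effect ratios must be > 0")
  } else {
    if (!chk_rank(rows$rank_m) || !chk_rank(rows$rank_f))
      stopf("fixture ranks must be positive integers")
    betas <- as.matrix(rows[, c("beta_current_m", "beta_never_m",
                                "beta_current_f", "beta_never_f")])
    if (any(betas < 0) || any(betas > 100))
      stopf("fixture beta means must lie in [0, 100] %%")
    dev_m <- abs(rows$delta_beta_m - (rows$beta_current_m - rows$beta_never_m))
    dev_f <- abs(rows$delta_beta_f - (rows$beta_current_f - rows$beta_never_f))
    dev_dd <- abs(rows$abs_delta_delta_beta -
                    abs(rows$delta_beta_f - rows$delta_beta_m))
    if (any(dev_m > tol) || any(dev_f > tol) || any(dev_dd > tol))
      stopf("fixture delta-beta columns inconsistent with beta means beyond 0.02")
  }
  if (any(rows$p_rank_diff <= 0 | rows$p_rank_diff >= 1))
    stopf("fixture rank-difference p-values must lie in (0, 1)")
  rows
}

#' Expression effect-size ratios by sex stratum
#'
#' Per-feature ratio of geometric-mean expression, current over never
#' smokers, within one sex: `2^(mean log2 current - mean log2 never)`.
#'
#' @param matrix An expression `omics_matrix` (log2 intensities).
#' @param phenotypes Phenotype table.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector of ratios (feature id -> ratio).
#' @export
expression_effect_ratio <- function(matrix, phenotypes, sex) {
  if (!inherits(matrix, "omics_matrix") || matrix$modality != "expression_log2")
    stopf("matrix must be an expression_log2 omics_matrix")
  grp <- stratum_groups_(matrix, phenotypes, sex)
  2^(rowMeans(matrix$values[, grp$current, drop = FALSE]) -
       rowMeans(matrix$values[, grp$never, drop = FALSE]))
}

#' Methylation delta-beta by sex stratum, and the sex contrast
#'
#' `methylation_delta_beta` returns, per CpG, the difference in mean %
#' methylation between current and never smokers within one sex:
#' `100 * (mean beta current - mean beta never)`. `delta_delta` combines the
#' two strata into the absolute female-vs-male contrast
#' `|delta_beta_f - delta_beta_m|`.
#'
#' @param matrix A methylation `omics_matrix` (beta fractions).
#' @param phenotypes Phenotype table.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector of delta-beta values in percentage points.
#' @export
methylation_delta_beta <- function(matrix, phenotypes, sex) {
  if (!inherits(matrix, "omics_matrix") || matrix$modality != "methylation_beta")
    stopf("matrix must be a methylation_beta omics_matrix")
  grp <- stratum_groups_(matrix, phenotypes, sex)
  100 * (rowMeans(matrix$values[, grp$current, drop = FALSE]) -
           rowMeans(matrix$values[, grp$never, drop = FALSE]))
}

#' @param delta_beta_f,delta_beta_m per-feature delta-beta values (%) from the
#'   two sex strata.
#' @rdname methylation_delta_beta
#' @export
delta_delta <- function(delta_beta_f, delta_beta_m) {
  abs(delta_beta_f - delta_beta_m)
}

stratum_groups_ <- function(matrix, phenotypes, sex) {
  if (length(sex) != 1 || !sex %in% c("male", "female"))
    stopf("sex must be 'male' or 'female'")
  ph <- phenotypes[phenotypes$sex == sex, , drop = FALSE]
  cur <- ph$subject_id[ph$smoking_status == "current"]
  nev <- ph$subject_id[ph$smoking_status == "never"]
  if (length(cur) == 0 || length(nev) == 0)
    stopf("empty smoking group in the %s stratum", sex)
  missing <- setdiff(c(cur, nev), colnames(matrix$values))
  if (length(missing))
    stopf("matrix lacks columns for %d stratum subjects", length(missing))
  list(current = cur, never = nev)
}

#' Median at printed precision
#'
#' Median convention used for the table summaries: with an odd count, the
#' middle order statistic; with an even count, the mean of the two central
#' order statistics truncated toward zero at the printed precision (integers
#' for ranks, two decimals for delta-beta and effect ratios). This convention
#' reproduces all the published even-count medians simultaneously.
#'
#' @param x numeric values.
#' @param digits printed decimal places (0 for ranks).
#' @return The median at printed precision.
#' @export
median_printed <- function(x, digits = 0) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) stopf("empty input")
  if (n %% 2 == 1) return(x[(n + 1) / 2])
  m <- (x[n / 2] + x[n / 2 + 1]) / 2
  trunc(m * 10^digits) / 10^digits
}

#' Summary statistics of a flagged result table
#'
#' Recomputes the summary statistics reported about the sex-specific result
#' tables. A row is female-specific when its female rank is better (smaller)
#' than its male rank. Medians and ranges of ranks and effect sizes are taken
#' over the female-specific subset (for the methylation table every row is
#' female-specific, so this equals the full table); medians use
#' [median_printed()] at the printed precision.
#'
#' @param rows A fixture data.frame ([load_flagged_fixture()]) or any table
#'   with the same columns.
#' @param table_kind `"expression"` or `"methylation"`.
#' @return A list of class `summary_report`; for expression: `n`,
#'   `n_female_specific`, `n_male_specific`, `median_rank_f`,
#'   `median_rank_m`, `median_effect_f`, `median_effect_m`,
#'   `range_effect_f`, `range_effect_m`; for methylation: `n`,
#'   `n_female_specific`, `n_male_specific`, `median_rank_f`,
#'   `median_rank_m`, `median_abs_delta_beta_f`, `median_abs_delta_beta_m`,
#'   `range_abs_delta_beta_f`, `range_abs_delta_beta_m`.
#' @export
summarize_flagged <- function(rows, table_kind = c("expression", "methylation")) {
  table_kind <- match.arg(table_kind)
  if (nrow(rows) == 0) stopf("empty input")
  fs <- rows$rank_f < rows$rank_m
  sub <- rows[fs, , drop = FALSE]
  if (nrow(sub) == 0) sub <- rows  # all male-specific: summarise what is there
  out <- list(
    n = nrow(rows),
    n_female_specific = sum(fs),
    n_male_specific = sum(!fs),
    median_rank_f = median_printed(sub$rank_f, 0),
    median_rank_m = median_printed(sub$rank_m, 0)
  )
  if (table_kind == "expression") {
    out$median_effect_f <- median_printed(sub$effect_f, 2)
    out$median_effect_m <- median_printed(sub$effect_m, 2)
    out$range_effect_f <- range(sub$effect_f)
    out$range_effect_m <- range(sub$effect_m)
  } else {
    adb_f <- abs(sub$delta_beta_f)
    adb_m <- abs(sub$delta_beta_m)
    out$median_abs_delta_beta_f <- median_printed(adb_f, 2)
    out$median_abs_delta_beta_m <- median_printed(adb_m, 2)
    out$range_abs_delta_beta_f <- range(adb_f)
    out$range_abs_delta_beta_m <- range(adb_m)
  }
  structure(out, class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("%d rows: %d female-specific, %d male-specific\n",
              x$n, x$n_female_specific, x$n_male_specific))
  cat(sprintf("median ranks: %s (female) / %s (male)\n",
              format(x$median_rank_f, big.mark = ","),
              format(x$median_rank_m, big.mark = ",")))
  if (!is.null(x$median_effect_f))
    cat(sprintf("median effect ratio: %.2f (female, range %.2f-%.2f) / %.2f (male, range %.2f-%.2f)\n",
                x$median_effect_f, x$range_effect_f[1], x$range_effect_f[2],
                x$median_effect_m, x$range_effect_m[1], x$range_effect_m[2]))
  if (!is.null(x$median_abs_delta_beta_f))
    cat(sprintf("median |delta beta|: %.2f%% (female, range %.2f-%.2f) / %.2f%% (male, range %.2f-%.2f)\n",
                x$median_abs_delta_beta_f, x$range_abs_delta_beta_f[1],
                x$range_abs_delta_beta_f[2], x$median_abs_delta_beta_m,
                x$range_abs_delta_beta_m[1], x$range_abs_delta_beta_m[2]))
  invisible(x)
}
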