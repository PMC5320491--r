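#' Model specification for per-feature smoking association
#'
#' Describes one differential-analysis run: the dependent-variable transform,
#' the adjustment covariates, batch and cell-composition adjustment, and the
#' stratum of subjects to analyse. Smoking is coded current = 1 vs never = 0;
#' former smokers are excluded by the default stratum filter.
#'
#' @param transform `"identity_log2"` (expression) or `"m_value"`
#'   (methylation beta fractions are logit2-transformed before fitting).
#' @param covariates character vector of phenotype columns used as adjustment
#'   covariates. `sex` should be included in mixed-sex runs and omitted in
#'   sex-stratified runs.
#' @param batch logical; adjust for the assay's processing batch as a fixed
#'   indicator covariate.
#' @param cells logical; adjust for the six leukocyte fractions (methylation
#'   only; one fraction is dropped to avoid the sum-to-one collinearity).
#' @param sex optional stratum filter: `"male"`, `"female"` or `NULL` (both).
#' @param smoking smoking groups retained; the first level is the exposed
#'   group, the second the referent.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(transform = c("identity_log2", "m_value"),
                       covariates = c("age", "bmi", "cohort",
                                      "future_disease", "case_control"),
                       batch = TRUE, cells = FALSE,
                       sex = NULL, smoking = c("current", "never")) {
  transform <- match.arg(transform)
  if (!is.null(sex) && !sex %in% c("male", "female"))
    stopf("sex stratum must be 'male', 'female' or NULL")
  if (length(smoking) != 2 || !all(smoking %in% c("current", "former", "never")))
    stopf("smoking must name an exposed and a referent group")
  structure(list(transform = transform, covariates = covariates,
                 batch = batch, cells = cells, sex = sex, smoking = smoking),
            class = "model_spec")
}

cell_cols_ <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")

build_design_ <- function(ph, spec, batch_col) {
  smoke <- as.numeric(ph$smoking_status == spec$smoking[1])
  df <- data.frame(smoking = smoke)
  for (cv in spec$covariates) {
    if (!cv %in% names(ph)) stopf("covariate '%s' not in phenotype table", cv)
    v <- ph[[cv]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) v <- droplevels(v)
    df[[cv]] <- v
  }
  if (spec$batch) df$batch <- droplevels(factor(ph[[batch_col]]))
  design <- stats::model.matrix(~ ., data = df)
  if (spec$cells) {
    # drop the first fraction: the six sum to one
    design <- cbind(design, as.matrix(ph[, cell_cols_[-1]]))
  }
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stopf("rank-deficient design: collinear column(s) %s",
          paste(dropped, collapse = ", "))
  }
  design
}

#' Per-feature association of smoking with an omics matrix
#'
#' Fits, for every feature, an ordinary least-squares linear model of the
#' (transformed) feature values on a current-vs-never smoking indicator plus
#' the adjustment covariates of the [model_spec()], within the requested
#' stratum. The per-feature fits are computed with `limma::lmFit` and the
#' reported p-value is the two-sided (non-moderated) Wald t-test of the
#' smoking coefficient. Processing batches enter as fixed indicator
#' covariates. Benjamini-Hochberg and Bonferroni adjusted values are attached.
#'
#' @param matrix An `omics_matrix` (see [generate_omics()] /
#'   [read_omics_matrix()]).
#' @param phenotypes Phenotype table covering the matrix's subjects.
#' @param spec A [model_spec()].
#' @return A data.frame of class `feature_association` with columns
#'   `feature_id`, `coef`, `se`, `p_value`, `q_bh`, `p_bonferroni`, `n`.
#' @export
fit_associations <- function(matrix, phenotypes, spec) {
  if (!inherits(matrix, "omics_matrix")) stopf("matrix must be an omics_matrix")
  if (!inherits(spec, "model_spec")) stopf("spec must be a model_spec")
  if (spec$transform == "m_value" && matrix$modality != "methylation_beta")
    stopf("m_value transform requires a methylation_beta matrix")
  if (spec$cells && matrix$modality != "methylation_beta")
    stopf("cell-composition adjustment applies to methylation only")

  ph <- phenotypes[phenotypes$smoking_status %in% spec$smoking, , drop = FALSE]
  if (!is.null(spec$sex)) ph <- ph[ph$sex == spec$sex, , drop = FALSE]
  counts <- table(factor(ph$smoking_status, levels = spec$smoking))
  if (any(counts < 2))
    stopf("stratum filter leaves fewer than 2 subjects in group '%s'",
          names(counts)[which(counts < 2)[1]])
  missing_sub <- setdiff(ph$subject_id, colnames(matrix$values))
  if (length(missing_sub))
    stopf("matrix lacks columns for %d phenotype subjects", length(missing_sub))

  vals <- matrix$values[, ph$subject_id, drop = FALSE]
  if (spec$transform == "m_value") vals <- beta_to_m(vals)

  batch_col <- if (matrix$modality == "methylation_beta")
    "batch_methylation" else "batch_expression"
  design <- build_design_(ph, spec, batch_col)

  fit <- limma::lmFit(vals, design)
  cf <- fit$coefficients[, "smoking"]
  se <- fit$stdev.unscaled[, "smoking"] * fit$sigma
  tstat <- cf / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]

  out <- data.frame(
    feature_id = rownames(vals),
    coef = unname(cf), se = unname(se), p_value = unname(p),
    q_bh = multiple_testing_adjust(unname(p), "bh"),
    p_bonferroni = multiple_testing_adjust(unname(p), "bonferroni"),
    n = nrow(ph),
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_association", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR values (capped at 1) or Bonferroni
#' `min(1, m * p)`.
#'
#' @param p_values numeric p-values, all in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted values, same length and order as the input.
#' @export
multiple_testing_adjust <- function(p_values, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stopf("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

#' Select candidate features by adjusted significance
#'
#' Features whose adjusted value falls below the threshold, ordered by
#' ascending raw p-value (ties broken by feature id). With
#' `method = "top"`, `threshold` is instead an integer count and the
#' `threshold` smallest raw p-values are selected; this supports calibration
#' analyses under a global null, where an FDR rule selects (correctly) almost
#' nothing.
#'
#' @param assocs A `feature_association` data.frame ([fit_associations()]).
#' @param threshold adjusted-value threshold in (0, 1), or a count for
#'   `method = "top"`.
#' @param method `"bh"`, `"bonferroni"` or `"top"`.
#' @return Character vector of candidate feature ids.
#' @export
select_candidates <- function(assocs, threshold, method = c("bh", "bonferroni", "top")) {
  method <- match.arg(method)
  if (!all(c("feature_id", "p_value") %in% names(assocs)))
    stopf("assocs must have feature_id and p_value columns")
  ord <- order(assocs$p_value, assocs$feature_id)
  if (method == "top") {
    k <- as.integer(threshold)
    if (k < 1) stopf("top-k threshold must be a positive count")
    return(assocs$feature_id[ord][seq_len(min(k, nrow(assocs)))])
  }
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie in (0, 1)")
  adj <- if (method == "bh") assocs$q_bh else assocs$p_bonferroni
  keep <- ord[adj[ord] < threshold]
  assocs$feature_id[keep]
}
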