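#' Generate a synthetic omics matrix with known ground truth
#'
#' Simulates a feature-by-subject matrix paired with a phenotype table, on the
#' analysis scale of the requested modality: log2 intensities for expression,
#' or M values for methylation (mapped back to beta fractions in the returned
#' matrix, so all methylation values lie strictly in (0, 1)).
#'
#' Each feature belongs to one truth class. `null` features carry no smoking
#' term. `both_sex` features shift current smokers of both sexes by the
#' configured magnitude; `female_specific` (`male_specific`) features shift
#' current smokers of that sex only. Former smokers are generated in the
#' cohort but carry no smoking effect (they are excluded from current-vs-never
#' contrasts downstream). On top of the smoking term, every feature receives
#' per-feature covariate effects (sex, age, BMI; methylation additionally the
#' leukocyte fractions), an additive batch intercept per processing batch, and
#' Gaussian residual noise.
#'
#' @param phenotypes A phenotype table from [generate_phenotypes()].
#' @param config The [study_config()] used to generate the phenotypes.
#' @param modality `"expression_log2"` or `"methylation_beta"`.
#' @return A list with elements `matrix` (an `omics_matrix`: list with
#'   `modality` and a numeric `values` matrix, features x subjects) and
#'   `truth` (a `truth_table` data.frame with `feature_id`, `class`,
#'   `effect`).
#' @export
generate_omics <- function(phenotypes, config,
                           modality = c("expression_log2", "methylation_beta")) {
  modality <- match.arg(modality)
  if (!inherits(config, "study_config"))
    stopf("config must be a study_config object")
  validate_phenotypes(phenotypes)
  n_sub <- nrow(phenotypes)
  if (n_sub == 0) stopf("phenotype table is empty")
  n_feat <- config$n_features
  if (sum(config$classes) > n_feat)
    stopf("effect classes exceed feature count")

  is_methyl <- modality == "methylation_beta"
  prefix <- if (is_methyl) "cpg" else "expr"
  feature_id <- sprintf("%s%05d", prefix, seq_len(n_feat))
  effects <- if (is_methyl) config$effect_methylation else config$effect_expression
  batch_col <- if (is_methyl) "batch_methylation" else "batch_expression"
  offset <- if (is_methyl) 23L else 17L

  with_seed(sub_seed(config$seed, offset), {
    # truth classes assigned at random so class is independent of feature order
    cls <- rep(names(config$classes), config$classes)
    cls <- sample(cls)
    effect <- numeric(n_feat)
    for (k in c("both_sex", "female_specific", "male_specific"))
      effect[cls == k] <- effects[[k]]

    # feature baselines: unimodal for log2 expression, bimodal on the M scale
    # (hypo-/hyper-methylated compartments) for methylation
    if (is_methyl) {
      comp <- sample(1:3, n_feat, replace = TRUE, prob = c(0.4, 0.4, 0.2))
      baseline <- c(-3, 3, 0)[comp] + stats::rnorm(n_feat, 0, c(1, 1, 1.5)[comp])
    } else {
      baseline <- stats::rnorm(n_feat, 8, 2)
    }

    sd_cov <- config$covariate_sd
    coef_sex <- stats::rnorm(n_feat, 0, sd_cov[["sex"]])
    coef_age <- stats::rnorm(n_feat, 0, sd_cov[["age"]])
    coef_bmi <- stats::rnorm(n_feat, 0, sd_cov[["bmi"]])

    batch_lab <- sprintf("b%02d", seq_len(config$n_batches))
    batch_int <- matrix(stats::rnorm(n_feat * config$n_batches, 0, config$batch_sd),
                        nrow = n_feat)
    colnames(batch_int) <- batch_lab

    female <- as.numeric(phenotypes$sex == "female")
    age_c <- phenotypes$age - mean(phenotypes$age)
    bmi_c <- phenotypes$bmi - mean(phenotypes$bmi)
    current <- as.numeric(phenotypes$smoking_status == "current")

    smoke_on <- outer(cls == "both_sex", current) +
      outer(cls == "female_specific", current * female) +
      outer(cls == "male_specific", current * (1 - female))

    vals <- baseline +
      outer(coef_sex, female) +
      outer(coef_age, age_c) +
      outer(coef_bmi, bmi_c) +
      batch_int[, phenotypes[[batch_col]], drop = FALSE] +
      effect * smoke_on +
      matrix(stats::rnorm(n_feat * n_sub, 0, config$noise_sd), nrow = n_feat)

    if (is_methyl) {
      cell_cols <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
      coef_cell <- matrix(stats::rnorm(n_feat * 6, 0, sd_cov[["cell"]]),
                          nrow = n_feat)
      props <- as.matrix(phenotypes[, cell_cols])
      props_c <- sweep(props, 2, colMeans(props))
      vals <- vals + coef_cell %*% t(props_c)
      vals <- m_to_beta(vals)
    }

    dimnames(vals) <- list(feature_id, phenotypes$subject_id)
    mat <- structure(list(modality = modality, values = vals),
                     class = "omics_matrix")
    truth <- data.frame(feature_id = feature_id, class = cls,
                        effect = effect, stringsAsFactors = FALSE)
    class(truth) <- c("truth_table", "data.frame")
    list(matrix = mat, truth = truth)
  })
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %s, %d features x %d subjects\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract feature ids of a truth class
#'
#' @param truth A `truth_table` from [generate_omics()].
#' @param cls One of `"null"`, `"both_sex"`, `"female_specific"`,
#'   `"male_specific"`.
#' @return Character vector of feature ids in that class.
#' @export
truth_labels <- function(truth, cls) {
  valid <- c("null", "both_sex", "female_specific", "male_specific")
  if (length(cls) != 1 || !cls %in% valid)
    stopf("unknown truth class '%s'", paste(cls, collapse = ","))
  if (!all(c("feature_id", "class") %in% names(truth)))
    stopf("truth must have feature_id and class columns")
  truth$feature_id[truth$class == cls]
}
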