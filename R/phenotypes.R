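#' Generate a synthetic phenotype table
#'
#' Draws one record per subject according to the cohort x sex x smoking cell
#' counts of a [study_config()]: demographics (age, BMI truncated to the
#' configured ranges), nested case-control status with future-disease labels
#' (breast cancer for female cases with probability 1/2, B-cell lymphoma
#' otherwise; male cases are B-cell lymphoma), one processing-batch label per
#' assay, and six leukocyte fractions drawn from a Dirichlet distribution
#' (summing to one).
#'
#' @param config A [study_config()].
#' @return A data.frame of class `phenotype_table` with columns `subject_id`,
#'   `sex`, `cohort`, `smoking_status`, `age`, `bmi`, `future_disease`,
#'   `case_control`, `batch_expression`, `batch_methylation` and the six
#'   leukocyte-fraction columns `CD4T`, `CD8T`, `NK`, `Bcell`, `Mono`, `Gran`.
#' @export
generate_phenotypes <- function(config) {
  if (!inherits(config, "study_config"))
    stopf("config must be a study_config object")
  cc <- config$cell_counts
  n_total <- sum(cc$n)

  with_seed(sub_seed(config$seed, 11L), {
    sex <- rep(cc$sex, cc$n)
    cohort <- rep(cc$cohort, cc$n)
    smoking <- rep(cc$smoking_status, cc$n)

    rtruncnorm <- function(n, mean, sd, range) {
      out <- stats::rnorm(n, mean, sd)
      bad <- which(out < range[1] | out > range[2])
      while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] < range[1] | out[bad] > range[2]]
      }
      out
    }
    age <- bmi <- numeric(n_total)
    for (s in c("male", "female")) {
      i <- sex == s
      age[i] <- rtruncnorm(sum(i), config$age_mean[[s]], config$age_sd[[s]],
                           config$age_range[[s]])
      bmi[i] <- rtruncnorm(sum(i), config$bmi_mean[[s]], config$bmi_sd[[s]],
                           config$bmi_range[[s]])
    }

    # case_control is the subject's role in the matched nested design;
    # future_disease is the subject's own later diagnosis. Cases usually (not
    # always) carry a diagnosis, controls occasionally do, so the two labels
    # are related but not collinear.
    case <- stats::runif(n_total) < config$p_case
    disease <- rep("none", n_total)
    diseased <- stats::runif(n_total) < ifelse(case, 0.9, 0.1)
    fem_dis <- which(diseased & sex == "female")
    breast <- fem_dis[stats::runif(length(fem_dis)) < 0.5]
    disease[diseased] <- "b_cell_lymphoma"
    disease[breast] <- "breast_cancer"

    batch_lab <- sprintf("b%02d", seq_len(config$n_batches))
    batch_e <- sample(batch_lab, n_total, replace = TRUE)
    batch_m <- sample(batch_lab, n_total, replace = TRUE)

    cells <- rdirichlet(n_total, config$cell_alpha)
    colnames(cells) <- names(config$cell_alpha)

    ph <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n_total)),
      sex = sex, cohort = cohort, smoking_status = smoking,
      age = age, bmi = bmi,
      future_disease = disease,
      case_control = ifelse(case, "case", "control"),
      batch_expression = batch_e, batch_methylation = batch_m,
      stringsAsFactors = FALSE
    )
    ph <- cbind(ph, as.data.frame(cells))
    class(ph) <- c("phenotype_table", "data.frame")
    validate_phenotypes(ph)
    ph
  })
}

#' Validate a phenotype table
#'
#' Checks uniqueness of subject ids, category enumerations and that the six
#' leukocyte fractions sum to one (within 1e-9).
#'
#' @param ph A phenotype table (data.frame).
#' @return `ph`, invisibly, if valid; otherwise an error.
#' @export
validate_phenotypes <- function(ph) {
  needed <- c("subject_id", "sex", "cohort", "smoking_status", "age", "bmi",
              "future_disease", "case_control",
              "CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
  miss <- setdiff(needed, names(ph))
  if (length(miss))
    stopf("phenotype table is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ph$subject_id))
    stopf("subject ids are not unique")
  if (!all(ph$sex %in% c("male", "female")))
    stopf("invalid sex value")
  if (!all(ph$smoking_status %in% c("current", "former", "never")))
    stopf("invalid smoking_status value")
  if (!all(ph$future_disease %in% c("none", "breast_cancer", "b_cell_lymphoma")))
    stopf("invalid future_disease value")
  cell_cols <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")
  s <- rowSums(as.matrix(ph[, cell_cols]))
  if (any(abs(s - 1) > 1e-9))
    stopf("leukocyte fractions must sum to 1 (max deviation %.3g)",
          max(abs(s - 1)))
  invisible(ph)
}
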