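#' Default cohort x sex x smoking cell counts
#'
#' The two-cohort blood-leukocyte study design: 236 males and 413 females from
#' NSHDS (Northern Sweden) and EPIC-Italy, classified as current, former or
#' never smokers. The published design reports only the margins (cohort totals
#' and smoking totals per sex); the cross-classification used here allocates
#' each sex's smoking counts across cohorts proportionally to the cohort
#' totals, with largest-remainder rounding constrained to reproduce every
#' printed margin exactly.
#'
#' @return A data.frame with columns `cohort`, `sex`, `smoking_status`, `n`.
#' @export
default_cell_counts <- function() {
  data.frame(
    cohort = rep(c("NSHDS", "EPIC_Italy"), each = 3, times = 2),
    sex = rep(c("male", "female"), each = 6),
    smoking_status = rep(c("current", "former", "never"), 4),
    n = c(31L, 74L, 66L,   # male NSHDS
          12L, 28L, 25L,   # male EPIC-Italy
          55L, 51L, 122L,  # female NSHDS
          45L, 42L, 98L),  # female EPIC-Italy
    stringsAsFactors = FALSE
  )
}

#' Study configuration for the synthetic cohort generator
#'
#' Bundles the design of the emulated study: subject counts per
#' cohort x sex x smoking cell, covariate distributions, feature-class sizes
#' and injected effect magnitudes per modality, batch structure and residual
#' noise. Defaults reproduce the study design (236 males / 413 females; 43/100
#' male/female current smokers, 91/220 never smokers) and a feature universe
#' of 2,000 features per modality of which 480 respond to smoking in both
#' sexes and 20 only in female smokers.
#'
#' Effect magnitudes are on the analysis scale: log2 units for expression and
#' M-value units for methylation (injected on the M scale, then mapped back to
#' beta fractions).
#'
#' @param cell_counts data.frame with columns `cohort`, `sex`,
#'   `smoking_status`, `n`; defaults to [default_cell_counts()].
#' @param age_mean,age_sd,age_range named numeric (male/female) age
#'   distribution parameters in years; normal, truncated to `age_range`.
#' @param bmi_mean,bmi_sd,bmi_range as above, in kg/m^2.
#' @param n_features number of features per modality.
#' @param classes named integer vector with entries `null`, `both_sex`,
#'   `female_specific`, `male_specific`; must sum to `n_features`.
#' @param effect_expression,effect_methylation named numeric effect magnitudes
#'   (entries `both_sex`, `female_specific`, `male_specific`) applied to
#'   current smokers of the responding sex(es); log2 units for expression,
#'   M-value units for methylation.
#' @param n_batches number of processing batches per assay.
#' @param batch_sd SD of additive batch intercepts (log2 / M units).
#' @param noise_sd residual SD (log2 / M units); must be > 0.
#' @param covariate_sd named numeric SDs of per-feature covariate
#'   coefficients: `sex` (indicator), `age` (per year), `bmi` (per kg/m^2),
#'   `cell` (per unit leukocyte fraction, methylation only).
#' @param cell_alpha Dirichlet concentration for the 6 leukocyte fractions.
#' @param p_case proportion of subjects that are nested case-control cases.
#' @param seed integer random seed; all outputs are deterministic given it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cell_counts = default_cell_counts(),
                         age_mean = c(male = 51.0, female = 52.8),
                         age_sd = c(male = 8.7, female = 11.3),
                         age_range = list(male = c(30.2, 65.0),
                                          female = c(29.6, 74.9)),
                         bmi_mean = c(male = 26.5, female = 25.4),
                         bmi_sd = c(male = 3.4, female = 4.5),
                         bmi_range = list(male = c(19.0, 39.5),
                                          female = c(18.8, 55.28)),
                         n_features = 2000L,
                         classes = c(null = 1500L, both_sex = 480L,
                                     female_specific = 20L,
                                     male_specific = 0L),
                         effect_expression = c(both_sex = -0.32,
                                               female_specific = -0.32,
                                               male_specific = -0.32),
                         effect_methylation = c(both_sex = 1.0,
                                                female_specific = 1.0,
                                                male_specific = 1.0),
                         n_batches = 10L,
                         batch_sd = 0.3,
                         noise_sd = 0.5,
                         covariate_sd = c(sex = 0.1, age = 0.01,
                                          bmi = 0.02, cell = 2.0),
                         cell_alpha = 60 * c(CD4T = 0.15, CD8T = 0.10,
                                             NK = 0.06, Bcell = 0.06,
                                             Mono = 0.08, Gran = 0.55),
                         p_case = 0.5,
                         seed = 1L) {
  required <- c("cohort", "sex", "smoking_status", "n")
  if (!is.data.frame(cell_counts) || !all(required %in% names(cell_counts)))
    stopf("cell_counts must be a data.frame with columns %s",
          paste(required, collapse = ", "))
  if (any(cell_counts$n < 0) || any(cell_counts$n != round(cell_counts$n)))
    stopf("cell counts must be non-negative integers")
  if (sum(cell_counts$n) == 0)
    stopf("empty design: all cell counts are zero")
  if (!all(cell_counts$sex %in% c("male", "female")))
    stopf("sex must be 'male' or 'female'")
  if (!all(cell_counts$smoking_status %in% c("current", "former", "never")))
    stopf("smoking_status must be 'current', 'former' or 'never'")
  cls_names <- c("null", "both_sex", "female_specific", "male_specific")
  if (!all(cls_names %in% names(classes)))
    stopf("classes must name all of: %s", paste(cls_names, collapse = ", "))
  classes <- classes[cls_names]
  if (any(classes < 0))
    stopf("feature-class sizes must be non-negative")
  if (sum(classes) != n_features)
    stopf("feature-class sizes (%d) must sum to n_features (%d)",
          sum(classes), n_features)
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (n_batches < 1) stopf("n_batches must be >= 1")

  structure(list(
    cell_counts = cell_counts,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    n_features = as.integer(n_features), classes = classes,
    effect_expression = effect_expression,
    effect_methylation = effect_methylation,
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    noise_sd = noise_sd, covariate_sd = covariate_sd,
    cell_alpha = cell_alpha, p_case = p_case,
    seed = seed
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  tot <- tapply(x$cell_counts$n, x$cell_counts$sex, sum)
  cat("Synthetic study configuration\n")
  cat(sprintf("  subjects: %d male / %d female (%d total)\n",
              tot[["male"]], tot[["female"]], sum(tot)))
  cat(sprintf("  features per modality: %d (%s)\n", x$n_features,
              paste(sprintf("%s=%d", names(x$classes), x$classes),
                    collapse = ", ")))
  cat(sprintf("  batches: %d (sd %.2f), residual sd %.2f, seed %s\n",
              x$n_batches, x$batch_sd, x$noise_sd, format(x$seed)))
  invisible(x)
}
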