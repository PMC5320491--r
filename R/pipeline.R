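#' Run the sex-specificity pipeline end to end on a synthetic cohort
#'
#' Executes the full analysis sequence on one simulated study:
#' \enumerate{
#'   \item simulate phenotypes and one omics matrix ([generate_phenotypes()],
#'     [generate_omics()]);
#'   \item mixed-sex differential analysis of current vs never smokers,
#'     adjusted for sex, age, BMI, cohort, future disease, case-control
#'     status and batch (plus leukocyte fractions for methylation);
#'   \item candidate selection by adjusted significance
#'     ([select_candidates()]);
#'   \item sex-stratified differential analyses over the full feature
#'     universe, significance rankings, candidate rank differences, Gaussian
#'     null and survival-function calls ([call_sex_specific()]);
#'   \item optionally, the balanced female-resampling robustness check with
#'     per-round re-analysis and overlap statistics
#'     ([resampling_overlap()]).
#' }
#' Every output is reproducible from the configuration seed. If `out_dir` is
#' given, phenotypes, association lists, calls, the diagnostic histogram, the
#' overlap summary and a run log (package version, seed, parameters) are
#' written there as tab-separated text.
#'
#' @param config A [study_config()].
#' @param modality `"methylation_beta"` or `"expression_log2"`.
#' @param candidate_threshold adjusted-value threshold (or count for
#'   `candidate_method = "top"`). Defaults follow the study's thresholds:
#'   FDR < 0.05 for methylation, FDR < 0.10 for expression.
#' @param candidate_method `"bh"`, `"bonferroni"` or `"top"`.
#' @param alpha per-feature threshold on the rank-difference tail
#'   probability.
#' @param robust_null logical; use the median/MAD null fit.
#' @param resample `NULL`, or a [subsample_spec()] to run the balance check.
#' @param out_dir optional output directory.
#' @return A list with `phenotypes`, `truth`, `mixed`, `candidates`,
#'   `assoc_m`, `assoc_f`, `null`, `calls`, and (when requested) `overlap`.
#' @export
run_sex_specific_pipeline <- function(config,
                                      modality = c("methylation_beta",
                                                   "expression_log2"),
                                      candidate_threshold = NULL,
                                      candidate_method = "bh",
                                      alpha = 0.05,
                                      robust_null = FALSE,
                                      resample = NULL,
                                      out_dir = NULL) {
  modality <- match.arg(modality)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  is_methyl <- modality == "methylation_beta"
  if (is.null(candidate_threshold))
    candidate_threshold <- if (is_methyl) 0.05 else 0.10
  transform <- if (is_methyl) "m_value" else "identity_log2"

  ph <- generate_phenotypes(config)
  om <- generate_omics(ph, config, modality)

  covars <- c("age", "bmi", "cohort", "future_disease", "case_control")
  spec_mixed <- model_spec(transform, covariates = c("sex", covars),
                           batch = TRUE, cells = is_methyl)
  mixed <- fit_associations(om$matrix, ph, spec_mixed)
  candidates <- select_candidates(mixed, candidate_threshold, candidate_method)
  if (length(candidates) < 3)
    stopf("pipeline stage 'candidate selection': only %d candidates at threshold %s",
          length(candidates), format(candidate_threshold))

  stratified_calls <- function(subjects) {
    ph_s <- ph[ph$subject_id %in% subjects, , drop = FALSE]
    a_m <- fit_associations(om$matrix, ph_s, model_spec(
      transform, covariates = covars, batch = TRUE, cells = is_methyl,
      sex = "male"))
    a_f <- fit_associations(om$matrix, ph_s, model_spec(
      transform, covariates = covars, batch = TRUE, cells = is_methyl,
      sex = "female"))
    r_m <- rank_by_pvalue(a_m, "male")
    r_f <- rank_by_pvalue(a_f, "female")
    diffs <- compute_rank_differences(r_m, r_f, candidates)
    null <- fit_gaussian_null(diffs, robust = robust_null)
    list(assoc_m = a_m, assoc_f = a_f,
         calls = call_sex_specific(diffs, null, alpha), null = null)
  }

  full <- stratified_calls(ph$subject_id)
  out <- list(phenotypes = ph, truth = om$truth, mixed = mixed,
              candidates = candidates, assoc_m = full$assoc_m,
              assoc_f = full$assoc_f, null = full$null, calls = full$calls)

  if (!is.null(resample)) {
    if (!inherits(resample, "subsample_spec"))
      stopf("resample must be a subsample_spec")
    full_flagged <- full$calls$feature_id[full$calls$flagged]
    rounds <- lapply(seq_len(resample$rounds), function(r) {
      ids <- draw_balanced_subsample(ph, resample, r)
      sub <- stratified_calls(ids)
      sub$calls$feature_id[sub$calls$flagged]
    })
    out$round_flagged <- rounds
    out$overlap <- if (length(full_flagged))
      resampling_overlap(full_flagged, rounds) else NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotypes(ph, file.path(out_dir, "phenotypes.tsv"))
    write_result_table(mixed, file.path(out_dir, "associations_mixed.tsv"))
    write_result_table(full$assoc_m, file.path(out_dir, "associations_male.tsv"))
    write_result_table(full$assoc_f, file.path(out_dir, "associations_female.tsv"))
    write_result_table(full$calls, file.path(out_dir, "sex_specific_calls.tsv"))
    write_result_table(attr(full$calls, "histogram"),
                       file.path(out_dir, "p_diff_histogram.tsv"))
    if (!is.null(out$overlap))
      write_result_table(
        data.frame(round = seq_along(out$overlap$per_round),
                   overlap_pct = out$overlap$per_round,
                   cumulative_pct = out$overlap$cumulative),
        file.path(out_dir, "resampling_overlap.tsv"))
    log <- c(
      sprintf("sexspec version: %s",
              as.character(utils::packageVersion("sexspec"))),
      sprintf("R version: %s", R.version.string),
      sprintf("seed: %s", format(config$seed)),
      sprintf("modality: %s", modality),
      sprintf("candidate rule: %s < %s", candidate_method,
              format(candidate_threshold)),
      sprintf("alpha: %s", format(alpha)),
      sprintf("n candidates: %d", length(candidates)),
      sprintf("n flagged: %d", sum(full$calls$flagged))
    )
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}
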