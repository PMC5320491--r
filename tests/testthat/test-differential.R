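test_that("BH and Bonferroni adjustments match their definitions", {
  expect_equal(multiple_testing_adjust(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(multiple_testing_adjust(rep(0.01, 100), "bonferroni")[1], 1)
  expect_equal(multiple_testing_adjust(rep(0.2, 5), "bh"), rep(0.2, 5))
  expect_error(multiple_testing_adjust(numeric(0), "bh"), "empty")
  expect_error(multiple_testing_adjust(c(0.5, 0), "bh"), "in \\(0, 1\\]")
  expect_error(multiple_testing_adjust(c(0.5, 1.2), "bh"), "in \\(0, 1\\]")
})

test_that("BH equals the brute-force step-up definition on small inputs", {
  set.seed(424)
  for (rep in 1:60) {
    n <- sample(1:8, 1)
    p <- round(runif(n), sample(1:3, 1))
    p[p == 0] <- 0.001
    expect_equal(multiple_testing_adjust(p, "bh"), brute_force_bh(p))
  }
})

test_that("single-feature fit agrees with stats::lm", {
  cfg <- tiny_config(seed = 8)
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "expression_log2")
  spec <- model_spec("identity_log2",
                     covariates = c("sex", "age", "bmi", "cohort"),
                     batch = FALSE)
  assoc <- fit_associations(om$matrix, ph, spec)

  sub <- ph[ph$smoking_status %in% c("current", "never"), ]
  y <- om$matrix$values[1, sub$subject_id]
  fit <- lm(y ~ I(smoking_status == "current") + sex + age + bmi + cohort,
            data = sub)
  cf <- summary(fit)$coefficients[2, ]
  expect_equal(assoc$coef[1], unname(cf["Estimate"]), tolerance = 1e-10)
  expect_equal(assoc$se[1], unname(cf["Std. Error"]), tolerance = 1e-10)
  expect_equal(assoc$p_value[1], unname(cf["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(assoc$n[1], nrow(sub))
})

test_that("p-values are uniform with nominal type-I error under the global null", {
  # pooled over three independent all-null cohorts (3 x 2,000 features) to
  # keep the Monte-Carlo error of the rejection-rate estimate well inside
  # the asserted band
  p_all <- unlist(lapply(51:53, function(s) {
    cfg <- study_config(seed = s,
                        classes = c(null = 2000L, both_sex = 0L,
                                    female_specific = 0L, male_specific = 0L))
    ph <- generate_phenotypes(cfg)
    om <- generate_omics(ph, cfg, "methylation_beta")
    spec <- model_spec("m_value",
                       covariates = c("sex", "age", "bmi", "cohort",
                                      "future_disease", "case_control"),
                       batch = TRUE, cells = TRUE)
    fit_associations(om$matrix, ph, spec)$p_value
  }))
  frac <- mean(p_all < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
  ks <- suppressWarnings(ks.test(p_all, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong injected effect attains the minimum p in its stratum", {
  # effect = 5 x residual SD; the target feature should be the most
  # significant of 500 in the female stratum in (almost) every replicate
  hits <- 0L
  for (s in 1:20) {
    cfg <- study_config(seed = 600 + s, n_features = 500L,
                        classes = c(null = 499L, both_sex = 0L,
                                    female_specific = 1L, male_specific = 0L),
                        effect_methylation = c(both_sex = 0,
                                               female_specific = 2.5,
                                               male_specific = 0))
    ph <- generate_phenotypes(cfg)
    om <- generate_omics(ph, cfg, "methylation_beta")
    assoc <- fit_associations(om$matrix, ph, model_spec(
      "m_value", covariates = c("age", "bmi", "cohort"), cells = TRUE,
      sex = "female"))
    target <- truth_labels(om$truth, "female_specific")
    if (assoc$feature_id[which.min(assoc$p_value)] == target) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("estimated smoking coefficients are unbiased for the injected effect", {
  effects <- unlist(lapply(1:40, function(s) {
    cfg <- tiny_config(seed = 700 + s, n_features = 20L,
                       classes = c(null = 15L, both_sex = 0L,
                                   female_specific = 5L, male_specific = 0L),
                       effect_methylation = c(both_sex = 0,
                                              female_specific = 1,
                                              male_specific = 0))
    ph <- generate_phenotypes(cfg)
    om <- generate_omics(ph, cfg, "methylation_beta")
    assoc <- fit_associations(om$matrix, ph, model_spec(
      "m_value", covariates = c("age", "bmi", "cohort"), cells = TRUE,
      sex = "female"))
    assoc$coef[assoc$feature_id %in% truth_labels(om$truth, "female_specific")]
  }))
  bias <- mean(effects) - 1
  se <- sd(effects) / sqrt(length(effects))
  expect_lt(abs(bias), 3 * se + 1e-12)
})

test_that("stratified fits are independent across strata", {
  cfg <- tiny_config(seed = 9)
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "expression_log2")
  spec_m <- model_spec("identity_log2", covariates = c("age", "bmi", "cohort"),
                       sex = "male")
  a1 <- fit_associations(om$matrix, ph, spec_m)

  # scramble every female column; the male results must be bit-identical
  om2 <- om
  fem <- ph$subject_id[ph$sex == "female"]
  om2$matrix$values[, fem] <- om2$matrix$values[, rev(fem)] * 2 + 1
  a2 <- fit_associations(om2$matrix, ph, spec_m)
  expect_identical(a1, a2)
})

test_that("degenerate designs and strata are model errors", {
  cfg <- tiny_config(seed = 10)
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "expression_log2")
  ph$const <- 1
  expect_error(
    fit_associations(om$matrix, ph, model_spec("identity_log2",
                                               covariates = "const",
                                               batch = FALSE)),
    "rank-deficient design.*const")
  ph2 <- ph[ph$smoking_status != "current" | ph$sex != "male", ]
  ph2 <- ph2[!(ph2$sex == "male" & ph2$smoking_status == "current"), ]
  expect_error(
    fit_associations(om$matrix, ph2, model_spec("identity_log2",
                                                covariates = "age",
                                                batch = FALSE, sex = "male")),
    "fewer than 2 subjects")
  expect_error(
    fit_associations(om$matrix, ph, model_spec("m_value", covariates = "age")),
    "methylation_beta")
})

test_that("candidate selection filters and orders by significance", {
  assoc <- make_assoc(c(0.001, 0.9, 0.004, 0.5), ids = c("d", "a", "b", "c"))
  assoc$q_bh <- c(0.04, 0.9, 0.09, 0.2)
  expect_equal(select_candidates(assoc, 0.10, "bh"), c("d", "b"))
  expect_equal(select_candidates(assoc, 0.999, "bh"), c("d", "b", "c", "a"))
  expect_equal(select_candidates(assoc, 3, "top"), c("d", "b", "c"))
  expect_equal(select_candidates(make_assoc(numeric(0), character(0)),
                                 0.1, "bh"), character(0))
  expect_error(select_candidates(assoc, 1.5, "bh"), "threshold")
})
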