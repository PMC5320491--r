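test_that("default design reproduces the study's population margins", {
  cfg <- study_config(seed = 7)
  ph <- generate_phenotypes(cfg)

  sex_tot <- table(ph$sex)
  expect_equal(unname(sex_tot[["male"]]), 236)
  expect_equal(unname(sex_tot[["female"]]), 413)

  smk <- table(ph$smoking_status)
  expect_equal(unname(smk[["current"]]), 143)
  expect_equal(unname(smk[["never"]]), 311)

  cn <- ph[ph$smoking_status %in% c("current", "never"), ]
  expect_equal(sum(cn$sex == "male"), 134)
  expect_equal(sum(cn$sex == "female"), 320)

  # exact cell counts, not just margins
  got <- as.data.frame(table(ph$cohort, ph$sex, ph$smoking_status),
                       stringsAsFactors = FALSE)
  names(got) <- c("cohort", "sex", "smoking_status", "n")
  want <- default_cell_counts()
  key <- function(d) paste(d$cohort, d$sex, d$smoking_status)
  expect_equal(got$n[match(key(want), key(got))], want$n)
})

test_that("phenotype records satisfy the table invariants", {
  ph <- generate_phenotypes(tiny_config(seed = 3))
  expect_false(anyDuplicated(ph$subject_id) > 0)
  expect_true(all(ph$future_disease %in%
                    c("none", "breast_cancer", "b_cell_lymphoma")))
  # breast cancer is a female diagnosis in this design
  expect_true(all(ph$sex[ph$future_disease == "breast_cancer"] == "female"))
  cells <- rowSums(as.matrix(ph[, c("CD4T", "CD8T", "NK", "Bcell",
                                    "Mono", "Gran")]))
  expect_lt(max(abs(cells - 1)), 1e-9)
  expect_true(all(ph$age >= 29.6 & ph$age <= 74.9))
})

test_that("an empty or invalid design is a configuration error", {
  cc <- default_cell_counts()
  cc$n <- 0L
  expect_error(study_config(cell_counts = cc), "empty design")
  cc$n <- -1L
  expect_error(study_config(cell_counts = cc), "non-negative")
  expect_error(study_config(classes = c(null = 10L, both_sex = 0L,
                                        female_specific = 0L,
                                        male_specific = 0L)),
               "sum to n_features")
})

test_that("generation is deterministic given the seed and varies across seeds", {
  cfg <- tiny_config(seed = 11)
  ph1 <- generate_phenotypes(cfg)
  ph2 <- generate_phenotypes(cfg)
  expect_identical(ph1, ph2)
  om1 <- generate_omics(ph1, cfg, "methylation_beta")
  om2 <- generate_omics(ph1, cfg, "methylation_beta")
  expect_identical(om1, om2)

  cfg_b <- tiny_config(seed = 12)
  ph3 <- generate_phenotypes(cfg_b)
  expect_false(isTRUE(all.equal(ph1$age, ph3$age)))
  om3 <- generate_omics(ph3, cfg_b, "methylation_beta")
  expect_false(isTRUE(all.equal(om1$matrix$values, om3$matrix$values)))

  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_phenotypes(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("methylation values stay in (0,1) and round-trip through M values", {
  cfg <- tiny_config(seed = 5)
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "methylation_beta")
  b <- om$matrix$values
  expect_true(all(b > 0 & b < 1))
  expect_lt(max(abs(m_to_beta(beta_to_m(b)) - b)), 1e-9)
})

test_that("truth table covers every feature once and truth_labels filters it", {
  cfg <- tiny_config(seed = 5)
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "expression_log2")
  expect_setequal(om$truth$feature_id, rownames(om$matrix$values))
  expect_false(anyDuplicated(om$truth$feature_id) > 0)
  expect_length(truth_labels(om$truth, "female_specific"), 10)
  expect_length(truth_labels(om$truth, "both_sex"), 10)
  expect_length(truth_labels(om$truth, "null"), 40)
  expect_error(truth_labels(om$truth, "bogus"), "unknown truth class")

  all_null <- tiny_config(seed = 6, classes = c(
    null = 60L, both_sex = 0L, female_specific = 0L, male_specific = 0L))
  om0 <- generate_omics(generate_phenotypes(all_null), all_null,
                        "expression_log2")
  expect_setequal(truth_labels(om0$truth, "null"), om0$truth$feature_id)
})

test_that("injected female-specific M effect appears in females only", {
  # compare current-vs-never group mean M differences against the injected
  # parameter (+1 M unit) within 3 standard errors of each group contrast
  cfg <- study_config(seed = 21, n_features = 200L,
                      classes = c(null = 180L, both_sex = 0L,
                                  female_specific = 20L, male_specific = 0L),
                      effect_methylation = c(both_sex = 0, female_specific = 1,
                                             male_specific = 0),
                      batch_sd = 0, covariate_sd = c(sex = 0, age = 0,
                                                     bmi = 0, cell = 0))
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "methylation_beta")
  m <- beta_to_m(om$matrix$values)
  fem_spec <- truth_labels(om$truth, "female_specific")

  diff_in <- function(sex) {
    cur <- ph$subject_id[ph$sex == sex & ph$smoking_status == "current"]
    nev <- ph$subject_id[ph$sex == sex & ph$smoking_status == "never"]
    se <- cfg$noise_sd * sqrt(1 / length(cur) + 1 / length(nev))
    list(d = rowMeans(m[fem_spec, cur]) - rowMeans(m[fem_spec, nev]), se = se)
  }
  # mean over the 20 injected features within 3 SE of the mean; each single
  # feature within a simultaneous 4-SE envelope
  f <- diff_in("female")
  expect_lt(abs(mean(f$d) - 1), 3 * f$se / sqrt(length(f$d)))
  expect_true(all(abs(f$d - 1) < 4 * f$se))
  mm <- diff_in("male")
  expect_lt(abs(mean(mm$d)), 3 * mm$se / sqrt(length(mm$d)))
  expect_true(all(abs(mm$d) < 4 * mm$se))
})

test_that("zero effects and zero batch scale leave group means equal", {
  cfg <- study_config(seed = 31, n_features = 100L,
                      classes = c(null = 0L, both_sex = 100L,
                                  female_specific = 0L, male_specific = 0L),
                      effect_expression = c(both_sex = 0, female_specific = 0,
                                            male_specific = 0),
                      batch_sd = 0,
                      covariate_sd = c(sex = 0, age = 0, bmi = 0, cell = 0))
  ph <- generate_phenotypes(cfg)
  om <- generate_omics(ph, cfg, "expression_log2")
  v <- om$matrix$values
  cur <- ph$subject_id[ph$smoking_status == "current"]
  nev <- ph$subject_id[ph$smoking_status == "never"]
  d <- rowMeans(v[, cur]) - rowMeans(v[, nev])
  se <- cfg$noise_sd * sqrt(1 / length(cur) + 1 / length(nev))
  expect_true(all(abs(d) < 4 * se))
})
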