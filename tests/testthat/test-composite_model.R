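test_that("univariate binary-marker beta equals ln(OR) of the 2x2 table", {
  ds <- simulate_cohort(pair_config(log(2), 200, 200, seed = 31))
  el <- pattern_element("A", "T", "dominant")
  fit <- fit_composite_logistic(ds, marker_set(A_T = carriage_pattern(el)))
  or <- odds_ratio(evaluate_pattern(ds, el)$table, correct = FALSE)
  expect_equal(unname(fit$beta["A_T"]), log(or$OR), tolerance = 1e-8)
})

test_that("composite fit recovers known coefficients at large n", {
  cfg <- pair_config(0, 10000, 10000, seed = 35,
                     beta = c(log(1.8), log(2.5)))
  ds <- simulate_cohort(cfg)
  ms <- marker_set(
    A = carriage_pattern(pattern_element("A", "T", "dominant")),
    B = carriage_pattern(pattern_element("B", "T", "dominant")))
  fit <- fit_composite_logistic(ds, ms)
  expect_equal(unname(fit$beta["A"]), log(1.8), tolerance = 0.1)
  expect_equal(unname(fit$beta["B"]), log(2.5), tolerance = 0.1)
  expect_true(all(fit$wald_p < 0.01))
})

test_that("complete separation errors by default, ridge fallback works", {
  # marker identical to the outcome
  g <- ifelse(rep(0:1, each = 20) == 1, "TT", "CC")
  ds <- genotype_dataset(sprintf("s%d", 1:40), rep(0:1, each = 20), NULL,
                         list(locus("A", c("C", "T"))),
                         matrix(g, ncol = 1))
  ms <- marker_set(A = carriage_pattern(
    pattern_element("A", "T", "dominant")))
  expect_error(fit_composite_logistic(ds, ms), "separation")
  fit <- fit_composite_logistic(ds, ms, on_separation = "ridge")
  expect_true(fit$ridged)
  expect_true(is.finite(fit$beta["A"]))
})

test_that("apply_model transfers coefficients without refitting", {
  cfg <- pair_config(log(3), 300, 300, seed = 41)
  ds <- simulate_cohort(cfg)
  ms <- marker_set(
    A = carriage_pattern(pattern_element("A", "T", "dominant")),
    B = carriage_pattern(pattern_element("B", "T", "dominant")))
  fit <- fit_composite_logistic(ds, ms)
  expect_equal(roc_auc(apply_model(fit, ds), ds$phenotype)$auc,
               fit$train_auc, tolerance = 1e-12)
  # second cohort from the same generator: AUC within MC noise
  cfg2 <- cfg; cfg2$seed <- 42L
  ds2 <- simulate_cohort(cfg2)
  auc2 <- roc_auc(apply_model(fit, ds2), ds2$phenotype)$auc
  expect_lt(abs(auc2 - fit$train_auc), 0.1)
  # a dataset missing a marker locus errors with its name
  ds3 <- genotype_dataset(ds2$samples, ds2$phenotype, ds2$sex,
                          ds2$loci[1], ds2$genotypes[, 1, drop = FALSE])
  expect_error(apply_model(fit, ds3), "B")
})

test_that("ROC/AUC: extremes, ties, and the Mann-Whitney identity", {
  y <- rep(0:1, each = 10)
  expect_equal(roc_auc(c(rep(0, 10), rep(1, 10)), y)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 20), y)$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")

  set.seed(55)
  s <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)  # heavy ties
  yy <- rbinom(200, 1, plogis(2 * s - 1))
  r <- roc_auc(s, yy)
  expect_equal(r$auc, auc_rank_oracle(s, yy), tolerance = 1e-12)
  # curve runs from (0,0) to (1,1), monotone in both coordinates
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  # complement identity for tie-free scores
  s2 <- runif(100); y2 <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(s2, y2)$auc + roc_auc(-s2, y2)$auc, 1,
               tolerance = 1e-12)
})

test_that("AUC matches pROC on a simulated cohort", {
  skip_if_not_installed("pROC")
  ds <- simulate_cohort(pair_config(log(3), 150, 150, seed = 61))
  ms <- marker_set(
    A = carriage_pattern(pattern_element("A", "T", "dominant")),
    B = carriage_pattern(pattern_element("B", "T", "dominant")))
  fit <- fit_composite_logistic(ds, ms)
  scores <- apply_model(fit, ds)
  ref <- as.numeric(pROC::auc(pROC::roc(ds$phenotype, scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(fit$train_auc, ref, tolerance = 1e-12)
})

test_that("composite AUC is never below the best single marker", {
  ds <- simulate_cohort(pair_config(log(4), 250, 250, seed = 71))
  mkA <- marker_set(A = carriage_pattern(
    pattern_element("A", "T", "dominant")))
  mkB <- marker_set(B = carriage_pattern(
    pattern_element("B", "T", "dominant")))
  both <- marker_set(
    A = carriage_pattern(pattern_element("A", "T", "dominant")),
    B = carriage_pattern(pattern_element("B", "T", "dominant")))
  aucs <- vapply(list(mkA, mkB), function(m) {
    fit_composite_logistic(ds, m)$train_auc
  }, numeric(1))
  expect_gte(fit_composite_logistic(ds, both)$train_auc, max(aucs) - 1e-9)
})

test_that("gender moderation: null and planted male-specific effect", {
  # identical marker effect in both sexes -> interaction near 0
  loci <- data.frame(id = "A", freq = 0.3, mode = "dominant",
                     beta = log(2), stringsAsFactors = FALSE)
  cfg0 <- sim_config(loci, intercept = -2.2, sex_effect = log(1.5),
                     n_case = 10000, n_control = 10000, seed = 81)
  ds0 <- simulate_cohort(cfg0)
  el <- pattern_element("A", "T", "dominant")
  g0 <- gender_moderation_test(ds0, el)
  expect_lt(abs(g0$interaction_beta), 0.1)

  # OR 3 in males, OR 1 in females
  cfg1 <- sim_config(
    data.frame(id = "A", freq = 0.3, mode = "dominant", beta = 0,
               stringsAsFactors = FALSE),
    sex_interactions = data.frame(locus = "A", extra = log(3)),
    intercept = -2.2, n_case = 10000, n_control = 10000, seed = 82)
  ds1 <- simulate_cohort(cfg1)
  g1 <- gender_moderation_test(ds1, el)
  expect_lt(g1$interaction_p, 0.01)
  expect_equal(g1$verdict$call, "synergistic")

  # single-sex dataset errors
  ds_m <- ds1
  ds_m$sex <- rep("M", length(ds_m$sex))
  expect_error(gender_moderation_test(ds_m, el), "both sexes")
})
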