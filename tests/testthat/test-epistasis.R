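test_that("conditional null distribution matches hand enumeration", {
  t1 <- table2x2x2(cases = rep(1, 4), controls = rep(1, 4))
  d <- conditional_null_distribution(t1)
  expect_equal(d$x, 0:2)
  expect_equal(d$prob, c(1 / 18, 8 / 9, 1 / 18), tolerance = 1e-12)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # a zero two-way margin forces a singleton support
  t2 <- table2x2x2(cases = c(5, 3, 0, 0), controls = c(4, 2, 0, 0))
  d2 <- conditional_null_distribution(t2)
  expect_length(d2$x, 1)
  expect_equal(d2$prob, 1)
})

test_that("normalization holds on random tables", {
  set.seed(42)
  for (i in 1:50) {
    d <- conditional_null_distribution(random_3way_table())
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("FLINT p on fixtures: all-ones, symmetric, singleton", {
  expect_equal(flint_exact_test(
    table2x2x2(cases = rep(1, 4), controls = rep(1, 4)))$p, 1)
  t_sym <- table2x2x2(cases = c(3, 1, 1, 3), controls = c(1, 3, 3, 1))
  res <- flint_exact_test(t_sym)
  expect_equal(res$p, flint_oracle(t_sym), tolerance = 1e-10)
  expect_equal(res$p, 0.2840, tolerance = 5e-4)
  t_single <- table2x2x2(cases = c(5, 3, 0, 0), controls = c(4, 2, 0, 0))
  expect_equal(flint_exact_test(t_single)$p, 1)
  expect_equal(flint_exact_test(t_single)$support_size, 1)
})

test_that("FLINT agrees with the all-tables enumeration oracle", {
  set.seed(2024)
  for (i in 1:60) {
    tab <- random_3way_table(max_cell = 5)
    expect_equal(flint_exact_test(tab)$p, flint_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("FLINT p is invariant under permuting the three variable roles", {
  set.seed(7)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in 1:40) {
    tab <- random_3way_table()
    p0 <- flint_exact_test(tab)$p
    for (pm in perms) {
      p <- flint_exact_test(table_from_array(aperm(tab$n, pm)))$p
      expect_equal(p, p0, tolerance = 1e-10)
    }
  }
})

test_that("synergy factor: closed forms, symmetry, zero-cell correction", {
  t_mult <- table2x2x2(cases = c(10, 20, 30, 60),
                       controls = c(10, 10, 10, 10))
  s <- synergy_factor(t_mult)
  expect_equal(s$SF, 1)
  expect_equal(s$or_10, 2); expect_equal(s$or_01, 3)
  expect_equal(s$or_11, 6)

  t_sym <- table2x2x2(cases = c(3, 1, 1, 3), controls = c(1, 3, 3, 1))
  s2 <- synergy_factor(t_sym)
  expect_equal(s2$SF, 81)
  expect_true(s2$ci_low < 1 && s2$ci_high > 1)

  # A/B swap invariance
  set.seed(11)
  for (i in 1:20) {
    tab <- random_3way_table()
    if (any(tab$n == 0)) next
    swapped <- table_from_array(aperm(tab$n, c(2, 1, 3)))
    expect_equal(synergy_factor(tab, correct = FALSE)$SF,
                 synergy_factor(swapped, correct = FALSE)$SF,
                 tolerance = 1e-12)
  }

  t_zero <- table2x2x2(cases = c(0, 2, 3, 4), controls = c(5, 1, 2, 3))
  s3 <- synergy_factor(t_zero)
  expect_true(s3$corrected)
  expect_true(is.finite(s3$SF) && is.finite(s3$ci_high))
})

test_that("SF factors into 2x2 sub-table odds ratios", {
  set.seed(13)
  for (i in 1:20) {
    tab <- random_3way_table()
    if (any(tab$n == 0)) next
    n <- tab$n
    sub_or <- function(a, b) {
      odds_ratio(table2x2(n[a + 1, b + 1, 2], n[1, 1, 2],
                          n[a + 1, b + 1, 1], n[1, 1, 1]),
                 correct = FALSE)$OR
    }
    expect_equal(synergy_factor(tab, correct = FALSE)$SF,
                 sub_or(1, 1) / (sub_or(1, 0) * sub_or(0, 1)),
                 tolerance = 1e-10)
  }
})

test_that("build_3way_table: conservation and marginal consistency", {
  cfg <- pair_config(log(4), 150, 150, seed = 19)
  cfg$missing_rate <- 0.05
  ds <- simulate_cohort(cfg)
  elA <- pattern_element("A", "T", "dominant")
  elB <- pattern_element("B", "T", "dominant")
  tab <- build_3way_table(ds, elA, elB)
  both_complete <- !is.na(pattern_indicator(ds, carriage_pattern(elA))) &
    !is.na(pattern_indicator(ds, carriage_pattern(elB)))
  expect_equal(sum(tab$n), sum(both_complete))
  # collapsing over B reproduces A's 2x2 table on the same complete cases
  collapsed <- apply(tab$n, c(1, 3), sum)
  keep <- both_complete
  ds_cc <- genotype_dataset(ds$samples[keep], ds$phenotype[keep],
                            ds$sex[keep], ds$loci,
                            ds$genotypes[keep, , drop = FALSE])
  recA <- evaluate_pattern(ds_cc, elA)
  expect_equal(collapsed[2, 2], recA$table$n11)
  expect_equal(collapsed[1, 2], recA$table$n10)
  expect_equal(collapsed[2, 1], recA$table$n01)
  expect_equal(collapsed[1, 1], recA$table$n00)
  expect_error(build_3way_table(ds, elA, elA), "share loci")
})

test_that("decision rule requires confirmation by both statistics", {
  mk_syn <- function(sf, lo, hi) structure(
    list(SF = sf, ci_low = lo, ci_high = hi, alpha = 0.05,
         corrected = FALSE), class = "synergy_result")
  mk_flint <- function(p) structure(
    list(p = p, support_size = 10, observed_prob = 0.1),
    class = "flint_result")
  # published decision examples: values as printed in the source tables
  expect_equal(sf_flint_decision(mk_syn(5.18, 1.46, 18.4),
                                 mk_flint(0.018))$call, "synergistic")
  expect_equal(sf_flint_decision(mk_syn(2.22, 0.78, 6.33),
                                 mk_flint(0.18))$call, "none")
  expect_equal(sf_flint_decision(mk_syn(0.39, 0.086, 1.77),
                                 mk_flint(0.26))$call, "none")
  # CI excludes 1 but FLINT insignificant -> none; and vice versa
  expect_equal(sf_flint_decision(mk_syn(3, 1.2, 7), mk_flint(0.3))$call,
               "none")
  expect_equal(sf_flint_decision(mk_syn(0.4, 0.1, 0.9),
                                 mk_flint(0.01))$call, "compensatory")
})

test_that("sf_flint_test detects a strongly planted interaction", {
  ds <- simulate_cohort(pair_config(log(6), 1500, 1500, seed = 23))
  v <- sf_flint_test(ds, pattern_element("A", "T", "dominant"),
                     pattern_element("B", "T", "dominant"))
  expect_equal(v$call, "synergistic")
  expect_gt(v$synergy$SF, 1)
  expect_lt(v$flint$p, 0.05)
})
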