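test_that("Fisher exact p matches hand enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(table2x2(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(table2x2(0, 10, 0, 10)), 1)
  # large-table agreement with an independent choose()-based enumeration
  expect_equal(fisher_exact_2x2(table2x2(33, 187, 8, 189)),
               fisher_oracle(33, 187, 8, 189), tolerance = 1e-12)
  # order of magnitude of the published replication p
  expect_lt(fisher_exact_2x2(table2x2(33, 187, 8, 189)), 5e-4)
  expect_error(fisher_exact_2x2(table2x2(0, 0, 0, 0)), "all-zero")
})

test_that("Fisher exact p equals brute-force enumeration on random tables", {
  set.seed(101)
  for (i in 1:500) {
    repeat {
      cells <- as.integer(stats::rmultinom(1, sample(4:60, 1), rep(1, 4)))
      if (sum(cells) > 0) break
    }
    expect_equal(fisher_exact_2x2(table2x2(cells[1], cells[2],
                                           cells[3], cells[4])),
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("odds ratio reproduces published replication values", {
  # counts rebuilt from printed frequencies at the replication group sizes
  t_crp <- table2x2(reconstruct_counts(0.15, 220),
                    220 - reconstruct_counts(0.15, 220),
                    reconstruct_counts(0.04, 197),
                    197 - reconstruct_counts(0.04, 197))
  or <- odds_ratio(t_crp)
  expect_equal(round(or$OR, 2), 4.17)
  expect_equal(round(or$ci_low, 2), 1.88, tolerance = 0.011)
  expect_equal(round(or$ci_high, 2), 9.26, tolerance = 0.011)

  or2 <- odds_ratio(table2x2(38, 287, 8, 177))
  expect_equal(round(or2$OR, 2), 2.93)

  or3 <- odds_ratio(table2x2(10, 10, 10, 10))
  expect_equal(or3$OR, 1)
  expect_equal(log(or3$ci_low), -log(or3$ci_high), tolerance = 1e-12)
})

test_that("odds ratio inverts under row swap and corrects zero cells", {
  or <- odds_ratio(table2x2(12, 5, 7, 20), correct = FALSE)
  or_swap <- odds_ratio(table2x2(7, 20, 12, 5), correct = FALSE)
  expect_equal(or$OR, 1 / or_swap$OR, tolerance = 1e-12)

  orz <- odds_ratio(table2x2(0, 10, 5, 5))
  expect_true(orz$corrected)
  expect_true(is.finite(orz$OR) && orz$OR > 0)
})

test_that("exact HWE test matches small enumerations and flags monomorphs", {
  expect_equal(hwe_test(1, 0, 1)$p, 1 / 3, tolerance = 1e-12)
  res <- hwe_test(25, 50, 25, method = "chi-square")
  expect_equal(res$p, 1)
  expect_warning(resm <- hwe_test(30, 0, 0), "monomorphic")
  expect_equal(resm$p, 1)
  expect_true(resm$monomorphic)
})

test_that("exact and chi-square HWE p converge for balanced large counts", {
  set.seed(7)
  for (i in 1:5) {
    g <- as.integer(stats::rmultinom(1, 5000, c(0.25, 0.5, 0.25)))
    pe <- hwe_test(g[1], g[2], g[3])$p
    pc <- hwe_test(g[1], g[2], g[3], method = "chi-square")$p
    expect_lt(abs(pe - pc), 0.03)
  }
})

test_that("ld_pair: complete coupling LD gives D' = 1", {
  # only AABB and aabb genotypes: haplotypes AB and ab, no ambiguity
  g <- cbind(rep(c("AA", "CC"), each = 50), rep(c("GG", "TT"), each = 50))
  ds <- genotype_dataset(sprintf("s%d", 1:100), rep(0:1, 50), NULL,
                         list(locus("l1", c("A", "C")),
                              locus("l2", c("G", "T"))), g)
  res <- ld_pair(ds, "l1", "l2")
  expect_equal(abs(res$Dprime), 1, tolerance = 1e-6)
  expect_equal(res$linkage_class, "moderate")
})

test_that("ld_pair: exact independence gives D = 0, LOD = 0", {
  # genotype counts exactly at independence: outer product of HWE margins
  gA <- rep(c("AA", "AC", "CC"), times = c(1, 2, 1))
  gB <- rep(c("GG", "GT", "TT"), times = c(1, 2, 1))
  comb <- expand.grid(a = gA, b = gB, stringsAsFactors = FALSE)
  ds <- genotype_dataset(sprintf("s%d", seq_len(nrow(comb))),
                         rep(0:1, length.out = nrow(comb)), NULL,
                         list(locus("l1", c("A", "C")),
                              locus("l2", c("G", "T"))),
                         as.matrix(comb))
  res <- ld_pair(ds, "l1", "l2")
  expect_equal(res$D, 0, tolerance = 1e-9)
  expect_equal(res$LOD, 0, tolerance = 1e-9)
  expect_equal(res$linkage_class, "weak")
})

test_that("EM haplotype frequencies match direct likelihood maximization", {
  cfg <- pair_config(0, 150, 150, seed = 21)
  cfg$ld_pairs <- data.frame(locusA = "A", locusB = "B", dprime = 0.5)
  ds <- simulate_cohort(cfg)
  res <- ld_pair(ds, "A", "B")
  # 1-parameter profile: haplotype freqs given the (sufficient) allele freqs
  d1 <- sapply(strsplit(ds$genotypes[, "A"], ""), function(x) sum(x == "T"))
  d2 <- sapply(strsplit(ds$genotypes[, "B"], ""), function(x) sum(x == "T"))
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  cnt <- table(factor(d1, 0:2), factor(d2, 0:2))
  ll <- function(pab) {
    p <- c(pab, pA - pab, pB - pab, 1 - pA - pB + pab)
    if (any(p <= 0)) return(-Inf)
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- p[1]^2; pr[3, 2] <- 2 * p[1] * p[2]; pr[3, 1] <- p[2]^2
    pr[2, 3] <- 2 * p[1] * p[3]; pr[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
    pr[2, 1] <- 2 * p[2] * p[4]; pr[1, 3] <- p[3]^2
    pr[1, 2] <- 2 * p[3] * p[4]; pr[1, 1] <- p[4]^2
    m <- as.matrix(cnt)  # row/col i = dosage i-1 of the risk allele
    sum(m[m > 0] * log(pr[m > 0]))
  }
  opt <- stats::optimize(ll, c(max(0, pA + pB - 1), min(pA, pB)),
                         maximum = TRUE, tol = 1e-12)
  # EM reports freq of the risk-allele (T) haplotype as "AB"
  expect_equal(res$haplotype_freq[["AB"]], opt$maximum, tolerance = 1e-6)
})

test_that("|D'| is invariant under allele relabeling", {
  cfg <- pair_config(0, 100, 100, seed = 33)
  cfg$ld_pairs <- data.frame(locusA = "A", locusB = "B", dprime = 0.6)
  ds <- simulate_cohort(cfg)
  res <- ld_pair(ds, "A", "B")
  # swap the allele order of locus A (flips the dosage reference)
  ds2 <- ds
  ds2$loci[[1]] <- locus("A", rev(ds$loci[[1]]$alleles))
  res2 <- ld_pair(ds2, "A", "B")
  expect_equal(abs(res$Dprime), abs(res2$Dprime), tolerance = 1e-8)
  expect_equal(res$LOD, res2$LOD, tolerance = 1e-8)
  expect_gte(res$LOD, 0)
})

test_that("single_variant_scan flags the planted replication-style signal", {
  ds <- dataset_from_table(33, 187, 8, 189, extra_locus = TRUE)
  res <- single_variant_scan(ds)
  row <- res[res$locus == "rsX" & res$allele == "T" &
               res$mode == "recessive", ]
  expect_equal(round(row$OR, 2), 4.17)
  expect_true(row$significant)
  # identical case/control genotype columns -> nothing flagged
  g <- rep(c("CT", "TT", "CC"), 20)
  ds2 <- genotype_dataset(sprintf("s%d", 1:120), rep(0:1, each = 60), NULL,
                          list(locus("rs1", c("C", "T"))),
                          matrix(c(g, g), ncol = 1))
  expect_false(any(single_variant_scan(ds2)$significant))
})

test_that("single_variant_scan skips monomorphic loci with a warning", {
  ds <- genotype_dataset(sprintf("s%d", 1:8), rep(0:1, 4), NULL,
                         list(locus("rs1", c("C", "T")),
                              locus("rs2", c("A", "G"))),
                         cbind(rep("TT", 8), rep(c("AG", "AA"), 4)))
  expect_warning(res <- single_variant_scan(ds), "monomorphic")
  expect_false("rs1" %in% res$locus)
  expect_true("rs2" %in% res$locus)
})
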