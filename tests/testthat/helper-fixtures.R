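# Shared fixtures and independent oracles for the test suite.

# -- small datasets -----------------------------------------------------------

toy_tsv <- function() {
  c("sample_id\tphenotype\tsex\trs1982073",
    "s1\t1\tM\tTT",
    "s2\t0\tF\tCT")
}

# dataset realizing a given 2x2 table for a recessive TT element at one locus
dataset_from_table <- function(n11, n10, n01, n00, extra_locus = FALSE) {
  n <- n11 + n10 + n01 + n00
  geno <- c(rep("TT", n11), rep("CT", n10), rep("TT", n01), rep("CC", n00))
  phen <- rep(c(1L, 1L, 0L, 0L), c(n11, n10, n01, n00))
  g <- matrix(geno, ncol = 1)
  loci <- list(locus("rsX", c("C", "T")))
  if (extra_locus) {
    g <- cbind(g, rep(c("AG", "GG"), length.out = n))
    loci <- c(loci, list(locus("rsY", c("A", "G"))))
  }
  genotype_dataset(sprintf("s%d", seq_len(n)), phen,
                   sex = rep(c("M", "F"), length.out = n),
                   loci = loci, genotypes = g)
}

# two-locus case-control config with a plantable interaction
pair_config <- function(gamma, n_case, n_control, seed,
                        beta = log(1.3), freq = c(0.3, 0.2)) {
  sim_config(
    loci = data.frame(id = c("A", "B"), freq = freq, mode = "dominant",
                      beta = beta, stringsAsFactors = FALSE),
    epistatic_pairs = data.frame(locusA = "A", locusB = "B", gamma = gamma),
    intercept = -2.2, n_case = n_case, n_control = n_control, seed = seed
  )
}

# null (no-effect) multi-locus config for permutation calibration
null_config <- function(n_loci, n_case, n_control, seed) {
  sim_config(
    loci = data.frame(id = sprintf("L%d", seq_len(n_loci)),
                      freq = seq(0.2, 0.5, length.out = n_loci),
                      mode = "dominant", beta = 0,
                      stringsAsFactors = FALSE),
    intercept = -2.2, n_case = n_case, n_control = n_control, seed = seed
  )
}

# -- independent oracles ------------------------------------------------------

# Fisher 2x2 two-sided p by direct enumeration with choose()
fisher_oracle <- function(n11, n10, n01, n00) {
  k <- n11 + n10; m <- n11 + n01; N <- n11 + n10 + n01 + n00
  xs <- max(0, k + m - N):min(k, m)
  pr <- choose(m, xs) * choose(N - m, k - xs) / choose(N, k)
  sum(pr[pr <= pr[xs == n11] * (1 + 1e-7)])
}

# FLINT oracle: enumerate the A=1 slab cells over a full grid, reconstruct
# the A=0 slab from the B-by-outcome margins, keep tables matching all
# two-way margins, and normalize prod(1/n!) weights.  Structurally
# independent of the one-parameter-family implementation.
flint_oracle <- function(tab) {
  n <- tab$n
  m_by <- apply(n, c(2, 3), sum)  # B x Y margin
  m_ab <- apply(n, c(1, 2), sum)  # A x B margin
  m_ay <- apply(n, c(1, 3), sum)  # A x Y margin
  grid <- expand.grid(n100 = 0:m_by[1, 1], n101 = 0:m_by[1, 2],
                      n110 = 0:m_by[2, 1], n111 = 0:m_by[2, 2])
  # A = 0 slab implied by the B x Y margins
  n000 <- m_by[1, 1] - grid$n100; n001 <- m_by[1, 2] - grid$n101
  n010 <- m_by[2, 1] - grid$n110; n011 <- m_by[2, 2] - grid$n111
  ok <- n000 >= 0 & n001 >= 0 & n010 >= 0 & n011 >= 0 &
    (grid$n100 + grid$n101) == m_ab[2, 1] &
    (grid$n110 + grid$n111) == m_ab[2, 2] &
    (grid$n100 + grid$n110) == m_ay[2, 1] &
    (grid$n101 + grid$n111) == m_ay[2, 2]
  g <- cbind(grid, n000, n001, n010, n011)[ok, , drop = FALSE]
  logw <- -rowSums(lgamma(g + 1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  obs <- g$n111 == n[2, 2, 2] & g$n110 == n[2, 2, 1] &
    g$n101 == n[2, 1, 2] & g$n100 == n[2, 1, 1]
  sum(w[w <= w[obs] * (1 + 1e-12)])
}

# rebuild a table2x2x2 from a 2x2x2 array (dims A, B, Y)
table_from_array <- function(arr) {
  table2x2x2(cases = c(arr[1, 1, 2], arr[2, 1, 2], arr[1, 2, 2], arr[2, 2, 2]),
             controls = c(arr[1, 1, 1], arr[2, 1, 1], arr[1, 2, 1], arr[2, 2, 1]))
}

random_3way_table <- function(max_cell = 6) {
  table_from_array(array(sample(0:max_cell, 8, replace = TRUE), c(2, 2, 2)))
}

# Mann-Whitney AUC via average ranks (independent of the ROC sweep)
auc_rank_oracle <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
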