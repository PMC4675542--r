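#' Construct a 2x2 carriage-by-outcome table
#'
#' @param n11 Carrier cases.
#' @param n10 Non-carrier cases.
#' @param n01 Carrier controls.
#' @param n00 Non-carrier controls.
#' @return An object of class `table2x2`.
#' @export
table2x2 <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("table2x2 cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

# Two-sided Fisher p for scalar counts, probability-mass ordering over the
# hypergeometric support with the conventional 1 + 1e-7 tie tolerance.
# Kept as a tight scalar kernel: pattern mining with a family-wise
# permutation null evaluates it millions of times per run.
fisher_p_scalar <- function(n11, n10, n01, n00) {
  k <- n11 + n10          # cases
  m <- n11 + n01          # carriers
  N <- n11 + n10 + n01 + n00
  if (N == 0L) stop("all-zero 2x2 table", call. = FALSE)
  lo <- max(0L, k + m - N)
  hi <- min(k, m)
  if (lo == hi) return(1)
  d <- stats::dhyper(lo:hi, m, N - m, k)
  sum(d[d <= d[n11 - lo + 1L] * (1 + 1e-7)])
}

fisher_p_vec <- function(n11, n10, n01, n00) {
  vapply(seq_along(n11), function(i) {
    fisher_p_scalar(n11[i], n10[i], n01[i], n00[i])
  }, numeric(1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by probability-mass ordering over the hypergeometric
#' distribution with the table's margins (the convention of
#' [stats::fisher.test()]): the p-value is the total null mass of tables no
#' more probable than the one observed.
#'
#' @param table A [table2x2()].
#' @return The two-sided exact p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(inherits(table, "table2x2"))
  fisher_p_scalar(table$n11, table$n10, table$n01, table$n00)
}

#' Odds ratio with Woolf (log-Wald) confidence interval
#'
#' `OR = (n11 * n00) / (n10 * n01)`; the CI is
#' `exp(ln OR +/- z * sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00))`.  If any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells first.
#'
#' @param table A [table2x2()].
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param correct Apply the 0.5 correction on zero cells (default TRUE;
#'   set FALSE to get the raw cross-product ratio, possibly 0 or Inf).
#' @return List of class `odds_ratio_result` with `OR`, `ci_low`, `ci_high`,
#'   `alpha`, `corrected`.
#' @export
odds_ratio <- function(table, alpha = 0.05, correct = TRUE) {
  stopifnot(inherits(table, "table2x2"))
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  corrected <- FALSE
  if (any(cells == 0L)) {
    if (correct) {
      cells <- cells + 0.5
      corrected <- TRUE
    }
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(OR = or, ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se),
         alpha = alpha, corrected = corrected),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3g (%.0f%% CI %.3g-%.3g)%s\n", x$OR,
              100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$corrected) " [0.5-corrected]" else ""))
  invisible(x)
}

#' Hardy-Weinberg equilibrium test
#'
#' Exact method: conditions on the observed allele counts; the null
#' distribution of the heterozygote count `h` has mass proportional to
#' `2^h / (n_AA! n_Aa! n_aa!)`, and the p-value is the total mass of
#' outcomes no more probable than the observed one.  Chi-square method:
#' 1-df goodness of fit against `p^2, 2pq, q^2`.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @param method `"exact"` (default) or `"chi-square"`.
#' @return List of class `hwe_result` with `p`, `method`, `monomorphic`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chi-square")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("empty genotype counts", call. = FALSE)
  n1 <- 2L * n_aa + n_Aa          # count of the 'a' allele
  if (n1 == 0L || n1 == 2L * n) {
    warning("monomorphic locus: HWE p set to 1")
    return(structure(list(p = 1, method = method, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  if (method == "exact") {
    h_min <- n1 %% 2L
    h <- seq.int(h_min, min(n1, 2L * n - n1), by = 2L)
    naa <- (n1 - h) / 2L
    nAA <- n - naa - h
    logw <- h * log(2) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1)
    w <- exp(logw - max(logw))
    pr <- w / sum(w)
    p_obs <- pr[match(n_Aa, h)]
    p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  } else {
    q <- n1 / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  structure(list(p = p, method = method, monomorphic = FALSE),
            class = "hwe_result")
}

# genotype -> copies of the locus's first allele, NA-safe
allele1_dosage <- function(dataset, locus_id) {
  loc <- get_locus(dataset, locus_id)
  g <- dataset$genotypes[, locus_id]
  d <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  d[ok] <- (substr(g[ok], 1, 1) == loc$alleles[1]) +
    (substr(g[ok], 2, 2) == loc$alleles[1])
  d
}

#' Pairwise linkage disequilibrium (D' and LOD) between two loci
#'
#' Two-locus haplotype frequencies are estimated by EM over the
#' double-heterozygote phase ambiguity (random-union-of-gametes likelihood).
#' `D = p_AB - p_A p_B`; `D'` normalizes by the sign-appropriate bound;
#' `LOD` is the log10 likelihood ratio of the EM optimum against linkage
#' equilibrium.  Loci with `LOD > 2` are classed `"moderate"`, else
#' `"weak"`.
#'
#' @param dataset A [genotype_dataset()].
#' @param locusA,locusB Locus ids.
#' @param tol EM stopping tolerance on the log-likelihood (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List of class `ld_result` with `D`, `Dprime`, `LOD`,
#'   `linkage_class`, `haplotype_freq` (named AB, Ab, aB, ab where A/B are
#'   each locus's first allele), and `n` (complete pairs used).
#' @export
ld_pair <- function(dataset, locusA, locusB, tol = 1e-10, max_iter = 1000L) {
  dA <- allele1_dosage(dataset, locusA)
  dB <- allele1_dosage(dataset, locusB)
  ok <- !is.na(dA) & !is.na(dB)
  if (sum(ok) < 2L) stop("need >= 2 complete genotype pairs", call. = FALSE)
  dA <- dA[ok]; dB <- dB[ok]
  n <- length(dA)
  if (length(unique(dA)) == 1L && dA[1] %in% c(0L, 2L) ||
      length(unique(dB)) == 1L && dB[1] %in% c(0L, 2L)) {
    stop("monomorphic locus: LD undefined", call. = FALSE)
  }
  pA <- mean(dA) / 2
  pB <- mean(dB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic locus: LD undefined", call. = FALSE)
  }
  # 3x3 joint genotype counts, indices = dosage of first allele (0,1,2)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    cnt[dA[i] + 1L, dB[i] + 1L] <- cnt[dA[i] + 1L, dB[i] + 1L] + 1
  }
  loglik <- function(p) {
    # p = c(AB, Ab, aB, ab); per-genotype-class probabilities
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- p[1]^2;           pr[3, 2] <- 2 * p[1] * p[2]
    pr[3, 1] <- p[2]^2;           pr[2, 3] <- 2 * p[1] * p[3]
    pr[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
    pr[2, 1] <- 2 * p[2] * p[4];  pr[1, 3] <- p[3]^2
    pr[1, 2] <- 2 * p[3] * p[4];  pr[1, 1] <- p[4]^2
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }
  # EM from linkage equilibrium
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  ll <- loglik(p)
  for (it in seq_len(max_iter)) {
    # expected haplotype counts; double heterozygote split by phase odds
    e <- numeric(4)
    e[1] <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
    e[2] <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
    e[3] <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
    e[4] <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
    dh <- cnt[2, 2]
    if (dh > 0) {
      w <- p[1] * p[4] / (p[1] * p[4] + p[2] * p[3])
      e[1] <- e[1] + dh * w;       e[4] <- e[4] + dh * w
      e[2] <- e[2] + dh * (1 - w); e[3] <- e[3] + dh * (1 - w)
    }
    p_new <- e / (2 * n)
    ll_new <- loglik(p_new)
    p <- p_new
    if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  p0 <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  lod <- max(0, (ll - loglik(p0)) / log(10))
  D <- p[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax == 0) 0 else D / dmax
  structure(
    list(D = D, Dprime = dprime, LOD = lod,
         linkage_class = if (lod > 2) "moderate" else "weak",
         haplotype_freq = stats::setNames(p, c("AB", "Ab", "aB", "ab")),
         n = n),
    class = "ld_result"
  )
}

#' Scan every single-variant carriage element for association
#'
#' For each locus, evaluates dominant carriage of each allele and each
#' recessive homozygote against the case/control outcome: carriage
#' frequencies, odds ratio with CI, and the two-sided Fisher exact p.
#' Elements passing all gates (CI excludes 1 and `p_f` below the
#' threshold) are flagged.  Monomorphic loci are skipped with a warning.
#'
#' @param dataset A [genotype_dataset()].
#' @param p_f_threshold Fisher-p significance gate (default 0.01).
#' @param alpha CI level for the odds ratio (default 0.05).
#' @return A data.frame with one row per element: `locus`, `allele`,
#'   `mode`, `freq_case`, `freq_control`, `OR`, `ci_low`, `ci_high`,
#'   `p_f`, `significant`.
#' @export
single_variant_scan <- function(dataset, p_f_threshold = 0.01,
                                alpha = 0.05) {
  sizes <- group_sizes(dataset)
  if (any(sizes == 0L)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  rows <- list()
  for (loc in dataset$loci) {
    g <- dataset$genotypes[, loc$id]
    obs <- unique(unlist(strsplit(g[!is.na(g)], "")))
    if (length(obs) < 2L) {
      warning("monomorphic locus skipped: ", loc$id)
      next
    }
    for (a in loc$alleles) {
      for (mode in c("dominant", "recessive")) {
        el <- pattern_element(loc$id, a, mode)
        rec <- evaluate_pattern(dataset, carriage_pattern(el), alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loc$id, allele = a, mode = mode,
          freq_case = rec$freq_case, freq_control = rec$freq_control,
          OR = rec$or_result$OR, ci_low = rec$or_result$ci_low,
          ci_high = rec$or_result$ci_high, p_f = rec$p_f,
          significant = rec$p_f < p_f_threshold &
            (rec$or_result$ci_low > 1 | rec$or_result$ci_high < 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
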