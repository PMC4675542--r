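#' Enumerate carriage patterns up to a given order
#'
#' Generates every conjunction of per-locus carriage elements (dominant
#' carriage of each allele and each recessive homozygote: four elements per
#' biallelic locus) across distinct loci, up to `max_order` loci per
#' pattern, in a deterministic order (ascending order, then locus
#' combination, then element).  This bounded exhaustive enumeration plays
#' the role a stochastic combination sampler plays in larger marker panels:
#' at candidate-gene scale the full pattern space is small enough to visit
#' outright.
#'
#' @param dataset A [genotype_dataset()].
#' @param max_order Maximum number of loci per pattern (default 2).
#' @return List of [carriage_pattern()] objects.
#' @export
enumerate_patterns <- function(dataset, max_order = 2L) {
  stopifnot(max_order >= 1L)
  L <- length(dataset$loci)
  if (max_order > L) {
    warning("max_order ", max_order, " exceeds locus count ", L,
            "; truncated")
    max_order <- L
  }
  per_locus <- lapply(dataset$loci, function(loc) {
    list(pattern_element(loc$id, loc$alleles[1], "dominant"),
         pattern_element(loc$id, loc$alleles[2], "dominant"),
         pattern_element(loc$id, loc$alleles[1], "recessive"),
         pattern_element(loc$id, loc$alleles[2], "recessive"))
  })
  out <- list()
  for (ord in seq_len(max_order)) {
    combs <- utils::combn(L, ord, simplify = FALSE)
    for (cb in combs) {
      idx <- expand.grid(rep(list(1:4), ord))
      # vary the last locus's element fastest for a stable lexicographic order
      for (r in seq_len(nrow(idx))) {
        els <- lapply(seq_len(ord), function(j) {
          per_locus[[cb[j]]][[idx[r, j]]]
        })
        out[[length(out) + 1L]] <- carriage_pattern(els)
      }
    }
  }
  out
}

# Per-pattern carriage matrices for fast repeated counting.
# Returns C0 (carriage with NA -> 0) and M (1 = complete for the pattern),
# both n_samples x n_patterns numeric matrices, plus labels.
pattern_matrices <- function(dataset, patterns) {
  n <- length(dataset$samples)
  # element-level indicators, computed once
  el_key <- function(e) paste(e$locus_id, e$allele, e$mode, sep = "/")
  keys <- unique(unlist(lapply(patterns, function(p) {
    vapply(p$elements, el_key, character(1))
  })))
  E <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  for (k in keys) {
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    E[, k] <- carriage_indicator(
      dataset, pattern_element(parts[1], parts[2], parts[3]))
  }
  P <- length(patterns)
  C0 <- matrix(0, n, P)
  M <- matrix(0, n, P)
  for (i in seq_len(P)) {
    kk <- vapply(patterns[[i]]$elements, el_key, character(1))
    sub <- E[, kk, drop = FALSE]
    miss <- rowSums(is.na(sub)) > 0L
    carr <- rowSums(sub) == length(kk)
    carr[miss] <- FALSE
    C0[, i] <- as.numeric(carr)
    M[, i] <- as.numeric(!miss)
  }
  list(C0 = C0, M = M,
       labels = vapply(patterns, pattern_label, character(1)))
}

# 2x2 counts for every pattern under phenotype y (numeric 0/1)
pattern_counts <- function(pm, y) {
  n11 <- drop(crossprod(pm$C0, y))
  ncase <- drop(crossprod(pm$M, y))
  nc <- 1 - y
  n01 <- drop(crossprod(pm$C0, nc))
  nctrl <- drop(crossprod(pm$M, nc))
  list(n11 = n11, n10 = ncase - n11, n01 = n01, n00 = nctrl - n01)
}

#' Evaluate one carriage pattern against the outcome
#'
#' Carriage is the conjunction (AND) of the pattern's element indicators;
#' samples missing any constituent genotype are excluded (pairwise
#' complete cases).  Returns carriage frequencies, the 2x2 table, the odds
#' ratio with CI, and the two-sided Fisher exact p.
#'
#' @param dataset A [genotype_dataset()].
#' @param pattern A [carriage_pattern()] or [pattern_element()].
#' @param alpha CI level for the odds ratio (default 0.05).
#' @return List of class `association_record` with fields `pattern`,
#'   `label`, `order`, `freq_case`, `freq_control`, `table`, `or_result`,
#'   `p_f`, `p_perm` (NA until [permutation_adjust()]), `degenerate`.
#' @export
evaluate_pattern <- function(dataset, pattern, alpha = 0.05) {
  pattern <- as_pattern(pattern)
  ind <- pattern_indicator(dataset, pattern)
  ok <- !is.na(ind)
  if (!any(ok)) stop("no complete-case samples for pattern ",
                     pattern_label(pattern), call. = FALSE)
  y <- dataset$phenotype[ok]
  c1 <- ind[ok]
  tab <- table2x2(sum(c1 & y == 1L), sum(!c1 & y == 1L),
                  sum(c1 & y == 0L), sum(!c1 & y == 0L))
  new_association_record(pattern, tab, alpha)
}

new_association_record <- function(pattern, tab, alpha, p_perm = NA_real_) {
  ncase <- tab$n11 + tab$n10
  nctrl <- tab$n01 + tab$n00
  structure(
    list(pattern = pattern, label = pattern_label(pattern),
         order = pattern_order(pattern),
         freq_case = if (ncase > 0) tab$n11 / ncase else NA_real_,
         freq_control = if (nctrl > 0) tab$n01 / nctrl else NA_real_,
         table = tab, or_result = odds_ratio(tab, alpha = alpha),
         p_f = fisher_exact_2x2(tab), p_perm = p_perm,
         degenerate = (tab$n11 + tab$n01) == 0L ||
           (tab$n10 + tab$n00) == 0L),
    class = "association_record"
  )
}

#' @export
print.association_record <- function(x, ...) {
  cat(sprintf("%s  freq %.3f/%.3f  OR %.3g (%.3g-%.3g)  p_f %.3g%s\n",
              x$label, x$freq_case, x$freq_control, x$or_result$OR,
              x$or_result$ci_low, x$or_result$ci_high, x$p_f,
              if (!is.na(x$p_perm)) sprintf("  p_perm %.3g", x$p_perm)
              else ""))
  invisible(x)
}

#' Evaluate a list of patterns efficiently
#'
#' Equivalent to calling [evaluate_pattern()] on each pattern, but shares
#' the carriage-matrix computation across patterns.
#'
#' @inheritParams evaluate_pattern
#' @param patterns List of [carriage_pattern()] objects.
#' @return List of `association_record` objects, in pattern order.
#' @export
evaluate_patterns <- function(dataset, patterns, alpha = 0.05) {
  pm <- pattern_matrices(dataset, patterns)
  ct <- pattern_counts(pm, as.numeric(dataset$phenotype))
  lapply(seq_along(patterns), function(i) {
    tab <- table2x2(ct$n11[i], ct$n10[i], ct$n01[i], ct$n00[i])
    new_association_record(patterns[[i]], tab, alpha)
  })
}

#' Minimal-combination filter
#'
#' Retains a multi-element pattern only if its Fisher p is strictly smaller
#' than that of every sub-pattern obtained by removing one element — i.e.
#' the combination is associated with the phenotype more reliably than each
#' of its components.  Order-1 records pass unchanged.
#'
#' @param records List of `association_record`s that includes every
#'   sub-pattern of every multi-element pattern (guaranteed when produced
#'   from [enumerate_patterns()]).
#' @return The retained subset, in input order.
#' @export
minimality_filter <- function(records) {
  p_by_label <- stats::setNames(
    vapply(records, `[[`, numeric(1), "p_f"),
    vapply(records, `[[`, character(1), "label"))
  keep <- vapply(records, function(rec) {
    if (rec$order == 1L) return(TRUE)
    for (drop_i in seq_len(rec$order)) {
      sub <- carriage_pattern(rec$pattern$elements[-drop_i])
      sub_p <- p_by_label[pattern_label(sub)]
      if (is.na(sub_p)) {
        stop("missing sub-pattern record: ", pattern_label(sub),
             call. = FALSE)
      }
      if (rec$p_f >= sub_p) return(FALSE)
    }
    TRUE
  }, logical(1))
  records[keep]
}

#' Family-wise permutation-adjusted p-values
#'
#' For each of `R` permutations, phenotype labels are shuffled (preserving
#' the case/control totals), every pattern is re-evaluated, and the minimum
#' Fisher p over all patterns is recorded.  The adjusted p-value of a
#' pattern is the add-one estimate
#' `p_perm = (1 + #\{permutations with min-p <= observed p_f\}) / (1 + R)`,
#' i.e. the family-wise probability that a whole-search rerun on label-
#' randomized data of the same dimension attains a Fisher p at least as
#' extreme.
#'
#' @param dataset A [genotype_dataset()].
#' @param records Records to adjust (their patterns define the family; if
#'   the family searched was larger, pass `patterns` too).
#' @param R Number of permutations (default 100).
#' @param seed Integer seed for the permutation RNG.
#' @param patterns Optional full pattern family defining the null
#'   (defaults to the records' own patterns).
#' @return `records` with `p_perm` filled in.
#' @export
permutation_adjust <- function(dataset, records, R = 100L, seed = 1L,
                               patterns = NULL) {
  stopifnot(R >= 0L)
  if (R == 0L) {
    return(lapply(records, function(r) { r$p_perm <- 1; r }))
  }
  if (is.null(patterns)) patterns <- lapply(records, `[[`, "pattern")
  pm <- pattern_matrices(dataset, patterns)
  y <- as.numeric(dataset$phenotype)
  minp <- numeric(R)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (r in seq_len(R)) {
    yp <- sample(y)
    ct <- pattern_counts(pm, yp)
    minp[r] <- min(fisher_p_vec(ct$n11, ct$n10, ct$n01, ct$n00))
  }
  lapply(records, function(rec) {
    rec$p_perm <- (1 + sum(minp <= rec$p_f)) / (1 + R)
    rec
  })
}

#' Run the full combination-mining stage
#'
#' Enumerates all patterns up to `max_order`, evaluates them, applies the
#' family-wise permutation adjustment, flags significance against the
#' configured gates (CI excludes 1, `p_f` and `p_perm` below their
#' thresholds), and marks minimal combinations.
#'
#' @inheritParams permutation_adjust
#' @param max_order Maximum pattern order (default 2).
#' @param R Permutations for `p_perm` (default 100).
#' @param p_f_threshold,p_perm_threshold Significance gates
#'   (defaults 0.01 and 0.05).
#' @param alpha CI level (default 0.05).
#' @return A data.frame with one row per pattern: `pattern`, `order`,
#'   `freq_case`, `freq_control`, `OR`, `ci_low`, `ci_high`, `p_f`,
#'   `p_perm`, `minimal`, `significant`; the records themselves are
#'   attached as attribute `"records"`.
#' @export
mine_patterns <- function(dataset, max_order = 2L, R = 100L, seed = 1L,
                          p_f_threshold = 0.01, p_perm_threshold = 0.05,
                          alpha = 0.05) {
  patterns <- enumerate_patterns(dataset, max_order)
  records <- evaluate_patterns(dataset, patterns, alpha = alpha)
  records <- permutation_adjust(dataset, records, R = R, seed = seed)
  minimal_labels <- vapply(minimality_filter(records), `[[`,
                           character(1), "label")
  df <- records_to_df(records)
  df$minimal <- df$pattern %in% minimal_labels
  df$significant <- df$p_f < p_f_threshold &
    df$p_perm < p_perm_threshold &
    (df$ci_low > 1 | df$ci_high < 1)
  attr(df, "records") <- records
  df
}

records_to_df <- function(records) {
  data.frame(
    pattern = vapply(records, `[[`, character(1), "label"),
    order = vapply(records, `[[`, integer(1), "order"),
    freq_case = vapply(records, `[[`, numeric(1), "freq_case"),
    freq_control = vapply(records, `[[`, numeric(1), "freq_control"),
    OR = vapply(records, function(r) r$or_result$OR, numeric(1)),
    ci_low = vapply(records, function(r) r$or_result$ci_low, numeric(1)),
    ci_high = vapply(records, function(r) r$or_result$ci_high, numeric(1)),
    p_f = vapply(records, `[[`, numeric(1), "p_f"),
    p_perm = vapply(records, `[[`, numeric(1), "p_perm"),
    stringsAsFactors = FALSE
  )
}
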