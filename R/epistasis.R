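#' Construct a 2x2x2 carriage-by-carriage-by-outcome table
#'
#' Cells count subjects by carriage of factor A, carriage of factor B, and
#' outcome (1 = case, 0 = control).  Counts are given as two vectors of
#' four, ordered (neither, A-only, B-only, both).
#'
#' @param cases Length-4 vector of case counts (neither, A-only, B-only,
#'   both).
#' @param controls Length-4 vector of control counts, same order.
#' @return An object of class `table2x2x2` wrapping a 2x2x2 integer array
#'   with dimensions A, B, Y.
#' @export
table2x2x2 <- function(cases, controls) {
  stopifnot(length(cases) == 4L, length(controls) == 4L)
  cells <- c(controls, cases)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("table2x2x2 cells must be non-negative integers", call. = FALSE)
  }
  arr <- array(0L, c(2L, 2L, 2L),
               dimnames = list(A = c("0", "1"), B = c("0", "1"),
                               Y = c("0", "1")))
  # (neither, A-only, B-only, both) -> [a+1, b+1]
  for (y in 0:1) {
    v <- as.integer(if (y == 1L) cases else controls)
    arr[1L, 1L, y + 1L] <- v[1]
    arr[2L, 1L, y + 1L] <- v[2]
    arr[1L, 2L, y + 1L] <- v[3]
    arr[2L, 2L, y + 1L] <- v[4]
  }
  structure(list(n = arr), class = "table2x2x2")
}

#' @export
print.table2x2x2 <- function(x, ...) {
  cat("2x2x2 carriage-by-outcome table (A x B, controls then cases):\n")
  print(x$n[, , 1L]); print(x$n[, , 2L])
  invisible(x)
}

as_binary_factor <- function(dataset, factor) {
  if (inherits(factor, c("carriage_pattern", "pattern_element"))) {
    pat <- as_pattern(factor)
    list(ind = pattern_indicator(dataset, pat),
         loci = vapply(pat$elements, `[[`, character(1), "locus_id"),
         label = pattern_label(pat))
  } else {
    v <- as.integer(factor)
    stopifnot(length(v) == length(dataset$samples))
    if (!all(v[!is.na(v)] %in% c(0L, 1L))) {
      stop("binary factor must be 0/1/NA", call. = FALSE)
    }
    list(ind = v, loci = character(0), label = "custom")
  }
}

#' Build the 2x2x2 table for two binary factors
#'
#' Cross-tabulates complete cases by joint carriage status for the two
#' factors and the outcome.  Factors may be carriage patterns/elements or
#' arbitrary per-sample 0/1 indicators (e.g. sex); pattern factors must
#' reference disjoint locus sets.  Marginalizing over either factor
#' reproduces the other factor's 2x2 table on the same complete-case set.
#'
#' @param dataset A [genotype_dataset()].
#' @param factorA,factorB A [carriage_pattern()], [pattern_element()], or a
#'   per-sample 0/1/NA vector.
#' @return A [table2x2x2()].
#' @export
build_3way_table <- function(dataset, factorA, factorB) {
  fa <- as_binary_factor(dataset, factorA)
  fb <- as_binary_factor(dataset, factorB)
  if (length(intersect(fa$loci, fb$loci))) {
    stop("factors share loci: ",
         paste(intersect(fa$loci, fb$loci), collapse = ","), call. = FALSE)
  }
  ok <- !is.na(fa$ind) & !is.na(fb$ind)
  a <- fa$ind[ok]; b <- fb$ind[ok]; y <- dataset$phenotype[ok]
  counts <- function(yy) {
    c(sum(a == 0L & b == 0L & y == yy), sum(a == 1L & b == 0L & y == yy),
      sum(a == 0L & b == 1L & y == yy), sum(a == 1L & b == 1L & y == yy))
  }
  table2x2x2(cases = counts(1L), controls = counts(0L))
}

# The three two-way margins of a 2x2x2 array
margins_3way <- function(n) {
  list(AB = apply(n, c(1, 2), sum),
       AY = apply(n, c(1, 3), sum),
       BY = apply(n, c(2, 3), sum))
}

# Cells of the one-parameter family sharing the table's two-way margins.
# x = n[1][1][1] (both-carrier cases); returns an 8 x length(x) matrix of
# cell counts ordered n111, n110, n101, n011, n100, n010, n001, n000.
cells_given_margins <- function(n, x) {
  m <- margins_3way(n)
  N <- sum(n)
  mA1 <- sum(n[2, , ]); mB1 <- sum(n[, 2, ]); mY1 <- sum(n[, , 2])
  ab <- m$AB[2, 2]; ay <- m$AY[2, 2]; by <- m$BY[2, 2]
  rbind(
    n111 = x,
    n110 = ab - x,
    n101 = ay - x,
    n011 = by - x,
    n100 = mA1 - ab - ay + x,
    n010 = mB1 - ab - by + x,
    n001 = mY1 - ay - by + x,
    n000 = N - mA1 - mB1 - mY1 + ab + ay + by - x
  )
}

#' Conditional null distribution of a 2x2x2 table given its two-way margins
#'
#' Conditioning on all three two-way margins (A x B, A x outcome,
#' B x outcome) leaves a one-parameter family indexed by the both-carrier
#' case count `x`.  Under the no-three-way-interaction null of uniformly
#' distributed class populations with fixed margins, the probability of a
#' feasible table is proportional to the product of `1/n_cell!` over its
#' eight cells (computed in log space and normalized).
#'
#' @param table A [table2x2x2()].
#' @return List with `x` (feasible values of the both-carrier case count),
#'   `prob` (their null probabilities, summing to 1), and `x_obs` (the
#'   observed value).
#' @export
conditional_null_distribution <- function(table) {
  stopifnot(inherits(table, "table2x2x2"))
  n <- table$n
  x_obs <- n[2, 2, 2]
  x_all <- 0:sum(n)
  cells <- cells_given_margins(n, x_all)
  feas <- colSums(cells < 0) == 0L
  if (!any(feas)) stop("no feasible table under the margins", call. = FALSE)
  x <- x_all[feas]
  logw <- -colSums(lgamma(cells[, feas, drop = FALSE] + 1))
  w <- exp(logw - max(logw))
  list(x = x, prob = w / sum(w), x_obs = x_obs)
}

#' FLINT: exact Fisher-like three-way interaction test
#'
#' Tests for three-way interaction in a 2x2x2 table by conditioning on all
#' three two-way margins and summing, over the feasible one-parameter
#' family, the null probabilities of tables no more probable than the one
#' observed (probability ordering, as in Fisher's exact test; multiplicative
#' tie tolerance 1e-12).  One-sided tails order by the both-carrier case
#' count instead.
#'
#' @param table A [table2x2x2()].
#' @param alternative `"two.sided"` (probability ordering, default),
#'   `"greater"` or `"less"` (tail in the both-carrier case count).
#' @param mid_p Subtract half the observed table's probability (default
#'   FALSE).
#' @return List of class `flint_result` with `p`, `support_size`,
#'   `observed_prob`.
#' @export
flint_exact_test <- function(table,
                             alternative = c("two.sided", "greater", "less"),
                             mid_p = FALSE) {
  alternative <- match.arg(alternative)
  d <- conditional_null_distribution(table)
  i_obs <- match(d$x_obs, d$x)
  p_obs <- d$prob[i_obs]
  p <- switch(alternative,
    two.sided = sum(d$prob[d$prob <= p_obs * (1 + 1e-12)]),
    greater   = sum(d$prob[d$x >= d$x_obs]),
    less      = sum(d$prob[d$x <= d$x_obs])
  )
  if (mid_p) p <- p - p_obs / 2
  structure(
    list(p = min(1, p), support_size = length(d$x), observed_prob = p_obs),
    class = "flint_result"
  )
}

#' @export
print.flint_result <- function(x, ...) {
  cat(sprintf("FLINT p = %.4g (support %d tables)\n", x$p, x$support_size))
  invisible(x)
}

#' Synergy factor of a 2x2x2 table
#'
#' With the double non-carrier stratum as baseline, `OR_ab` is the odds
#' ratio of case status in stratum (a, b) versus (0, 0); the synergy factor
#' is `SF = OR_11 / (OR_10 * OR_01)`, the factor by which the joint odds
#' ratio exceeds the product of the single-exposure odds ratios.  SF > 1
#' indicates synergy, SF < 1 compensation.  The CI uses
#' `var(ln SF) = sum over the 8 cells of 1/n_cell`; if any cell is zero,
#' 0.5 is added to all eight cells first (flagged `corrected`).
#'
#' @param table A [table2x2x2()].
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param correct Apply the 0.5 rule on zero cells (default TRUE).
#' @return List of class `synergy_result` with `SF`, `ci_low`, `ci_high`,
#'   `alpha`, `corrected`, and the three stratum odds ratios `or_11`,
#'   `or_10`, `or_01`.
#' @export
synergy_factor <- function(table, alpha = 0.05, correct = TRUE) {
  stopifnot(inherits(table, "table2x2x2"))
  n <- table$n
  corrected <- FALSE
  if (any(n == 0L) && correct) {
    n <- n + 0.5
    corrected <- TRUE
  }
  or_stratum <- function(a, b) {
    (n[a + 1, b + 1, 2] * n[1, 1, 1]) / (n[a + 1, b + 1, 1] * n[1, 1, 2])
  }
  or11 <- or_stratum(1, 1); or10 <- or_stratum(1, 0); or01 <- or_stratum(0, 1)
  sf <- or11 / (or10 * or01)
  se <- sqrt(sum(1 / n))
  z <- stats::qnorm(1 - alpha / 2)
  structure(
    list(SF = sf, ci_low = exp(log(sf) - z * se),
         ci_high = exp(log(sf) + z * se), alpha = alpha,
         corrected = corrected, or_11 = or11, or_10 = or10, or_01 = or01),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("SF %.3g (%.0f%% CI %.3g-%.3g)%s\n", x$SF,
              100 * (1 - x$alpha), x$ci_low, x$ci_high,
              if (x$corrected) " [0.5-corrected]" else ""))
  invisible(x)
}

#' Combine SF and FLINT into an epistasis verdict
#'
#' An interaction is called only when confirmed by both statistics:
#' synergistic iff the SF CI lies entirely above 1 and the FLINT p is below
#' `flint_alpha`; compensatory iff the CI lies entirely below 1 with the
#' same FLINT gate; otherwise none.
#'
#' @param synergy A `synergy_result`.
#' @param flint A `flint_result` computed from the same table.
#' @param sf_alpha Level at which the SF CI was computed (default 0.05).
#' @param flint_alpha FLINT significance gate (default 0.05).
#' @return List of class `epistasis_verdict` with `synergy`, `flint`,
#'   `call` in `{"synergistic", "compensatory", "none"}`.
#' @export
sf_flint_decision <- function(synergy, flint, sf_alpha = 0.05,
                              flint_alpha = 0.05) {
  stopifnot(inherits(synergy, "synergy_result"),
            inherits(flint, "flint_result"))
  if (!isTRUE(all.equal(synergy$alpha, sf_alpha))) {
    warning("SF CI was computed at alpha = ", synergy$alpha,
            ", not the requested ", sf_alpha)
  }
  call <- if (flint$p < flint_alpha && synergy$ci_low > 1) "synergistic"
          else if (flint$p < flint_alpha && synergy$ci_high < 1) "compensatory"
          else "none"
  structure(list(synergy = synergy, flint = flint, call = call),
            class = "epistasis_verdict")
}

#' @export
print.epistasis_verdict <- function(x, ...) {
  print(x$synergy); print(x$flint)
  cat("verdict:", x$call, "\n")
  invisible(x)
}

#' One-call SF+FLINT epistasis test for two factors in a dataset
#'
#' Builds the 2x2x2 table via [build_3way_table()], computes
#' [synergy_factor()] and [flint_exact_test()], and combines them with
#' [sf_flint_decision()].
#'
#' @inheritParams build_3way_table
#' @param sf_alpha,flint_alpha Significance levels (defaults 0.05).
#' @return An `epistasis_verdict` with the table attached as `$table`.
#' @export
sf_flint_test <- function(dataset, factorA, factorB, sf_alpha = 0.05,
                          flint_alpha = 0.05) {
  tab <- build_3way_table(dataset, factorA, factorB)
  v <- sf_flint_decision(synergy_factor(tab, alpha = sf_alpha),
                         flint_exact_test(tab),
                         sf_alpha = sf_alpha, flint_alpha = flint_alpha)
  v$table <- tab
  v
}
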