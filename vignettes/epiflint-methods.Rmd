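---
title: "Methods: carriage association, allelic-combination mining, and the SF+FLINT epistasis test"
author: "epiflint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carriage association, combination mining, and SF+FLINT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiflint)
```

# The scientific problem

Candidate-gene case-control studies of a binary phenotype (here: myocardial
infarction against population controls) test whether *carriage* of an allele
at a biallelic SNP differs between cases and controls. Two carriage codings
are used throughout: **dominant** (at least one copy of the allele) and
**recessive-homozygote** (two copies). Beyond single variants, risk may be
carried by *allelic combinations* — conjunctions of carriage elements at
different loci — and a combination may act either additively (odds ratios
multiply) or *epistatically* (the joint effect departs from the product of
the single-locus effects on the odds scale). This package implements the
whole chain: QC screens, single-variant tests, combination mining with a
permutation-based family-wise null, a two-statistic epistasis procedure on
2×2×2 tables, and composite logistic risk models with ROC evaluation.

# Single-variant and combination association

For a carriage element or pattern, complete cases (subjects genotyped at all
constituent loci; exclusion is pairwise per table, not listwise) are
cross-tabulated into a 2×2 carriage-by-outcome table. We report:

* the **odds ratio** $OR = n_{11} n_{00} / (n_{10} n_{01})$ with a Woolf
  (log-Wald) confidence interval
  $\exp(\ln OR \pm z_{1-\alpha/2}\sqrt{\sum 1/n_{ij}})$; when any cell is
  zero, the Haldane–Anscombe correction adds 0.5 to all four cells (the
  result is flagged). Woolf intervals reproduce, to within one unit in the
  last printed digit, the published intervals we use as fixtures, which is
  why they are the default; the underlying CI method of those tables was
  not stated.
* the **two-sided Fisher exact p** ($p_f$), defined by probability-mass
  ordering over the hypergeometric support (the total null mass of tables
  no more probable than the observed one, with the conventional
  $1 + 10^{-7}$ tie tolerance). Probability ordering rather than
  tail-doubling matches the dominant convention of standard software; the
  package's implementation is validated against `stats::fisher.test` and a
  direct enumeration oracle in the tests. The package ships its own
  vectorized kernel because the permutation null re-evaluates the whole
  pattern family hundreds of times per run.

**Pattern mining.** At candidate-gene scale (≤ 17 loci) the space of
conjunctive patterns up to order 2–3 is small, so the package enumerates it
exhaustively (four elements per biallelic locus: dominant carriage of each
allele, each recessive homozygote) instead of sampling it stochastically.
Exhaustive search visits every pattern a sampler could visit and reports the
same statistics, so nothing is lost at this scale.

**Minimality.** A multi-locus pattern is retained only if its $p_f$ is
*strictly* smaller than that of every sub-pattern obtained by deleting one
element — the combination must be more reliably associated than each of its
components. Ties are resolved against the larger pattern.

**Permutation adjustment.** The permutation p-value answers: how often would
a full rerun of the search on phenotype-shuffled data of the same dimension
produce a Fisher p at least as extreme? For each of $R$ permutations
(default $R = 100$) the case/control labels are shuffled preserving group
totals, every pattern is re-evaluated, and the minimum $p_f$ over the family
is recorded; then
$p_{perm} = (1 + \#\{\min p \le p_f^{obs}\})/(1 + R)$ (add-one estimator,
so $p_{perm} \ge 1/(1+R) > 0$). Taking the family-wise minimum is the
conservative reading of "same result from randomized data of the same
dimension": it controls the family-wise error of the whole search, and the
null pools all pattern orders. Significance gates default to: CI excludes
1, $p_f < 0.01$, $p_{perm} < 0.05$.

# The SF+FLINT epistasis procedure

Interaction between two binary factors $A$, $B$ (any two logical variables —
carriage of two allele sets, or carriage × sex) and the outcome is tested on
the 2×2×2 table $n_{aby}$ by two statistics of different character, and an
interaction is called only when **both** agree.

**Synergy factor.** With the double non-carrier stratum as baseline and
$OR_{ab}$ the odds ratio of stratum $(a,b)$ versus $(0,0)$,

$$SF = \frac{OR_{11}}{OR_{10}\,OR_{01}}
     = \frac{n_{111} n_{100} n_{010} n_{001}}
            {n_{110} n_{101} n_{011} n_{000}},
\qquad \mathrm{var}(\ln SF) = \sum_{a,b,y} \frac{1}{n_{aby}},$$

with a log-normal CI. $SF > 1$ is synergistic, $SF < 1$ compensatory; under
a logistic model with interaction coefficient $\gamma$ on the carriage
product, $SF$ estimates $e^\gamma$. If any of the eight cells is zero, 0.5
is added to *all eight* cells (not only the zero ones): this keeps the
variance formula finite and preserves the A/B symmetry of the statistic;
corrected results are flagged.

**FLINT.** The exact Fisher-like interaction numeric test conditions on all
three two-way margins ($A{\times}B$, $A{\times}Y$, $B{\times}Y$). Under
these constraints the table is a one-parameter family indexed by
$x = n_{111}$, and under the null of uniformly distributed class populations
with fixed margins the probability of a feasible table is proportional to
$\prod_{cells} 1/n_{aby}!$ (computed in log space via `lgamma` and
normalized; relative error is far below $10^{-10}$ at any realistic total).
The two-sided p-value sums the null mass of tables no more probable than the
observed one, mirroring the Fisher convention, with a multiplicative tie
tolerance of $10^{-12}$; the source material does not print its tail rule,
so one-sided tails (ordered by $x$) and a mid-p variant are exposed as
options but off by default. The p-value is invariant under all six
permutations of the roles of $A$, $B$ and outcome, and the implementation is
checked against a brute-force oracle that enumerates all 2×2×2 tables of the
same total and filters on margins.

**Decision.** `synergistic` iff the SF CI lies above 1 *and*
$p_{FLINT} < 0.05$; `compensatory` iff the CI lies below 1 with the same
FLINT gate; otherwise `none`. The conjunction of two tests is conservative:
its type-I rate is below the nominal level of either component (the
acceptance suite measures ≈ 0.035–0.04 at $n = 325/185$).

# QC screens

**Hardy–Weinberg.** The default is the exact conditional test: given the
allele counts, the heterozygote count $h$ has null mass
$\propto 2^h/(n_{AA}!\,n_{Aa}!\,n_{aa}!)$, and the p-value is the mass of
outcomes no more probable than observed. A 1-df chi-square test is available
and converges to the exact p for balanced large-count tables. Violating loci
(default threshold $p < 0.01$, evaluated in cases and controls separately)
are *flagged, not removed*: the original workflow dropped one violating SNP
but retained another that violated HWE in cases only, so removal is a
configuration choice (`hwe_policy = "exclude"`), not an automatism.
Monomorphic loci get $p = 1$ with a warning.

**Linkage disequilibrium.** Two-locus haplotype frequencies are estimated by
EM over the double-heterozygote phase ambiguity (random union of gametes;
started at linkage equilibrium, stopped at a log-likelihood change below
$10^{-10}$ or 1000 iterations — the likelihood is concave in the single free
haplotype frequency, so the start only affects iteration count). We report
$D = p_{AB} - p_A p_B$, $D' = D/D_{max}$ with the sign-appropriate bound,
and the LOD, the $\log_{10}$ likelihood ratio of the EM optimum against
independence; $LOD > 2$ is classed "moderate", otherwise "weak" linkage.

# Composite risk model and ROC

Flagged markers enter a logistic regression as 0/1 carriage indicators —
never dosages; a multi-locus combination is recoded to a single indicator
that is 1 iff all its risk alleles are carried. Coefficients are
maximum-likelihood (`stats::glm`); a single binary marker's coefficient
equals the log odds ratio of its 2×2 table exactly, which the tests assert
to $10^{-8}$. Complete or quasi-complete separation (a marker with an empty
carrier cell in one outcome group — likely for rare recessive markers at
small $n$) is a hard error by default; an optional ridge fallback
($\lambda = 10^{-4}$, intercept unpenalized, flagged in the output) keeps
the coefficients finite. The end-to-end pipeline and the simulation sweeps
use the ridge fallback, since rare-marker separation is an expected event
across hundreds of replicates. Collinear (aliased) markers are an error;
the pipeline de-duplicates complementary indicators (at a biallelic locus,
dominant carriage of one allele is the complement of the other allele's
recessive homozygote) before fitting, keeping the risk-direction
representative.

The ROC curve is a threshold sweep over the unique score values; ties
produce diagonal segments, so the trapezoidal AUC equals the Mann–Whitney
statistic $U/(n_1 n_0)$ exactly (asserted to $10^{-12}$ against a rank-based
oracle and against pROC). Replication transfer reuses the discovery
coefficients verbatim and recomputes the ROC on the new cohort.

**Gender moderation** fits `outcome ~ marker * sex` and reports the Wald p
of the interaction term, and additionally runs SF+FLINT on the
(marker, male, outcome) 2×2×2 table, so both criteria are always reported
side by side.

# The synthetic cohort generator

No subject-level data accompany the source study, so calibration and
recovery claims rest on a generator that emulates the structure that study
assumes:

* genotypes in Hardy–Weinberg proportions, with optional pairwise LD
  planted at the haplotype level via $D'$;
* a logistic disease model on carriage indicators:
  $\mathrm{logit}\,P(case) = \beta_0 + \sum_l \beta_l c_l +
  \sum_{(l,m)} \gamma_{lm} c_l c_m + \beta_s \cdot male + \ldots$;
* case-control ascertainment by rejection sampling until exactly
  $n_{case}$ cases and $n_{control}$ controls are drawn — simple and exact
  under the model at these sizes;
* optional uniform genotype missingness and a configurable sex ratio.

The *conditional* (stratum-specific) odds ratios are the planted truth, so
the true synergy factor of a configured pair is $e^\gamma$ exactly and SF
recovery is directly testable; marginal single-locus odds ratios are derived
quantities computed by exact summation over the joint carriage strata
(`analytic_effects`).

`paper_like_config()` encodes the study conditions used throughout the
acceptance suite: three main-effect markers with control carriage
frequencies near 0.32 (recessive), 0.38 (dominant) and 0.04 (recessive) and
odds ratios 1.84, 1.80 and 2.93; one epistatic pair of a common (carriage
0.75) and a rare (carriage ≈ 0.07) dominant element with weak mains
(OR 1.1) and $\gamma = \ln 5$; 325 cases / 185 controls; male fraction
0.714; intercept −2.8 giving population prevalence near 0.1. Population
risk-allele frequencies are set slightly *above* the control targets
because ascertainment depletes controls of risk-allele carriers; the
offsets were derived analytically from the model (e.g. for the 0.32 target,
population carriage 0.335), not fitted to simulation output.

Two further fixed conditions are used by the calibration studies: a
two-locus configuration (dominant carriage frequencies 0.3 and 0.2, mains
OR 1.3, intercept −2.2) for SF coverage, type-I error and power; and a
four-locus null configuration (carriage-allele frequencies 0.2–0.5, all
effects zero) for permutation calibration.

What the generator does *not* emulate — population stratification,
relatedness, genotyping error beyond uniform missingness, more than
pairwise LD — bounds what passing tests show: calibration and recovery hold
under a clean logistic penetrance model with HWE genotypes, not necessarily
under confounded real data.

# Problem sizes and reproducibility

The simulation studies run at: 1000 cohorts of 2000/2000 for SF coverage;
1000 cohorts of 325/185 for type-I error; 500 cohorts each at 325/185 and
2000/2000 for power; 200 null cohorts with $R = 200$ permutations for
permutation calibration; 200 study-size cohorts for the AUC range. These
sizes keep Monte-Carlo standard errors small relative to the assertion
bands (e.g. coverage SE ≈ 0.007 at 1000 replicates) while completing in a
few minutes. Every random quantity in the package flows from an explicit
integer seed: simulation from the config seed, permutation from the
`permutation_adjust` seed, and a full pipeline rerun with the same inputs
and seed is byte-identical.

# Known limitations

* The published interaction rows print SF, its CI and $p_{FLINT}$ but not
  the underlying 8-cell tables, so those numbers serve as decision-logic
  fixtures only; they cannot be recomputed from printed data.
* Exact carrier counts behind published frequency tables are recoverable
  only where the rounding is unambiguous; the two reconstructible odds
  ratios (4.17, 0.44) are regression-tested, the others deliberately are
  not.
* The Woolf CI and probability-ordered two-sided conventions are defaults,
  not certainties about the original analyses; both are configurable at
  the function level.
* FLINT conditions on all three two-way margins; like all exact
  conditional tests it is conservative in small supports (a singleton
  support forces $p = 1$).
* No covariate adjustment beyond sex, no continuous phenotypes, no
  multi-allelic loci, no phased haplotypes beyond the two-locus EM.
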