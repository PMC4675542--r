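#' Construct a marker set
#'
#' A named collection of carriage patterns, each recoded to a subject-level
#' 0/1 indicator when entering a composite risk model (a multi-locus
#' combination becomes a single binary marker that is 1 iff all its risk
#' alleles are carried).
#'
#' @param ... Named [carriage_pattern()] / [pattern_element()] objects, or
#'   a single named list of them.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(...) {
  markers <- list(...)
  if (length(markers) == 1L && is.list(markers[[1]]) &&
      !inherits(markers[[1]], c("carriage_pattern", "pattern_element"))) {
    markers <- markers[[1]]
  }
  if (is.null(names(markers)) || any(!nzchar(names(markers))) ||
      anyDuplicated(names(markers))) {
    stop("markers must have unique non-empty names", call. = FALSE)
  }
  markers <- lapply(markers, as_pattern)
  structure(markers, class = "marker_set")
}

# subjects x markers 0/1 matrix (NA where any constituent genotype missing)
marker_matrix <- function(dataset, markers) {
  have <- locus_ids(dataset)
  for (nm in names(markers)) {
    need <- vapply(markers[[nm]]$elements, `[[`, character(1), "locus_id")
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop("marker ", nm, ": locus ", paste(miss, collapse = ","),
           " absent from dataset", call. = FALSE)
    }
  }
  X <- vapply(markers, function(p) pattern_indicator(dataset, p),
              integer(length(dataset$samples)))
  if (length(dataset$samples) == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- names(markers)
  X
}

# IRLS for ridge-penalized logistic regression (intercept unpenalized)
ridge_logistic <- function(X, y, lambda, max_iter = 100L, tol = 1e-10) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(Xi, w * Xi) + pen, crossprod(Xi, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  stats::setNames(beta, colnames(Xi))
}

#' Fit a composite logistic risk model on binary markers
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' marker indicator matrix (listwise complete cases).  Complete separation
#' is detected and raised as an error by default; with
#' `on_separation = "ridge"` a small ridge penalty (`lambda = 1e-4`) is
#' used instead and flagged.
#'
#' @param dataset A [genotype_dataset()].
#' @param markers A [marker_set()].
#' @param on_separation `"error"` (default) or `"ridge"`.
#' @return List of class `composite_model` with `intercept`, `beta`
#'   (named), `wald_p`, `train_auc`, `markers`, `n_used`, `separation`,
#'   `ridged`.
#' @export
fit_composite_logistic <- function(dataset, markers,
                                   on_separation = c("error", "ridge")) {
  on_separation <- match.arg(on_separation)
  if (any(group_sizes(dataset) == 0L)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  X <- marker_matrix(dataset, markers)
  ok <- rowSums(is.na(X)) == 0L
  X <- X[ok, , drop = FALSE]
  y <- dataset$phenotype[ok]
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-12)))
  if (anyNA(stats::coef(fit))) {
    stop("aliased (collinear) markers: ",
         paste(names(markers)[is.na(stats::coef(fit))[-1]],
               collapse = ","),
         "; markers must be linearly independent indicators",
         call. = FALSE)
  }
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 12) &&
    (min(mu) < 1e-8 || max(mu) > 1 - 1e-8)
  ridged <- FALSE
  if (separated) {
    if (on_separation == "error") {
      bad <- names(which(abs(stats::coef(fit)[-1]) > 12))
      stop("complete (or quasi-complete) separation detected",
           if (length(bad)) paste0(" (marker ",
                                   paste(bad, collapse = ","), ")"),
           "; refit with on_separation = \"ridge\" if intended",
           call. = FALSE)
    }
    beta_all <- ridge_logistic(X, y, lambda = 1e-4)
    wald_p <- rep(NA_real_, length(beta_all) - 1L)
    ridged <- TRUE
  } else {
    beta_all <- stats::coef(fit)
    wald_p <- summary(fit)$coefficients[-1, "Pr(>|z|)"]
  }
  scores <- stats::plogis(drop(cbind(1, X) %*% beta_all))
  structure(
    list(intercept = unname(beta_all[1]),
         beta = stats::setNames(unname(beta_all[-1]), colnames(X)),
         wald_p = stats::setNames(unname(wald_p), colnames(X)),
         train_auc = roc_auc(scores, y)$auc,
         markers = markers, n_used = length(y),
         separation = separated, ridged = ridged),
    class = "composite_model"
  )
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("composite logistic model (%d markers, n = %d)%s\n",
              length(x$beta), x$n_used,
              if (x$ridged) " [ridge fallback]" else ""))
  print(data.frame(beta = x$beta, wald_p = x$wald_p))
  cat(sprintf("training AUC: %.3f\n", x$train_auc))
  invisible(x)
}

#' Apply a fitted composite model to a dataset
#'
#' Computes fitted case probabilities on a (possibly new) cohort using the
#' trained coefficients verbatim — no refitting.  Every marker locus must
#' be present in the new dataset.
#'
#' @param model A `composite_model`.
#' @param dataset A [genotype_dataset()].
#' @return Numeric vector of per-subject risk scores (NA where a marker is
#'   incomputable for that subject).
#' @export
apply_model <- function(model, dataset) {
  X <- marker_matrix(dataset, model$markers)
  stats::plogis(model$intercept + drop(X %*% model$beta))
}

#' ROC curve and AUC of a risk score
#'
#' Threshold sweep over the unique score values, from the all-negative to
#' the all-positive operating point; AUC by the trapezoid rule.  Ties in
#' the scores produce diagonal segments, so the AUC equals the
#' Mann-Whitney statistic `U / (n1 * n0)` exactly.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels 0/1 outcome labels.
#' @return List of class `roc_curve` with `points` (data.frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("labels must include both classes", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  fp <- grp_end - tp
  points <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(points$fpr) *
             (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Test gender moderation of a marker effect
#'
#' Fits `outcome ~ marker + sex + marker:sex` by logistic regression and
#' reports the Wald p of the interaction coefficient; additionally runs the
#' SF+FLINT procedure on the (marker, male-sex, outcome) 2x2x2 table so
#' both interaction criteria are reported.
#'
#' @param dataset A [genotype_dataset()] with both sexes present.
#' @param marker A [carriage_pattern()] or [pattern_element()].
#' @return List of class `gender_moderation` with `interaction_beta`,
#'   `interaction_p`, `verdict` (the SF+FLINT `epistasis_verdict`), and
#'   `n_used`.
#' @export
gender_moderation_test <- function(dataset, marker) {
  sex_m <- ifelse(is.na(dataset$sex), NA_integer_,
                  as.integer(dataset$sex == "M"))
  if (length(unique(stats::na.omit(sex_m))) < 2L) {
    stop("both sexes must be present", call. = FALSE)
  }
  m <- pattern_indicator(dataset, as_pattern(marker))
  ok <- !is.na(m) & !is.na(sex_m)
  df <- data.frame(y = dataset$phenotype[ok], m = m[ok], male = sex_m[ok])
  fit <- suppressWarnings(
    stats::glm(y ~ m * male, family = stats::binomial(), data = df))
  cf <- summary(fit)$coefficients
  verdict <- sf_flint_test(dataset, marker, sex_m)
  structure(
    list(interaction_beta = unname(stats::coef(fit)["m:male"]),
         interaction_p = unname(cf["m:male", "Pr(>|z|)"]),
         verdict = verdict, n_used = nrow(df)),
    class = "gender_moderation"
  )
}

#' @export
print.gender_moderation <- function(x, ...) {
  cat(sprintf(
    "gender moderation: interaction beta %.3g (Wald p %.3g); SF+FLINT: %s\n",
    x$interaction_beta, x$interaction_p, x$verdict$call))
  invisible(x)
}
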