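#' Default pipeline configuration
#'
#' Returns the analysis thresholds the pipeline uses unless overridden:
#' HWE retention threshold 0.01 with policy `"flag"` (violating loci are
#' reported but kept; set `"exclude"` to drop them before mining), pattern
#' order cap 2, 100 permutations, significance gates `p_f < 0.01`,
#' `p_perm < 0.05`, CI excluding 1, and FLINT/SF levels 0.05.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    hwe_threshold = 0.01, hwe_policy = "flag",
    max_order = 2L, permutations = 100L,
    p_f_threshold = 0.01, p_perm_threshold = 0.05,
    sf_alpha = 0.05, flint_alpha = 0.05,
    alpha = 0.05, seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key: ", bad[1], call. = FALSE)
  utils::modifyList(cfg, over)
}

hwe_screen <- function(dataset, threshold) {
  rows <- lapply(dataset$loci, function(loc) {
    p_group <- vapply(c(case = 1L, control = 0L), function(ph) {
      d <- allele1_dosage(dataset, loc$id)[dataset$phenotype == ph]
      d <- d[!is.na(d)]
      res <- withCallingHandlers(
        hwe_test(sum(d == 2L), sum(d == 1L), sum(d == 0L)),
        warning = function(w) invokeRestart("muffleWarning"))
      res$p
    }, numeric(1))
    data.frame(locus = loc$id, p_case = p_group[["case"]],
               p_control = p_group[["control"]],
               violates = any(p_group < threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

ld_screen <- function(dataset) {
  ids <- locus_ids(dataset)
  if (length(ids) < 2L) {
    return(data.frame(locusA = character(0), locusB = character(0),
                      D = numeric(0), Dprime = numeric(0),
                      LOD = numeric(0), linkage_class = character(0)))
  }
  cmb <- utils::combn(ids, 2L, simplify = FALSE)
  rows <- lapply(cmb, function(pr) {
    res <- tryCatch(ld_pair(dataset, pr[1], pr[2]), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(locusA = pr[1], locusB = pr[2], D = res$D,
               Dprime = res$Dprime, LOD = res$LOD,
               linkage_class = res$linkage_class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full discovery / replication analysis pipeline
#'
#' Executes, in order: Hardy-Weinberg screen (flag or exclude per config),
#' pairwise LD screen, single-variant carriage scan, allelic-combination
#' mining with family-wise permutation adjustment and the minimality
#' filter, SF+FLINT epistasis testing of every minimal significant
#' two-locus combination, a composite logistic model over the flagged
#' markers with training ROC/AUC, and — when a replication cohort is given
#' — coefficient transfer with replication ROC/AUC plus an independent
#' scan and mining pass on the replication data.
#'
#' @param discovery A [genotype_dataset()] (or a path readable by
#'   [read_genotype_table()] in the native dialect).
#' @param replication Optional second cohort (same forms), or `NULL`.
#' @param config A list from [pipeline_config()], or named overrides.
#' @return List of class `run_report` with per-stage tables (`hwe`, `ld`,
#'   `single_variant`, `combinations`, `epistasis`), the fitted `model`
#'   and `train_roc`, `replication` results, the `config` used, and
#'   accumulated `warnings`.
#' @export
run_pipeline <- function(discovery, replication = NULL,
                         config = pipeline_config()) {
  config <- do.call(pipeline_config, as.list(config))
  as_ds <- function(x) {
    if (inherits(x, "genotype_dataset")) x else read_genotype_table(x)
  }
  discovery <- as_ds(discovery)
  if (!is.null(replication)) replication <- as_ds(replication)
  warn <- character(0)
  note <- function(msg) warn <<- c(warn, msg)

  hwe <- hwe_screen(discovery, config$hwe_threshold)
  ds <- discovery
  if (config$hwe_policy == "exclude" && any(hwe$violates)) {
    drop_ids <- hwe$locus[hwe$violates]
    note(paste("HWE-violating loci excluded:",
               paste(drop_ids, collapse = ",")))
    keep <- !locus_ids(ds) %in% drop_ids
    ds <- genotype_dataset(ds$samples, ds$phenotype, ds$sex,
                           ds$loci[keep],
                           ds$genotypes[, keep, drop = FALSE])
  } else if (any(hwe$violates)) {
    note(paste("HWE violations flagged (kept):",
               paste(hwe$locus[hwe$violates], collapse = ",")))
  }

  ld <- ld_screen(ds)
  sv <- withCallingHandlers(
    single_variant_scan(ds, p_f_threshold = config$p_f_threshold,
                        alpha = config$alpha),
    warning = function(w) { note(conditionMessage(w))
      invokeRestart("muffleWarning") })
  combos <- mine_patterns(
    ds, max_order = config$max_order, R = config$permutations,
    seed = config$seed, p_f_threshold = config$p_f_threshold,
    p_perm_threshold = config$p_perm_threshold, alpha = config$alpha)

  # SF+FLINT on minimal significant two-locus combinations
  records <- attr(combos, "records")
  epi_idx <- which(combos$minimal & combos$significant & combos$order == 2L)
  epi <- do.call(rbind, lapply(epi_idx, function(i) {
    els <- records[[i]]$pattern$elements
    v <- sf_flint_test(ds, els[[1]], els[[2]],
                       sf_alpha = config$sf_alpha,
                       flint_alpha = config$flint_alpha)
    data.frame(pattern = combos$pattern[i],
               factorA = element_label(els[[1]]),
               factorB = element_label(els[[2]]),
               SF = v$synergy$SF, sf_ci_low = v$synergy$ci_low,
               sf_ci_high = v$synergy$ci_high, p_flint = v$flint$p,
               call = v$call, stringsAsFactors = FALSE)
  }))

  # composite model over flagged markers: significant single variants plus
  # minimal significant combinations, each as one binary marker.  At a
  # biallelic locus, dominant carriage of one allele and the recessive
  # homozygote of the other are complementary indicators, so duplicated or
  # complementary markers are dropped (risk-direction representative kept).
  sv_sig <- sv[sv$significant, , drop = FALSE]
  sv_sig <- sv_sig[order(sv_sig$OR < 1, sv_sig$p_f), , drop = FALSE]
  mk <- list()
  seen <- list()
  add_marker <- function(name, pat) {
    ind <- pattern_indicator(ds, pat)
    for (s in seen) {
      same <- !is.na(ind) & !is.na(s)
      if (all(ind[same] == s[same]) || all(ind[same] == 1L - s[same])) {
        return(invisible(FALSE))
      }
    }
    seen[[length(seen) + 1L]] <<- ind
    mk[[name]] <<- pat
    invisible(TRUE)
  }
  for (i in seq_len(nrow(sv_sig))) {
    el <- pattern_element(sv_sig$locus[i], sv_sig$allele[i], sv_sig$mode[i])
    add_marker(element_label(el), carriage_pattern(el))
  }
  for (i in which(combos$minimal & combos$significant & combos$order > 1L)) {
    add_marker(combos$pattern[i], records[[i]]$pattern)
  }
  model <- NULL; train_roc <- NULL
  if (length(mk)) {
    model <- tryCatch(
      fit_composite_logistic(ds, marker_set(mk), on_separation = "ridge"),
      error = function(e) { note(conditionMessage(e)); NULL })
    if (!is.null(model) && model$ridged) {
      note("composite model used the ridge fallback (separation)")
    }
    if (!is.null(model)) {
      train_roc <- roc_auc(apply_model(model, ds), ds$phenotype)
    }
  } else {
    note("no markers passed the gates; composite model skipped")
  }

  repl <- NULL
  if (!is.null(replication)) {
    repl <- list(
      single_variant = withCallingHandlers(
        single_variant_scan(replication,
                            p_f_threshold = config$p_f_threshold,
                            alpha = config$alpha),
        warning = function(w) { note(conditionMessage(w))
          invokeRestart("muffleWarning") }),
      combinations = mine_patterns(
        replication, max_order = config$max_order,
        R = config$permutations, seed = config$seed,
        p_f_threshold = config$p_f_threshold,
        p_perm_threshold = config$p_perm_threshold, alpha = config$alpha)
    )
    if (!is.null(model)) {
      repl$roc <- tryCatch(
        roc_auc(apply_model(model, replication), replication$phenotype),
        error = function(e) { note(conditionMessage(e)); NULL })
    }
  }

  structure(
    list(hwe = hwe, ld = ld, single_variant = sv, combinations = combos,
         epistasis = epi, model = model, train_roc = train_roc,
         replication = repl, config = config,
         version = as.character(utils::packageVersion("epiflint")),
         warnings = warn),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  HWE screen: %d loci, %d flagged\n", nrow(x$hwe),
              sum(x$hwe$violates)))
  cat(sprintf("  single-variant scan: %d elements, %d significant\n",
              nrow(x$single_variant), sum(x$single_variant$significant)))
  cat(sprintf("  combinations: %d patterns, %d significant & minimal\n",
              nrow(x$combinations),
              sum(x$combinations$significant & x$combinations$minimal)))
  if (!is.null(x$epistasis) && nrow(x$epistasis)) {
    cat(sprintf("  epistasis verdicts: %s\n",
                paste(x$epistasis$call, collapse = ", ")))
  }
  if (!is.null(x$model)) {
    cat(sprintf("  composite model: %d markers, training AUC %.3f\n",
                length(x$model$beta), x$model$train_auc))
  }
  if (!is.null(x$replication$roc)) {
    cat(sprintf("  replication AUC: %.3f\n", x$replication$roc$auc))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Stage tables as TSV, the master report (thresholds, seeds, version,
#' model coefficients, AUCs, warnings) as JSON.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wtsv(report$hwe, "hwe")
  wtsv(report$ld, "ld")
  wtsv(report$single_variant, "single_variant")
  wtsv(as.data.frame(report$combinations), "combinations")
  wtsv(report$epistasis, "epistasis")
  if (!is.null(report$replication)) {
    wtsv(report$replication$single_variant, "replication_single_variant")
    wtsv(as.data.frame(report$replication$combinations),
         "replication_combinations")
  }
  if (!is.null(report$train_roc)) wtsv(report$train_roc$points, "roc_train")
  if (!is.null(report$replication$roc)) {
    wtsv(report$replication$roc$points, "roc_replication")
  }
  master <- list(
    version = report$version, config = report$config,
    warnings = report$warnings,
    model = if (!is.null(report$model)) list(
      intercept = report$model$intercept,
      beta = as.list(report$model$beta),
      wald_p = as.list(report$model$wald_p),
      train_auc = report$model$train_auc,
      ridged = report$model$ridged),
    replication_auc = if (!is.null(report$replication$roc))
      report$replication$roc$auc
  )
  mp <- file.path(out_dir, "report.json")
  jsonlite::write_json(master, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, mp))
}
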