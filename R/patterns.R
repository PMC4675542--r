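#' Construct a pattern element
#'
#' The atomic unit of a carriage pattern: carriage of one allele at one
#' locus under either the dominant model (at least one copy) or the
#' recessive-homozygote model (two copies).
#'
#' @param locus_id Locus identifier.
#' @param allele Single-character allele symbol.
#' @param mode `"dominant"` or `"recessive"`.
#' @return An object of class `pattern_element`.
#' @export
pattern_element <- function(locus_id, allele,
                            mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  stopifnot(is.character(locus_id), length(locus_id) == 1L,
            is.character(allele), nchar(allele) == 1L)
  structure(list(locus_id = locus_id, allele = allele, mode = mode),
            class = "pattern_element")
}

#' Construct a carriage pattern
#'
#' A conjunction of pattern elements over distinct loci; a subject carries
#' the pattern iff it carries every element.  Order (number of elements)
#' must be at least 1.
#'
#' @param ... [pattern_element()] objects, or a single list of them.
#' @return An object of class `carriage_pattern`.
#' @export
carriage_pattern <- function(...) {
  els <- list(...)
  if (length(els) == 1L && !inherits(els[[1]], "pattern_element")) {
    els <- els[[1]]
  }
  stopifnot(length(els) >= 1L,
            all(vapply(els, inherits, logical(1), "pattern_element")))
  ids <- vapply(els, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) {
    stop("pattern elements must reference distinct loci", call. = FALSE)
  }
  els <- els[order(ids)]
  structure(list(elements = els), class = "carriage_pattern")
}

pattern_order <- function(pattern) length(pattern$elements)

element_label <- function(e) {
  paste0(e$locus_id, "*", e$allele,
         if (e$mode == "recessive") "(hom)" else "")
}

#' Human-readable pattern label
#' @param pattern A [carriage_pattern()].
#' @return A string, elements joined by `;`.
#' @export
pattern_label <- function(pattern) {
  paste(vapply(pattern$elements, element_label, character(1)),
        collapse = ";")
}

#' @export
print.carriage_pattern <- function(x, ...) {
  cat("carriage_pattern:", pattern_label(x), "\n")
  invisible(x)
}

#' Per-sample carriage of a full pattern
#'
#' Conjunction (logical AND) of the element indicators; a sample missing
#' any constituent genotype is `NA`.
#'
#' @param dataset A [genotype_dataset()].
#' @param pattern A [carriage_pattern()] (a bare [pattern_element()] is
#'   promoted to an order-1 pattern).
#' @return Integer vector (0/1/NA).
#' @export
pattern_indicator <- function(dataset, pattern) {
  pattern <- as_pattern(pattern)
  ind <- vapply(pattern$elements, function(e) carriage_indicator(dataset, e),
                integer(length(dataset$samples)))
  if (length(dataset$samples) == 1L) ind <- matrix(ind, nrow = 1L)
  out <- as.integer(rowSums(ind) == pattern_order(pattern))
  out[rowSums(is.na(ind)) > 0L] <- NA_integer_
  out
}

as_pattern <- function(x) {
  if (inherits(x, "carriage_pattern")) return(x)
  if (inherits(x, "pattern_element")) return(carriage_pattern(x))
  stop("expected a carriage_pattern or pattern_element", call. = FALSE)
}
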