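#' Construct a locus descriptor
#'
#' A locus is a biallelic SNP identified by a short id (typically an rs
#' number) with an ordered pair of single-character allele symbols.
#'
#' @param id Locus identifier, a non-empty string.
#' @param alleles Character vector of two distinct single-character symbols.
#' @return An object of class `locus`.
#' @export
locus <- function(id, alleles) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  alleles <- as.character(alleles)
  if (length(alleles) != 2L || anyDuplicated(alleles) ||
      any(nchar(alleles) != 1L)) {
    stop("alleles must be two distinct single-character symbols", call. = FALSE)
  }
  structure(list(id = id, alleles = alleles), class = "locus")
}

#' Construct a subject-level genotype dataset
#'
#' The central container: samples x biallelic loci with a binary case/control
#' phenotype and an optional sex covariate.  Genotypes are unordered allele
#' pairs stored as two-character strings, canonicalized alphabetically
#' ("TC" becomes "CT"); missing genotypes are `NA`.
#'
#' @param samples Character vector of unique sample ids.
#' @param phenotype Integer vector, 1 = case, 0 = control.
#' @param sex Character vector in `{"M","F",NA}` (recycled `NA` if omitted).
#' @param loci List of [locus()] objects (or a data.frame with columns
#'   `id`, `a1`, `a2`).
#' @param genotypes Character matrix, samples x loci, entries two-character
#'   genotype strings or `NA`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, phenotype, sex = NULL, loci, genotypes) {
  samples <- as.character(samples)
  n <- length(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ",
         samples[anyDuplicated(samples)], call. = FALSE)
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n || anyNA(phenotype) ||
      !all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be 0/1 for every sample", call. = FALSE)
  }
  if (is.null(sex)) sex <- rep(NA_character_, n)
  sex <- as.character(sex)
  sex[!is.na(sex) & !sex %in% c("M", "F")] <- NA_character_
  if (is.data.frame(loci)) {
    loci <- lapply(seq_len(nrow(loci)), function(i) {
      locus(loci$id[i], c(loci$a1[i], loci$a2[i]))
    })
  }
  ids <- vapply(loci, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate locus id", call. = FALSE)
  genotypes <- as.matrix(genotypes)
  if (n == 0L) genotypes <- matrix(character(0), 0L, length(ids))
  stopifnot(nrow(genotypes) == n, ncol(genotypes) == length(ids))
  genotypes <- canonicalize_genotypes(genotypes)
  dimnames(genotypes) <- list(samples, ids)
  for (j in seq_along(loci)) {
    g <- genotypes[, j]
    obs <- unique(unlist(strsplit(g[!is.na(g)], "")))
    bad <- setdiff(obs, loci[[j]]$alleles)
    if (length(bad)) {
      stop("locus ", ids[j], ": allele(s) ", paste(bad, collapse = ","),
           " not in declared allele set", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, phenotype = phenotype, sex = sex,
         loci = loci, genotypes = genotypes),
    class = "genotype_dataset"
  )
}

canonicalize_genotypes <- function(g) {
  miss <- is.na(g) | g %in% c("NN", "--")
  g[miss] <- NA_character_
  ok <- !is.na(g)
  if (any(nchar(g[ok]) != 2L)) {
    stop("genotypes must be two-character strings", call. = FALSE)
  }
  a1 <- substr(g[ok], 1L, 1L)
  a2 <- substr(g[ok], 2L, 2L)
  swap <- a1 > a2
  g[ok] <- ifelse(swap, paste0(a2, a1), paste0(a1, a2))
  g
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d samples (%d cases / %d controls), %d loci\n",
    length(x$samples), sum(x$phenotype == 1L), sum(x$phenotype == 0L),
    length(x$loci)))
  invisible(x)
}

#' Number of cases and controls
#' @param dataset A [genotype_dataset()].
#' @return Named integer vector with elements `n_case`, `n_control`.
#' @export
group_sizes <- function(dataset) {
  c(n_case = sum(dataset$phenotype == 1L),
    n_control = sum(dataset$phenotype == 0L))
}

locus_ids <- function(dataset) {
  vapply(dataset$loci, `[[`, character(1), "id")
}

get_locus <- function(dataset, locus_id) {
  ids <- locus_ids(dataset)
  k <- match(locus_id, ids)
  if (is.na(k)) stop("unknown locus: ", locus_id, call. = FALSE)
  dataset$loci[[k]]
}

#' Read a genotype table
#'
#' Reads subject-level genotypes in one of three dialects:
#' \describe{
#'   \item{`"tsv"`}{native tab-separated dialect: header
#'     `sample_id<TAB>phenotype<TAB>sex<TAB><locus1>...`; phenotype in
#'     `{0,1}`; sex in `{M,F,NA}`; genotypes two characters, `NN` or `--`
#'     meaning missing.}
#'   \item{`"ped"`}{PED/MAP subset: 6 leading PED columns (family id,
#'     individual id, father, mother, sex code 1/2, phenotype code 1/2 with
#'     2 = case), then two allele columns per locus; `0` = missing allele.
#'     `map` must name the companion MAP file (locus ids in column 2).}
#'   \item{`"vcf"`}{biallelic-SNP VCF subset: fixed columns + per-sample GT
#'     fields; phasing separators `|` are treated as `/`.  Phenotypes are not
#'     carried by VCF and must be supplied via `phenotype`.}
#' }
#' Allele sets are inferred from the observed genotypes (and REF/ALT for VCF)
#' unless `loci` declares them.
#'
#' @param path File path (or connection for `"tsv"`).
#' @param dialect One of `"tsv"`, `"ped"`, `"vcf"`.
#' @param map MAP file path (PED dialect only).
#' @param phenotype Named or positional 0/1 vector (VCF dialect only).
#' @param sex Optional sex vector for dialects that do not carry it.
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "ped", "vcf"),
                                map = NULL, phenotype = NULL, sex = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
    tsv = read_native_tsv(path),
    ped = read_ped_map(path, map),
    vcf = read_vcf_biallelic(path, phenotype = phenotype, sex = sex)
  )
}

read_native_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty genotype file", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L ||
      !identical(header[1:3], c("sample_id", "phenotype", "sex"))) {
    stop("native dialect requires header sample_id, phenotype, sex, <loci...>",
         call. = FALSE)
  }
  loc_ids <- header[-(1:3)]
  body <- lines[-1]
  n <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    stop("line ", which(nf != length(header))[1] + 1L,
         ": expected ", length(header), " fields", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  phen_chr <- m[, 2L, drop = TRUE]
  bad <- which(!phen_chr %in% c("0", "1"))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, " (sample ", m[bad[1], 1L],
         "): phenotype must be 0 or 1, got '", phen_chr[bad[1]], "'",
         call. = FALSE)
  }
  geno <- m[, -(1:3), drop = FALSE]
  if (n == 0L) geno <- matrix(character(0), 0L, length(loc_ids))
  geno <- canonicalize_genotypes(geno)
  loci <- infer_loci(loc_ids, geno)
  genotype_dataset(
    samples = m[, 1L], phenotype = as.integer(phen_chr),
    sex = ifelse(m[, 3L] == "NA", NA_character_, m[, 3L]),
    loci = loci, genotypes = geno
  )
}

infer_loci <- function(loc_ids, geno, declared = NULL) {
  lapply(seq_along(loc_ids), function(j) {
    if (!is.null(declared)) return(declared[[j]])
    g <- geno[, j]
    obs <- sort(unique(unlist(strsplit(g[!is.na(g)], ""))))
    if (length(obs) > 2L) {
      stop("locus ", loc_ids[j], ": more than 2 distinct alleles observed (",
           paste(obs, collapse = ","), ")", call. = FALSE)
    }
    # pad unobserved second allele so the locus stays formally biallelic
    if (length(obs) == 0L) obs <- c("A", "B")
    if (length(obs) == 1L) obs <- c(obs, setdiff(c("A", "B", "C"), obs)[1])
    locus(loc_ids[j], obs)
  })
}

read_ped_map <- function(ped_path, map_path) {
  if (is.null(map_path)) stop("PED dialect requires a MAP file", call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 2L) stop("MAP file needs >= 2 columns", call. = FALSE)
  loc_ids <- map[[2]]
  lines <- readLines(ped_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * length(loc_ids)
  nf <- lengths(fields)
  if (any(nf != want)) {
    stop("PED line ", which(nf != want)[1], ": expected ", want,
         " fields, got ", nf[nf != want][1], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  phen_code <- m[, 6L]
  bad <- which(!phen_code %in% c("1", "2"))
  if (length(bad)) {
    stop("PED line ", bad[1], ": phenotype code must be 1 (control) or 2 ",
         "(case), got '", phen_code[bad[1]], "'", call. = FALSE)
  }
  sex <- c("1" = "M", "2" = "F")[m[, 5L]]
  geno <- matrix(NA_character_, nrow(m), length(loc_ids))
  for (j in seq_along(loc_ids)) {
    a1 <- m[, 5L + 2L * j]
    a2 <- m[, 6L + 2L * j]
    ok <- a1 != "0" & a2 != "0"
    geno[ok, j] <- paste0(a1[ok], a2[ok])
  }
  geno <- canonicalize_genotypes(geno)
  genotype_dataset(
    samples = m[, 2L], phenotype = as.integer(phen_code == "2"),
    sex = unname(sex), loci = infer_loci(loc_ids, geno), genotypes = geno
  )
}

read_vcf_biallelic <- function(path, phenotype = NULL, sex = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[[1]], "#CHROM")) {
    stop("not a VCF: missing #CHROM header", call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[[1]]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) stop("VCF has no sample columns", call. = FALSE)
  samples <- header[-(1:9)]
  recs <- strsplit(lines[-1], "\t", fixed = TRUE)
  loci <- list()
  geno_cols <- list()
  for (r in recs) {
    ref <- r[[4]]; alt <- r[[5]]
    if (nchar(ref) != 1L || nchar(alt) != 1L || alt == ".") {
      stop("VCF record ", r[[3]], ": only biallelic SNP records supported",
           call. = FALSE)
    }
    fmt <- strsplit(r[[9]], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("VCF record ", r[[3]], ": no GT field", call. = FALSE)
    gt <- vapply(strsplit(r[-(1:9)], ":", fixed = TRUE),
                 function(f) f[[gt_i]], character(1))
    gt <- gsub("|", "/", gt, fixed = TRUE)
    al <- c(`0` = ref, `1` = alt)
    parts <- strsplit(gt, "/", fixed = TRUE)
    g <- vapply(parts, function(p) {
      if (length(p) != 2L || any(!p %in% c("0", "1"))) return(NA_character_)
      paste0(al[p[1]], al[p[2]])
    }, character(1))
    id <- if (r[[3]] == ".") paste0(r[[1]], ":", r[[2]]) else r[[3]]
    loci[[length(loci) + 1L]] <- locus(id, c(ref, alt))
    geno_cols[[length(geno_cols) + 1L]] <- g
  }
  geno <- do.call(cbind, geno_cols)
  if (is.null(geno)) geno <- matrix(character(0), length(samples), 0L)
  if (is.null(phenotype)) {
    stop("VCF carries no phenotype; supply `phenotype`", call. = FALSE)
  }
  if (!is.null(names(phenotype))) phenotype <- phenotype[samples]
  genotype_dataset(samples, phenotype, sex, loci,
                   canonicalize_genotypes(geno))
}

#' Write a genotype table in the native TSV dialect
#'
#' The output re-reads (via [read_genotype_table()]) to a field-identical
#' dataset.  Missing genotypes are written as `NN`, missing sex as `NA`.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path or connection.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path) {
  ids <- locus_ids(dataset)
  header <- paste(c("sample_id", "phenotype", "sex", ids), collapse = "\t")
  g <- dataset$genotypes
  g[is.na(g)] <- "NN"
  sex <- dataset$sex
  sex[is.na(sex)] <- "NA"
  rows <- if (length(dataset$samples)) {
    apply(cbind(dataset$samples, dataset$phenotype, sex, g), 1L,
          paste, collapse = "\t")
  } else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Per-sample carriage indicator for one pattern element
#'
#' Dominant carriage: 1 iff the genotype contains at least one copy of the
#' element's allele.  Recessive homozygote: 1 iff the genotype is the allele
#' homozygote.  Missing genotypes yield `NA`.
#'
#' @param dataset A [genotype_dataset()].
#' @param element A [pattern_element()].
#' @return Integer vector (0/1/NA), one value per sample.
#' @export
carriage_indicator <- function(dataset, element) {
  loc <- get_locus(dataset, element$locus_id)
  if (!element$allele %in% loc$alleles) {
    stop("allele ", element$allele, " not in allele set of locus ",
         element$locus_id, call. = FALSE)
  }
  g <- dataset$genotypes[, element$locus_id]
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  if (element$mode == "dominant") {
    out[ok] <- as.integer(grepl(element$allele, g[ok], fixed = TRUE))
  } else {
    hom <- strrep(element$allele, 2L)
    out[ok] <- as.integer(g[ok] == hom)
  }
  out
}

#' Reconstruct a carrier count from a published frequency
#'
#' Published association tables print carriage frequencies rounded to two
#' decimals; the underlying carrier count is recovered as
#' `round(freq * n)`, rounding half away from zero.  Used to rebuild
#' 2x2 tables from printed group frequencies as test fixtures.
#'
#' @param freq Printed frequency in `[0, 1]`.
#' @param n Group size (positive integer).
#' @return Integer carrier count.
#' @export
reconstruct_counts <- function(freq, n) {
  if (any(freq < 0 | freq > 1)) {
    stop("freq must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(n > 0))
  # round half away from zero (base round() rounds half to even)
  as.integer(floor(freq * n + 0.5))
}
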