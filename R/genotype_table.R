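#' Genotype table
#'
#' The central genotype container: a set of samples with population labels,
#' an ordered locus map, and one diploid call per sample and locus. Allele
#' calls are integer codes (`NA` = missing); what the codes mean depends on
#' the source format: first-seen coding for PLINK PED input, REF = 0 / ALT = 1
#' for VCF, raw allele sizes for Genepop microsatellites. The missing value is
#' always `NA`, never a valid allele code.
#'
#' @param a1,a2 Integer matrices (samples x loci) holding the two allele
#'   calls of each genotype. Both entries must be `NA` together (a genotype
#'   with one missing allele is treated as missing).
#' @param sample_ids Character vector of unique sample identifiers.
#' @param pop Character vector of population labels, one per sample.
#' @param loci Data frame with columns `name`, `chrom`, `pos` (1-based bp,
#'   `NA` allowed for unmapped microsatellites), `marker_class`
#'   (`"snp"` or `"microsatellite"`). An optional list column `alleles`
#'   stores the source allele labels indexed by code + 1 (used to write
#'   PED/VCF back out).
#'
#' @return An object of class `genotab`.
#' @export
genotab <- function(a1, a2, sample_ids, pop, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers")
  if (nrow(a1) != n || nrow(a2) != n)
    stop("call matrices must have one row per sample")
  if (ncol(a1) != nrow(loci) || ncol(a2) != nrow(loci))
    stop("call matrices must have one column per locus")
  if (length(pop) != n)
    stop("every sample needs a population label")
  stopifnot(all(c("name", "chrom", "pos", "marker_class") %in% names(loci)))
  if (!all(loci$marker_class %in% c("snp", "microsatellite")))
    stop("marker_class must be 'snp' or 'microsatellite'")
  # one-sided missingness is not representable: propagate NA to both alleles
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, loci$name)
  snp <- which(loci$marker_class == "snp")
  if (length(snp)) {
    k <- vapply(snp, function(j) {
      length(unique(c(a1[, j], a2[, j])[!is.na(c(a1[, j], a2[, j]))]))
    }, integer(1))
    if (any(k > 2))
      stop("snp locus with more than two observed alleles: ",
           loci$name[snp[which(k > 2)[1]]])
  }
  structure(
    list(a1 = a1, a2 = a2,
         sample_ids = as.character(sample_ids),
         pop = as.character(pop),
         loci = as.data.frame(loci)),
    class = "genotab")
}

#' @export
print.genotab <- function(x, ...) {
  cat("Genotype table:", length(x$sample_ids), "samples,",
      nrow(x$loci), "loci\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$pop)), table(x$pop)),
            collapse = ", "), "\n")
  cls <- table(x$loci$marker_class)
  cat("  marker classes:",
      paste(sprintf("%s (%d)", names(cls), cls), collapse = ", "), "\n")
  cr <- mean(!is.na(x$a1))
  cat(sprintf("  overall call rate: %.3f\n", cr))
  invisible(x)
}

#' @export
summary.genotab <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Number of samples / loci in a genotype table
#' @param x A `genotab` object.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname n_samples
#' @export
n_loci <- function(x) nrow(x$loci)

#' Subset a genotype table
#'
#' @param x A `genotab`.
#' @param samples Sample indices, logical mask, or identifiers (default all).
#' @param loci Locus indices, logical mask, or names (default all).
#' @return A `genotab` restricted to the selection.
#' @export
subset_genotab <- function(x, samples = NULL, loci = NULL) {
  si <- seq_along(x$sample_ids)
  li <- seq_len(nrow(x$loci))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample identifier")
  }
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, x$loci$name) else li[loci]
    if (anyNA(li)) stop("unknown locus name")
  }
  genotab(x$a1[si, li, drop = FALSE], x$a2[si, li, drop = FALSE],
          x$sample_ids[si], x$pop[si], x$loci[li, , drop = FALSE])
}

#' Restrict a genotype table to one population
#' @param x A `genotab`.
#' @param population Population label.
#' @return A `genotab` with only that population's samples.
#' @export
pop_subset <- function(x, population) {
  if (!population %in% x$pop) stop("no such population: ", population)
  subset_genotab(x, samples = x$pop == population)
}

# heterozygosity indicator matrix (NA where missing)
.het_matrix <- function(x) {
  h <- x$a1 != x$a2
  h
}

# order loci by (chrom, pos); microsatellites without positions keep file order
.sort_loci <- function(x) {
  key <- order(x$loci$chrom, x$loci$pos, na.last = TRUE)
  subset_genotab(x, loci = key)
}
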