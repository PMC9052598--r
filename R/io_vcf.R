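#' Read genotypes or phased haplotypes from a VCF
#'
#' Only the GT field is used and only biallelic records are kept (others are
#' skipped with a message). Allele coding is REF = 0, ALT = 1. With
#' `require_phase = TRUE` the file is interpreted as phased haplotypes: any
#' unphased heterozygote is an error, and the within-sample haplotype order
#' of the GT field is preserved.
#'
#' @param vcf_path Path to a VCF 4.x file (plain text or bgzipped).
#' @param require_phase Return a [haplotab()] of phased haplotypes instead of
#'   a [genotab()]?
#' @param pop Optional named character vector mapping sample id to population
#'   label; unnamed samples get `"pop1"`.
#' @return A [genotab()] or, with `require_phase = TRUE`, a [haplotab()].
#' @export
read_vcf <- function(vcf_path, require_phase = FALSE, pop = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  gt_region <- v@gt
  if (!"FORMAT" %in% colnames(gt_region) ||
      !any(grepl("GT", gt_region[, "FORMAT"])))
    stop("VCF has no GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"]) &
    fix[, "ALT"] != "."
  if (any(!biallelic))
    message("skipped ", sum(!biallelic), " non-biallelic record(s)")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- colnames(gt)
  L <- nrow(gt); n <- length(ids)
  nm <- fix[, "ID"]
  nm[is.na(nm) | nm == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(nm) | nm == "."]
  loci <- data.frame(name = nm, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     marker_class = "snp", stringsAsFactors = FALSE)
  loci$alleles <- Map(c, fix[, "REF"], fix[, "ALT"])
  gt[is.na(gt)] <- "./."
  h1 <- sub("^([0-9.])[|/].*$", "\\1", gt)
  h2 <- sub("^[0-9.][|/]([0-9.]).*$", "\\1", gt)
  phased <- grepl("|", gt, fixed = TRUE)
  a1 <- suppressWarnings(matrix(as.integer(h1), L, n))
  a2 <- suppressWarnings(matrix(as.integer(h2), L, n))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  if (require_phase) {
    het_unphased <- !phased & !miss & a1 != a2
    if (any(het_unphased)) {
      w <- which(het_unphased, arr.ind = TRUE)[1, ]
      stop("unphased heterozygote at locus ", loci$name[w[1]],
           ", sample ", ids[w[2]])
    }
    H <- matrix(NA_integer_, 2 * n, L)
    H[seq(1, 2 * n, by = 2), ] <- t(a1)
    H[seq(2, 2 * n, by = 2), ] <- t(a2)
    return(haplotab(H, ids, loci))
  }
  if (is.null(pop)) popv <- rep("pop1", n)
  else {
    popv <- unname(pop[ids])
    popv[is.na(popv)] <- "pop1"
  }
  genotab(t(a1), t(a2), ids, popv, loci)
}

#' Write a genotype table or haplotype table as a plain-text VCF
#'
#' Minimal GT-only VCF 4.2 writer. A `genotab` is written unphased (`/`),
#' a `haplotab` phased (`|`).
#'
#' @param x A [genotab()] or [haplotab()].
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_vcf <- function(x, path) {
  is_hap <- inherits(x, "haplotab")
  loci <- x$loci
  lab <- loci$alleles
  refalt <- function(j) {
    if (!is.null(lab) && !is.null(lab[[j]]) && length(lab[[j]]) >= 1) {
      r <- lab[[j]][1]
      a <- if (length(lab[[j]]) >= 2) lab[[j]][2] else "."
      c(r, a)
    } else c("A", "C")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  ids <- x$sample_ids
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  n <- length(ids)
  for (j in seq_len(nrow(loci))) {
    ra <- refalt(j)
    if (is_hap) {
      g1 <- x$H[seq(1, 2 * n, by = 2), j]
      g2 <- x$H[seq(2, 2 * n, by = 2), j]
      gt <- paste(ifelse(is.na(g1), ".", g1),
                  ifelse(is.na(g2), ".", g2), sep = "|")
    } else {
      gt <- paste(ifelse(is.na(x$a1[, j]), ".", x$a1[, j]),
                  ifelse(is.na(x$a2[, j]), ".", x$a2[, j]), sep = "/")
    }
    writeLines(paste(c(loci$chrom[j], loci$pos[j], loci$name[j], ra[1], ra[2],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(x)
}
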