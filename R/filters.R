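#' Call-rate and chromosome filters
#'
#' Mirrors the usual SNP-array quality-control sequence: loci failing the
#' locus call-rate threshold are removed first, then samples failing the
#' sample call-rate threshold (computed on the retained loci), and optionally
#' all sex-chromosome loci are dropped. The order matters and is fixed:
#' loci, then samples.
#'
#' @param x A [genotab()].
#' @param locus_call_rate Minimum fraction of samples with a non-missing call
#'   for a locus to be kept (default 0.9).
#' @param sample_call_rate Minimum fraction of retained loci called for a
#'   sample to be kept (default 0.95).
#' @param autosomes_only Drop loci whose chromosome label is one of
#'   X, Y, XY, MT (case-insensitive)? Default `FALSE`.
#' @return The filtered `genotab`, with an attribute `"filter_report"`
#'   (named integer vector of removed locus/sample counts).
#' @export
filter_genotypes <- function(x, locus_call_rate = 0.9,
                             sample_call_rate = 0.95,
                             autosomes_only = FALSE) {
  stopifnot(locus_call_rate >= 0, locus_call_rate <= 1,
            sample_call_rate >= 0, sample_call_rate <= 1)
  sex_chrom <- c("x", "y", "xy", "mt", "m", "chrx", "chry", "chrm")
  n_sex <- 0L
  if (autosomes_only) {
    keep <- !(tolower(as.character(x$loci$chrom)) %in% sex_chrom)
    n_sex <- sum(!keep)
    if (!any(keep)) stop("no autosomal loci left after filtering")
    x <- subset_genotab(x, loci = keep)
  }
  called <- !is.na(x$a1)
  locus_cr <- colMeans(called)
  keep_l <- locus_cr >= locus_call_rate
  n_loci_rm <- sum(!keep_l)
  if (!any(keep_l)) stop("all loci removed by the call-rate filter")
  x <- subset_genotab(x, loci = keep_l)
  sample_cr <- rowMeans(!is.na(x$a1))
  keep_s <- sample_cr >= sample_call_rate
  n_samp_rm <- sum(!keep_s)
  if (!any(keep_s)) stop("all samples removed by the call-rate filter")
  x <- subset_genotab(x, samples = keep_s)
  attr(x, "filter_report") <- c(sex_chromosome_loci = n_sex,
                                low_call_rate_loci = n_loci_rm,
                                low_call_rate_samples = n_samp_rm)
  x
}

#' Flag likely duplicate samples by genotype concordance
#'
#' Pairwise genotype concordance over loci called in both samples; pairs at
#' or above the threshold are flagged. When dropping is requested the
#' later-listed sample of each flagged pair is removed.
#'
#' @param x A [genotab()].
#' @param threshold Concordance at or above which a pair is flagged
#'   (default 0.95).
#' @param drop Remove the later-listed member of each flagged pair?
#' @return If `drop = FALSE`, a data frame of flagged pairs
#'   (`sample1`, `sample2`, `concordance`, `n_shared`); otherwise the pruned
#'   `genotab` with the pair table in attribute `"duplicates"`.
#' @export
find_duplicates <- function(x, threshold = 0.95, drop = FALSE) {
  n <- n_samples(x)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(x$a1[i, ]) & !is.na(x$a1[j, ])
      ns <- sum(ok)
      if (ns == 0) next
      same <- (x$a1[i, ok] == x$a1[j, ok] & x$a2[i, ok] == x$a2[j, ok]) |
              (x$a1[i, ok] == x$a2[j, ok] & x$a2[i, ok] == x$a1[j, ok])
      conc <- mean(same)
      if (conc >= threshold)
        out[[length(out) + 1]] <- data.frame(
          sample1 = x$sample_ids[i], sample2 = x$sample_ids[j],
          concordance = conc, n_shared = ns)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(sample1 = character(), sample2 = character(),
               concordance = numeric(), n_shared = integer())
  if (!drop) return(pairs)
  if (nrow(pairs)) {
    rm_ids <- unique(pairs$sample2)
    message("dropping ", length(rm_ids), " duplicate sample(s): ",
            paste(rm_ids, collapse = ", "))
    x <- subset_genotab(x, samples = !(x$sample_ids %in% rm_ids))
  }
  attr(x, "duplicates") <- pairs
  x
}
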