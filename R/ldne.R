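#' Pairwise LD (r-squared) within a distance window
#'
#' Squared Pearson correlation of 0/1/2 allele dosages between SNP pairs on
#' the same chromosome whose distance falls inside `[min_dist, max_dist]`,
#' using pairwise-complete samples. Loci failing the MAF filter (or
#' monomorphic) are excluded with a message.
#'
#' Run this on one population at a time (subset with [pop_subset()]); LD
#' mixed across populations reflects structure, not drift.
#'
#' @param x A [genotab()] of biallelic SNPs with positions.
#' @param maf Minor allele frequency floor (default 0.05).
#' @param min_dist,max_dist Distance window in bp (defaults 5e4 and 4e6).
#' @return Data frame: `locus1`, `locus2`, `chrom`, `dist_bp`, `r2`, with
#'   attribute `"n_samples"` (samples the table holds).
#' @export
pairwise_r2 <- function(x, maf = 0.05, min_dist = 5e4, max_dist = 4e6) {
  if (any(x$loci$marker_class != "snp"))
    stop("LD analysis needs SNP loci only")
  dos <- x$a1 + x$a2
  p <- colMeans(dos, na.rm = TRUE) / 2
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf
  if (any(!keep))
    message("excluded ", sum(!keep), " locus/loci below MAF ", maf)
  rows <- list()
  for (chr in unique(x$loci$chrom[keep])) {
    jj <- which(keep & x$loci$chrom == chr)
    if (length(jj) < 2) next
    pos <- x$loci$pos[jj]
    r <- suppressWarnings(
      stats::cor(dos[, jj, drop = FALSE], use = "pairwise.complete.obs"))
    dmat <- abs(outer(pos, pos, "-"))
    sel <- which(upper.tri(dmat) & dmat >= min_dist & dmat <= max_dist,
                 arr.ind = TRUE)
    if (!nrow(sel)) next
    rows[[length(rows) + 1]] <- data.frame(
      locus1 = x$loci$name[jj][sel[, 1]],
      locus2 = x$loci$name[jj][sel[, 2]],
      chrom = chr,
      dist_bp = dmat[sel],
      r2 = r[sel]^2)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus1 = character(), locus2 = character(),
               chrom = character(), dist_bp = numeric(), r2 = numeric())
  out <- out[!is.na(out$r2), ]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n_samples(x)
  out
}

# bp -> Morgan map functions and recombination-rate corrections
.map_morgans <- function(bp, map = c("linear"), cm_per_mb = 1) {
  map <- match.arg(map)
  bp * cm_per_mb * 1e-8
}

.recomb_correction <- function(d, correction = c("sved_feldman", "none",
                                                 "haldane", "kosambi")) {
  correction <- match.arg(correction)
  switch(correction,
         none = d,
         sved_feldman = d * (2 - d) / 2,
         haldane = (1 - exp(-2 * d)) / 2,
         kosambi = tanh(2 * d) / 2)
}

#' Historical effective population size from LD decay
#'
#' Bins locus pairs by distance (logarithmically spaced bins over the
#' analysis window), corrects the mean r-squared for finite sample size
#' (`beta = 1/n` for unphased genotype-based r2, `1/(2n)` for phased
#' haplotypes), converts mean distance to Morgans (linear map, default
#' 1 cM/Mb) and applies a recombination-rate correction (Sved-Feldman
#' quadratic by default; none/Haldane/Kosambi available). Each bin then
#' yields `Ne = (1/(4c)) * (1/r2_adj - alpha)` at `t = 1/(2c)` generations
#' ago; bins are reported oldest (smallest distance) to newest.
#'
#' @param pairs A [pairwise_r2()] result.
#' @param n_samples Number of diploid samples behind the r2 values (taken
#'   from `pairs` when omitted).
#' @param n_bins Number of distance bins (default 30).
#' @param alpha Mutation adjustment in Sved's relation: 1 (default, no
#'   mutation) or 2.2.
#' @param correction Recombination-rate correction (see Details).
#' @param cm_per_mb Linear map rate (default 1).
#' @param phased Were r2 values computed from phased haplotypes?
#' @param min_pairs Bins with fewer pairs trigger a warning (default 100).
#' @return Data frame of class `ne_trajectory`: `bin`, `mean_bp`, `c`,
#'   `n_pairs`, `r2`, `r2_adj`, `t_generations`, `Ne` (`NA` and flagged when
#'   the adjusted r2 would give a non-positive Ne), ordered by increasing
#'   distance, i.e. oldest to newest (decreasing t).
#' @export
ne_from_ld <- function(pairs, n_samples = attr(pairs, "n_samples"),
                       n_bins = 30, alpha = 1,
                       correction = c("sved_feldman", "none", "haldane",
                                      "kosambi"),
                       cm_per_mb = 1, phased = FALSE, min_pairs = 100) {
  correction <- match.arg(correction)
  if (!nrow(pairs)) stop("no locus pairs supplied")
  beta <- if (phased) 1 / (2 * n_samples) else 1 / n_samples
  rng <- range(pairs$dist_bp)
  br <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  br[1] <- br[1] - 1; br[n_bins + 1] <- br[n_bins + 1] + 1
  bin <- cut(pairs$dist_bp, breaks = br, labels = FALSE)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, mean_bp = mean(pairs$dist_bp[sel]),
               n_pairs = sum(sel), r2 = mean(pairs$r2[sel]))
  })
  out <- do.call(rbind, rows)
  if (any(out$n_pairs < min_pairs))
    warning(sum(out$n_pairs < min_pairs), " bin(s) hold fewer than ",
            min_pairs, " pairs")
  d <- .map_morgans(out$mean_bp, cm_per_mb = cm_per_mb)
  out$c <- .recomb_correction(d, correction)
  out$r2_adj <- out$r2 - beta
  out$t_generations <- 1 / (2 * out$c)
  ne <- (1 / (4 * out$c)) * (1 / out$r2_adj - alpha)
  bad <- out$r2_adj <= 0 | ne <= 0
  ne[bad] <- NA_real_
  out$Ne <- ne
  out$flagged <- bad
  out <- out[order(out$mean_bp), ]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("LD-based Ne trajectory:", nrow(x), "bins,",
      sum(!is.na(x$Ne)), "with defined Ne\n")
  ok <- !is.na(x$Ne)
  if (any(ok))
    cat(sprintf("  t range %.0f-%.0f generations ago, Ne range %.0f-%.0f\n",
                min(x$t_generations[ok]), max(x$t_generations[ok]),
                min(x$Ne[ok]), max(x$Ne[ok])))
  invisible(x)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  ok <- !is.na(x$Ne)
  plot(x$t_generations[ok], x$Ne[ok], log = "xy", type = "b",
       xlab = "generations ago", ylab = "Ne", ...)
  invisible(x)
}
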