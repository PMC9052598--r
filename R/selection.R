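#' Phased haplotype table
#'
#' Container for phased biallelic haplotypes: a `2n x L` matrix of 0/1 codes
#' (`NA` = missing) with two consecutive rows per sample, a locus map with
#' strictly increasing positions per chromosome, and an ancestral allele per
#' locus.
#'
#' @param H Integer matrix (`2 * samples` rows, loci columns) of 0/1/`NA`.
#' @param sample_ids Character vector of sample identifiers.
#' @param loci Locus data frame as in [genotab()].
#' @param ancestral Integer vector of ancestral allele codes per locus
#'   (default all 0, the VCF REF convention).
#' @return An object of class `haplotab`.
#' @export
haplotab <- function(H, sample_ids, loci, ancestral = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) != 2 * length(sample_ids))
    stop("haplotype count must be twice the sample count")
  if (ncol(H) != nrow(loci)) stop("one column per locus required")
  for (chr in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == chr]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  if (is.null(ancestral)) ancestral <- rep(0L, nrow(loci))
  stopifnot(length(ancestral) == nrow(loci))
  structure(list(H = H, sample_ids = as.character(sample_ids),
                 loci = as.data.frame(loci),
                 ancestral = as.integer(ancestral)),
            class = "haplotab")
}

#' @export
print.haplotab <- function(x, ...) {
  cat("Haplotype table:", nrow(x$H), "haplotypes (",
      length(x$sample_ids), "samples ),", nrow(x$loci), "loci\n")
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotypes
#'
#' @param x A [haplotab()].
#' @param pop Population labels per sample (default one population).
#' @return A [genotab()].
#' @export
haplo_to_geno <- function(x, pop = NULL) {
  n <- length(x$sample_ids)
  if (is.null(pop)) pop <- rep("pop1", n)
  genotab(x$H[seq(1, 2 * n, 2), , drop = FALSE],
          x$H[seq(2, 2 * n, 2), , drop = FALSE],
          x$sample_ids, pop, x$loci)
}

#' Extended haplotype homozygosity around a core allele
#'
#' EHH at a marker x is the probability that two randomly drawn carriers of
#' the core allele are identical over all markers between the core and x:
#' `EHH(x) = sum_groups C(n_g, 2) / C(n_core, 2)`, with groups the distinct
#' haplotype strings from the core to x. EHH at the core is 1 and, on
#' complete data, never increases with distance. A haplotype with a missing
#' call is dropped from the computation (numerator and denominator) from
#' that marker outward on that side.
#'
#' @param x A [haplotab()].
#' @param core Locus index or name of the core marker.
#' @param core_allele Allele (0 or 1) defining the carrier set.
#' @param side `"both"` (default), `"left"` or `"right"`.
#' @param limit Stop walking outward once EHH falls below this value (the
#'   first sub-limit point is still recorded). Default 0: the full curve.
#' @return Data frame with columns `pos`, `side`, `ehh`, `n_haps` (carriers
#'   still in the computation). Attribute `"defined"` is `FALSE` when fewer
#'   than two haplotypes carry the core allele.
#' @export
ehh <- function(x, core, core_allele, side = c("both", "left", "right"),
                limit = 0) {
  side <- match.arg(side)
  j0 <- if (is.character(core)) match(core, x$loci$name) else core
  if (is.na(j0) || j0 < 1 || j0 > nrow(x$loci)) stop("bad core locus")
  chr <- x$loci$chrom[j0]
  jj <- which(x$loci$chrom == chr)
  carriers <- which(!is.na(x$H[, j0]) & x$H[, j0] == core_allele)
  if (length(carriers) < 2) {
    out <- data.frame(pos = x$loci$pos[j0], side = "core", ehh = NA_real_,
                      n_haps = length(carriers))
    attr(out, "defined") <- FALSE
    return(out)
  }
  Hc <- x$H[carriers, , drop = FALSE]
  walk <- function(idx_seq, side_label) {
    grp <- rep(1L, length(carriers))
    alive <- rep(TRUE, length(carriers))
    np <- length(idx_seq)
    pos_v <- numeric(np); ehh_v <- numeric(np); nh_v <- integer(np)
    used <- 0L
    for (j in idx_seq) {
      al <- Hc[, j]
      alive <- alive & !is.na(al)
      nh <- sum(alive)
      if (nh < 2) break
      key <- grp[alive] * 2L + al[alive]
      grp[alive] <- match(key, unique(key))
      sizes <- tabulate(grp[alive])
      val <- sum(sizes * (sizes - 1)) / (nh * (nh - 1))
      used <- used + 1L
      pos_v[used] <- x$loci$pos[j]; ehh_v[used] <- val; nh_v[used] <- nh
      if (val < limit) break
    }
    idx <- seq_len(used)
    data.frame(pos = pos_v[idx], side = rep(side_label, used),
               ehh = ehh_v[idx], n_haps = nh_v[idx])
  }
  core_row <- data.frame(pos = x$loci$pos[j0], side = "core", ehh = 1,
                         n_haps = length(carriers))
  left <- if (side %in% c("both", "left") && j0 > min(jj))
    walk(jj[jj < j0][order(jj[jj < j0], decreasing = TRUE)], "left")
  else NULL
  right <- if (side %in% c("both", "right") && j0 < max(jj))
    walk(jj[jj > j0], "right")
  else NULL
  if (!is.null(left) && nrow(left))
    left <- left[rev(seq_len(nrow(left))), , drop = FALSE]
  out <- rbind(left, core_row, right)
  rownames(out) <- NULL
  attr(out, "defined") <- TRUE
  out
}

#' Integrated EHH
#'
#' Trapezoidal integral of the EHH curve over physical distance on each side
#' of the core. Integration stops at the first marker where EHH falls below
#' `truncation` (that final trapezoid is included); a side whose curve never
#' falls below the threshold before the data edge is integrated to the edge
#' and flagged.
#'
#' @param curve An [ehh()] result.
#' @param truncation EHH cutoff (default 0.05).
#' @return List: `ihh` (bp x EHH units, both sides summed), `left`, `right`
#'   (per-side contributions), `edge` (`TRUE` when either side hit the data
#'   edge above the cutoff).
#' @export
ihh <- function(curve, truncation = 0.05) {
  if (!isTRUE(attr(curve, "defined")))
    return(list(ihh = NA_real_, left = NA_real_, right = NA_real_,
                edge = NA))
  core_pos <- curve$pos[curve$side == "core"]
  one_side <- function(side_label) {
    sub <- curve[curve$side == side_label, ]
    if (!nrow(sub)) return(list(val = 0, edge = FALSE))
    ord <- order(abs(sub$pos - core_pos))
    pos <- c(core_pos, sub$pos[ord])
    e <- c(1, sub$ehh[ord])
    below <- which(e < truncation)
    stop_at <- if (length(below)) below[1] else length(e)
    seg <- seq_len(stop_at)
    val <- sum(diff(abs(pos[seg] - core_pos)) *
                 (utils::head(e[seg], -1) + utils::tail(e[seg], -1)) / 2)
    list(val = val, edge = !length(below))
  }
  l <- one_side("left"); r <- one_side("right")
  list(ihh = l$val + r$val, left = l$val, right = r$val,
       edge = l$edge || r$edge)
}

#' Integrated haplotype score scan
#'
#' For every locus with derived-allele frequency inside `[maf, 1 - maf]`,
#' computes the integrated EHH of the ancestral-allele carriers (`iHH_A`)
#' and derived-allele carriers (`iHH_D`), the unstandardised score
#' `ln(iHH_A / iHH_D)`, and the iHS standardised to mean 0 / sd 1 within
#' derived-allele-frequency bins (equal-width bins on `[0, 1]`). Loci where
#' either iHH is zero or undefined are flagged and excluded from
#' standardisation; loci in bins with fewer than `min_bin` markers are
#' standardised but flagged.
#'
#' @param x A [haplotab()] with ancestral alleles assigned.
#' @param maf Derived-frequency window half-width (default 0.05).
#' @param n_bins Number of frequency bins (default 20).
#' @param truncation EHH integration cutoff (default 0.05).
#' @param min_bin Minimum markers per bin (default 10).
#' @param threshold |iHS| above which a locus is a candidate (default 4).
#' @return Data frame of class `ihs_result`: `locus`, `chrom`, `pos`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `uihs`, `bin`, `ihs`, `candidate`,
#'   and flags `edge`, `small_bin`, `excluded`.
#' @export
ihs_scan <- function(x, maf = 0.05, n_bins = 20, truncation = 0.05,
                     min_bin = 10, threshold = 4) {
  L <- nrow(x$loci)
  anc <- x$ancestral
  dfreq <- vapply(seq_len(L), function(j) {
    v <- x$H[, j]; v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v != anc[j])
  }, numeric(1))
  use <- which(!is.na(dfreq) & dfreq >= maf & dfreq <= 1 - maf)
  rows <- lapply(use, function(j) {
    der <- 1L - anc[j]
    ca <- ihh(ehh(x, j, anc[j], limit = truncation), truncation)
    cd <- ihh(ehh(x, j, der, limit = truncation), truncation)
    data.frame(locus = x$loci$name[j], chrom = x$loci$chrom[j],
               pos = x$loci$pos[j], derived_freq = dfreq[j],
               ihh_a = ca$ihh, ihh_d = cd$ihh,
               edge = isTRUE(ca$edge) || isTRUE(cd$edge))
  })
  if (!length(rows))
    stop("no locus passes the derived-allele-frequency window")
  out <- do.call(rbind, rows)
  out$uihs <- ifelse(!is.na(out$ihh_a) & !is.na(out$ihh_d) &
                       out$ihh_a > 0 & out$ihh_d > 0,
                     log(out$ihh_a / out$ihh_d), NA_real_)
  out$excluded <- is.na(out$uihs)
  out$bin <- pmin(pmax(ceiling(out$derived_freq * n_bins), 1L), n_bins)
  out$ihs <- NA_real_
  out$small_bin <- FALSE
  for (b in unique(out$bin)) {
    sel <- out$bin == b & !out$excluded
    if (!any(sel)) next
    m <- mean(out$uihs[sel]); s <- stats::sd(out$uihs[sel])
    out$small_bin[out$bin == b] <- sum(sel) < min_bin
    out$ihs[sel] <- if (!is.na(s) && s > 0) (out$uihs[sel] - m) / s
                    else 0
  }
  out$candidate <- !is.na(out$ihs) & abs(out$ihs) >= threshold
  rownames(out) <- NULL
  class(out) <- c("ihs_result", "data.frame")
  out
}

#' Merge candidate iHS loci into regions
#'
#' Contiguous candidate loci (|iHS| at or above the threshold) within
#' `merge_kb` of each other are merged into candidate regions.
#'
#' @param ihs An [ihs_scan()] result.
#' @param threshold |iHS| cutoff (default 4).
#' @param merge_kb Merge window in kb (default 500).
#' @return Data frame: `chrom`, `start_bp`, `end_bp`, `n_snps`, `max_ihs`.
#' @export
candidate_regions <- function(ihs, threshold = 4, merge_kb = 500) {
  hits <- ihs[!is.na(ihs$ihs) & abs(ihs$ihs) >= threshold, ]
  if (!nrow(hits))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      max_ihs = numeric()))
  hits <- hits[order(hits$chrom, hits$pos), ]
  gap <- merge_kb * 1000
  grp <- cumsum(c(TRUE, diff(hits$pos) > gap |
                    hits$chrom[-1] != hits$chrom[-nrow(hits)]))
  rows <- lapply(split(hits, grp), function(h)
    data.frame(chrom = h$chrom[1], start_bp = min(h$pos),
               end_bp = max(h$pos), n_snps = nrow(h),
               max_ihs = h$ihs[which.max(abs(h$ihs))]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
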