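#' Call runs of homozygosity
#'
#' Per sample and chromosome, finds all maximal stretches of consecutive SNP
#' loci that contain at most `max_het` heterozygous and at most `max_missing`
#' missing calls, then trims each stretch so both endpoints are homozygous
#' non-missing calls, and keeps those with at least `min_snps` homozygous
#' calls spanning at least `min_length_bp`. Maximality means no kept run can
#' be extended in either direction without violating a constraint. When two
#' maximal candidate windows overlap (possible only through the placement of
#' missing calls), the longer one is kept (ties: the left-most), so segments
#' of one sample on one chromosome never overlap.
#'
#' @param x A [genotab()] of SNP loci with positions, sorted by
#'   (chromosome, position).
#' @param min_length_bp Minimum span in bp (default 1e6).
#' @param min_snps Minimum number of homozygous SNPs in a run (default 25).
#' @param max_missing Maximum missing calls tolerated inside a run
#'   (default 5); missing calls count toward neither `min_snps` nor the
#'   endpoints.
#' @param max_het Maximum heterozygous calls tolerated inside a run
#'   (default 0).
#' @param max_gap Optional maximum inter-SNP gap in bp; runs are broken at
#'   larger gaps (default `NULL`, no gap constraint).
#' @return Data frame of class `roh_set`: columns `sample`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_missing`, `length_bp`
#'   (`end - start + 1`). Attributes: `samples` (all sample ids, including
#'   those without segments), `pop` (their population labels).
#' @export
call_roh <- function(x, min_length_bp = 1e6, min_snps = 25,
                     max_missing = 5, max_het = 0, max_gap = NULL) {
  if (any(x$loci$marker_class != "snp"))
    stop("ROH calling needs SNP loci only")
  if (anyNA(x$loci$pos)) stop("ROH calling needs locus positions")
  ord <- order(x$loci$chrom, x$loci$pos)
  if (!identical(ord, seq_len(n_loci(x))))
    stop("loci must be sorted by (chromosome, position)")
  segs <- list()
  for (chr in unique(x$loci$chrom)) {
    jj <- which(x$loci$chrom == chr)
    pos <- x$loci$pos[jj]
    blocks <- list(seq_along(jj))
    if (!is.null(max_gap) && length(jj) > 1) {
      cutp <- which(diff(pos) > max_gap)
      blocks <- split(seq_along(jj),
                      findInterval(seq_along(jj), cutp + 1))
    }
    for (i in seq_len(n_samples(x))) {
      g1 <- x$a1[i, jj]; g2 <- x$a2[i, jj]
      state <- ifelse(is.na(g1), 2L, ifelse(g1 != g2, 1L, 0L))
      for (bl in blocks) {
        w <- .maximal_windows(state[bl], max_het, max_missing)
        if (!nrow(w)) next
        w$from <- bl[w$from]; w$to <- bl[w$to]
        keep <- .trim_filter_windows(w, state, pos, min_snps, min_length_bp)
        if (!nrow(keep)) next
        keep$sample <- x$sample_ids[i]
        keep$chrom <- chr
        segs[[length(segs) + 1]] <- keep
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(from = integer(), to = integer(), n_snps = integer(),
               n_missing = integer(), sample = character(),
               chrom = character())
  out <- data.frame(sample = out$sample, chrom = out$chrom,
                    start_bp = if (nrow(out)) out$start_bp else integer(),
                    end_bp = if (nrow(out)) out$end_bp else integer(),
                    n_snps = out$n_snps, n_missing = out$n_missing,
                    stringsAsFactors = FALSE)
  out$length_bp <- out$end_bp - out$start_bp + 1
  rownames(out) <- NULL
  structure(out, samples = x$sample_ids,
            pop = stats::setNames(x$pop, x$sample_ids),
            class = c("roh_set", "data.frame"))
}

# maximal windows over a state vector (0 hom, 1 het, 2 missing) with
# at most H hets and K missings; two-pointer, O(L)
.maximal_windows <- function(state, H, K) {
  L <- length(state)
  from <- integer(0); to <- integer(0)
  e <- 0L; nh <- 0L; nm <- 0L
  last_end <- 0L
  for (s in seq_len(L)) {
    if (e < s) { e <- s - 1L; nh <- 0L; nm <- 0L }
    repeat {
      if (e >= L) break
      st <- state[e + 1L]
      nh2 <- nh + (st == 1L); nm2 <- nm + (st == 2L)
      if (nh2 > H || nm2 > K) break
      e <- e + 1L; nh <- nh2; nm <- nm2
    }
    if (e >= s && e > last_end) {   # maximal: strictly longer reach
      from <- c(from, s); to <- c(to, e)
      last_end <- e
    }
    st <- state[s]
    nh <- nh - (st == 1L); nm <- nm - (st == 2L)
  }
  data.frame(from = from, to = to)
}

# trim windows to homozygous endpoints, enforce min_snps / min_length,
# drop contained windows, resolve overlaps by keeping the longest
.trim_filter_windows <- function(w, state, pos, min_snps, min_length_bp) {
  res <- list()
  for (k in seq_len(nrow(w))) {
    a <- w$from[k]; b <- w$to[k]
    while (a <= b && state[a] != 0L) a <- a + 1L
    while (b >= a && state[b] != 0L) b <- b - 1L
    if (a > b) next
    nh <- sum(state[a:b] == 0L)
    nm <- sum(state[a:b] == 2L)
    span <- pos[b] - pos[a] + 1
    if (nh < min_snps || span < min_length_bp) next
    res[[length(res) + 1]] <- data.frame(
      from = a, to = b, start_bp = pos[a], end_bp = pos[b],
      n_snps = nh, n_missing = nm)
  }
  if (!length(res)) return(data.frame())
  out <- unique(do.call(rbind, res))
  # drop windows contained in another
  keep <- rep(TRUE, nrow(out))
  for (k in seq_len(nrow(out))) {
    for (m in seq_len(nrow(out))) {
      if (m != k && keep[m] &&
          out$from[m] <= out$from[k] && out$to[m] >= out$to[k] &&
          (out$from[m] < out$from[k] || out$to[m] > out$to[k]))
        keep[k] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  # resolve remaining overlaps: longest first (ties -> left-most)
  out <- out[order(-(out$to - out$from), out$from), , drop = FALSE]
  chosen <- list()
  for (k in seq_len(nrow(out))) {
    ov <- vapply(chosen, function(cs)
      out$from[k] <= cs$to && out$to[k] >= cs$from, logical(1))
    if (!any(ov)) chosen[[length(chosen) + 1]] <- out[k, ]
  }
  out <- do.call(rbind, chosen)
  out[order(out$from), , drop = FALSE]
}

#' Classify ROH segments by length
#'
#' Left-closed length classes in Mb; defaults are short `[1.0, 2.5)`,
#' medium `[2.5, 5.0)` and long `[5.0, Inf)`.
#'
#' @param roh A [call_roh()] result.
#' @param bounds Strictly increasing inner class boundaries in bp
#'   (default `c(2.5e6, 5e6)`).
#' @param labels Class labels (one more than `bounds`).
#' @return The `roh_set` with an added `length_class` factor column.
#' @export
classify_roh <- function(roh, bounds = c(2.5e6, 5e6),
                         labels = c("short", "medium", "long")) {
  stopifnot(all(diff(bounds) > 0), length(labels) == length(bounds) + 1)
  roh$length_class <- cut(roh$length_bp, breaks = c(-Inf, bounds, Inf),
                          labels = labels, right = FALSE)
  roh
}

#' Per-sample and per-population ROH summaries
#'
#' Counts and mean lengths of ROH per length class.
#'
#' @param roh A classified [call_roh()] result (see [classify_roh()]).
#' @param by `"sample"` or `"population"`.
#' @return Data frame of counts and mean lengths (Mb) per class.
#' @export
roh_summary <- function(roh, by = c("population", "sample")) {
  by <- match.arg(by)
  if (is.null(roh$length_class)) roh <- classify_roh(roh)
  pop <- attr(roh, "pop")
  key <- if (by == "sample") roh$sample else unname(pop[roh$sample])
  cls <- levels(roh$length_class)
  groups <- if (by == "sample") attr(roh, "samples") else unique(pop)
  rows <- lapply(groups, function(g) {
    sel <- key == g
    # per-sample means within populations need per-sample counts first
    if (by == "population") {
      smp <- names(pop)[pop == g]
      cnt_all <- vapply(smp, function(s) sum(roh$sample == s), numeric(1))
      cnts <- vapply(cls, function(cl) mean(vapply(smp, function(s)
        sum(roh$sample == s & roh$length_class == cl), numeric(1))),
        numeric(1))
      data.frame(group = g, n_samples = length(smp),
                 mean_n_all = mean(cnt_all),
                 t(stats::setNames(cnts, paste0("mean_n_", cls))),
                 mean_len_all_mb = mean(roh$length_bp[sel]) / 1e6,
                 t(stats::setNames(vapply(cls, function(cl)
                   mean(roh$length_bp[sel & roh$length_class == cl]) / 1e6,
                   numeric(1)), paste0("mean_len_", cls, "_mb"))))
    } else {
      data.frame(group = g, n_all = sum(sel),
                 t(stats::setNames(vapply(cls, function(cl)
                   sum(sel & roh$length_class == cl), numeric(1)),
                   paste0("n_", cls))),
                 mean_len_all_mb = mean(roh$length_bp[sel]) / 1e6)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` is the fraction of the autosomal genome covered by an
#' individual's ROH. The default autosome length is the Sscrofa11.1 value
#' 2,330,828,850 bp.
#'
#' @param roh A [call_roh()] result.
#' @param autosome_length_bp Total autosome length (default 2,330,828,850).
#' @param by_class Also report per-length-class F_ROH (requires
#'   [classify_roh()] first, or uses the default classes)?
#' @return Data frame with one row per sample (samples with no segments get
#'   0): `sample`, `pop`, `F_ROH`, and with `by_class`, `F_ROH_<class>`
#'   columns which sum to `F_ROH`.
#' @export
f_roh <- function(roh, autosome_length_bp = 2330828850, by_class = FALSE) {
  stopifnot(autosome_length_bp > 0)
  samples <- attr(roh, "samples")
  pop <- attr(roh, "pop")
  tot <- vapply(samples, function(s)
    sum(roh$length_bp[roh$sample == s]), numeric(1))
  out <- data.frame(sample = samples, pop = unname(pop[samples]),
                    F_ROH = tot / autosome_length_bp,
                    stringsAsFactors = FALSE)
  if (by_class) {
    if (is.null(roh$length_class)) roh <- classify_roh(roh)
    for (cl in levels(roh$length_class)) {
      out[[paste0("F_ROH_", cl)]] <- vapply(samples, function(s)
        sum(roh$length_bp[roh$sample == s & roh$length_class == cl]),
        numeric(1)) / autosome_length_bp
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-SNP ROH incidence within populations
#'
#' For every SNP and population, the fraction of the population's
#' individuals whose ROH cover the SNP (the Manhattan-plot quantity behind
#' ROH islands).
#'
#' @param roh A [call_roh()] result.
#' @param x The [genotab()] the ROH were called from (provides the SNP map).
#' @return Data frame: `pop`, `chrom`, `pos`, `locus`, `incidence`.
#' @export
roh_incidence <- function(roh, x) {
  pop <- attr(roh, "pop")
  pops <- unique(unname(pop))
  rows <- list()
  for (p in pops) {
    smp <- names(pop)[pop == p]
    inc <- numeric(n_loci(x))
    for (s in smp) {
      seg <- roh[roh$sample == s, ]
      if (!nrow(seg)) next
      for (k in seq_len(nrow(seg))) {
        covered <- x$loci$chrom == seg$chrom[k] &
          x$loci$pos >= seg$start_bp[k] & x$loci$pos <= seg$end_bp[k]
        inc <- inc + covered
      }
    }
    rows[[p]] <- data.frame(pop = p, chrom = x$loci$chrom,
                            pos = x$loci$pos, locus = x$loci$name,
                            incidence = inc / length(smp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect ROH islands
#'
#' Within each population, islands are maximal stretches of consecutive SNPs
#' whose ROH incidence (fraction of individuals covered, see
#' [roh_incidence()]) is at or above `threshold`.
#'
#' @param roh A [call_roh()] result.
#' @param x The [genotab()] the ROH were called from.
#' @param threshold Minimum incidence (default 0.5).
#' @param min_pop_size Populations smaller than this trigger a warning
#'   (default 5).
#' @return Data frame: `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `peak_incidence`, `mean_incidence`.
#' @export
roh_islands <- function(roh, x, threshold = 0.5, min_pop_size = 5) {
  pop <- attr(roh, "pop")
  small <- names(which(table(unname(pop)) < min_pop_size))
  if (length(small))
    warning("population(s) below ", min_pop_size, " individuals: ",
            paste(small, collapse = ", "))
  inc <- roh_incidence(roh, x)
  rows <- list()
  for (p in unique(inc$pop)) {
    for (chr in unique(x$loci$chrom)) {
      sub <- inc[inc$pop == p & inc$chrom == chr, ]
      if (!nrow(sub)) next
      sub <- sub[order(sub$pos), ]
      hit <- sub$incidence >= threshold
      if (!any(hit)) next
      runs <- rle(hit)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      for (k in which(runs$values)) {
        idx <- starts[k]:ends[k]
        rows[[length(rows) + 1]] <- data.frame(
          population = p, chrom = chr,
          start_bp = sub$pos[idx[1]], end_bp = sub$pos[idx[length(idx)]],
          n_snps = length(idx),
          peak_incidence = max(sub$incidence[idx]),
          mean_incidence = mean(sub$incidence[idx]))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(), n_snps = integer(),
               peak_incidence = numeric(), mean_incidence = numeric())
  rownames(out) <- NULL
  out
}
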