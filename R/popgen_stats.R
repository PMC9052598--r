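# Shared helper: per-population, per-locus allele counts.
# Returns list over populations of lists over loci of named integer vectors
# (names = allele codes, values = allele-copy counts among typed genotypes).
.allele_counts <- function(x) {
  pops <- unique(x$pop)
  L <- n_loci(x)
  out <- vector("list", length(pops))
  names(out) <- pops
  for (p in pops) {
    rows <- x$pop == p
    cnt <- vector("list", L)
    for (j in seq_len(L)) {
      v <- c(x$a1[rows, j], x$a2[rows, j])
      v <- v[!is.na(v)]
      cnt[[j]] <- if (length(v)) table(v) else table(integer(0))
    }
    names(cnt) <- x$loci$name
    out[[p]] <- cnt
  }
  out
}

#' Per-locus, per-population diversity statistics
#'
#' For every (population, locus) pair: sample size, observed and expected
#' heterozygosity, allele counts, effective allele number, polymorphism
#' information content and a null-allele frequency estimate.
#'
#' Expected heterozygosity is `1 - sum(p^2)`; the unbiased form multiplies by
#' `2n / (2n - 1)`. PIC and the effective allele number use the plain
#' frequency-based definitions:
#' `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2` and `N_AE = 1 / sum(p^2)`.
#' The default null-allele estimator is Brookfield's first,
#' `(He - Ho) / (1 + He)`; `"chakraborty"` gives `(He - Ho) / (He + Ho)`.
#'
#' @param x A [genotab()].
#' @param unbiased Also report the small-sample corrected expected
#'   heterozygosity (default `TRUE`; the biased form is always reported too).
#' @param null_estimator `"brookfield"` (default) or `"chakraborty"`.
#' @return Data frame with one row per (population, locus): `pop`, `locus`,
#'   `marker_class`, `n_typed`, `n_alleles`, `n_eff`, `H_obs`, `H_exp`,
#'   `H_exp_unbiased`, `PIC`, `null_freq`, `polymorphic`.
#' @export
locus_stats <- function(x, unbiased = TRUE,
                        null_estimator = c("brookfield", "chakraborty")) {
  null_estimator <- match.arg(null_estimator)
  counts <- .allele_counts(x)
  rows <- list()
  for (p in names(counts)) {
    prow <- x$pop == p
    for (j in seq_len(n_loci(x))) {
      cnt <- counts[[p]][[j]]
      nc <- sum(cnt)                      # allele copies
      n_typed <- nc / 2
      if (nc == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          pop = p, locus = x$loci$name[j],
          marker_class = x$loci$marker_class[j],
          n_typed = 0L, n_alleles = 0L, n_eff = NA_real_,
          H_obs = NA_real_, H_exp = NA_real_, H_exp_unbiased = NA_real_,
          PIC = NA_real_, null_freq = NA_real_, polymorphic = NA)
        next
      }
      pfreq <- as.numeric(cnt) / nc
      sp2 <- sum(pfreq^2)
      He <- 1 - sp2
      He_u <- He * nc / (nc - 1)
      het <- x$a1[prow, j] != x$a2[prow, j]
      Ho <- mean(het, na.rm = TRUE)
      pic <- He - sum((outer(pfreq^2, pfreq^2))[lower.tri(diag(length(pfreq)))] * 2)
      nf <- if (null_estimator == "brookfield") (He - Ho) / (1 + He)
            else if (He + Ho > 0) (He - Ho) / (He + Ho) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, locus = x$loci$name[j],
        marker_class = x$loci$marker_class[j],
        n_typed = as.integer(n_typed), n_alleles = length(pfreq),
        n_eff = 1 / sp2, H_obs = Ho, H_exp = He,
        H_exp_unbiased = if (nc > 1) He_u else NA_real_,
        PIC = pic, null_freq = nf,
        polymorphic = length(pfreq) >= 2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-population summary statistics
#'
#' Averages the per-locus statistics per population and adds the
#' multi-population quantities: private alleles (alleles observed in exactly
#' one population), their mean within-population frequency (Pa), the
#' percentage of polymorphic loci, nucleotide diversity and the mean major
#' allele frequency.
#'
#' Nucleotide diversity per locus is the probability that two distinct
#' sampled allele copies differ: `1 - sum(n_a * (n_a - 1)) / (n * (n - 1))`
#' with `n_a` the allele-copy counts and `n` their total; the reported value
#' is its mean over typed loci.
#'
#' @param x A [genotab()] with at least two populations (with a single
#'   population the private-allele fields are `NA` with a warning).
#' @param stats Optional precomputed [locus_stats()] table.
#' @return Data frame with one row per population: `pop`, `n`, `mean_H_obs`,
#'   `mean_H_exp`, `mean_H_exp_unbiased`, `mean_PIC`, `mean_n_alleles`,
#'   `mean_n_eff`, `mean_null_freq`, `private_alleles`, `private_mean_freq`,
#'   `pct_polymorphic`, `pi`, `major_freq`.
#' @export
pop_summary <- function(x, stats = NULL) {
  if (is.null(stats)) stats <- locus_stats(x)
  counts <- .allele_counts(x)
  pops <- names(counts)
  single <- length(pops) < 2
  if (single) warning("private alleles are undefined for a single population")
  L <- n_loci(x)
  # which populations carry each allele, per locus
  private <- stats::setNames(vector("list", length(pops)), pops)
  if (!single) {
    for (j in seq_len(L)) {
      seen <- lapply(pops, function(p) names(counts[[p]][[j]]))
      all_alleles <- unique(unlist(seen))
      for (al in all_alleles) {
        holders <- pops[vapply(seen, function(s) al %in% s, logical(1))]
        if (length(holders) == 1) {
          cnt <- counts[[holders]][[j]]
          private[[holders]] <- c(private[[holders]],
                                  as.numeric(cnt[al]) / sum(cnt))
        }
      }
    }
  }
  rows <- lapply(pops, function(p) {
    st <- stats[stats$pop == p & stats$n_typed > 0, ]
    cnt <- counts[[p]]
    pi_l <- vapply(seq_len(L), function(j) {
      cc <- as.numeric(cnt[[j]]); n <- sum(cc)
      if (n < 2) return(NA_real_)
      1 - sum(cc * (cc - 1)) / (n * (n - 1))
    }, numeric(1))
    maj <- vapply(seq_len(L), function(j) {
      cc <- as.numeric(cnt[[j]])
      if (!sum(cc)) return(NA_real_)
      max(cc) / sum(cc)
    }, numeric(1))
    pa <- private[[p]]
    data.frame(
      pop = p, n = sum(x$pop == p),
      mean_H_obs = mean(st$H_obs, na.rm = TRUE),
      mean_H_exp = mean(st$H_exp, na.rm = TRUE),
      mean_H_exp_unbiased = mean(st$H_exp_unbiased, na.rm = TRUE),
      mean_PIC = mean(st$PIC, na.rm = TRUE),
      mean_n_alleles = mean(st$n_alleles, na.rm = TRUE),
      mean_n_eff = mean(st$n_eff, na.rm = TRUE),
      mean_null_freq = mean(st$null_freq, na.rm = TRUE),
      private_alleles = if (single) NA_integer_ else length(pa),
      private_mean_freq = if (single) NA_real_
                          else if (length(pa)) mean(pa) else 0,
      pct_polymorphic = 100 * mean(st$polymorphic, na.rm = TRUE),
      pi = mean(pi_l, na.rm = TRUE),
      major_freq = mean(maj, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weir-Cockerham F-statistics
#'
#' Multiallelic Weir & Cockerham (1984) variance components per allele and
#' locus: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals). Multi-locus estimates are
#' ratios of sums over alleles and loci: `F_ST = A / (A + B + C)`,
#' `F_IT = (A + B) / (A + B + C)`, `F_IS = 1 - C / (B + C)`. Pairwise
#' `F_ST` restricts the calculation to each population pair.
#'
#' @param x A [genotab()] with at least two populations.
#' @param pairwise Also compute the pairwise F_ST matrix (default `TRUE`).
#' @return List of class `fstats` with elements `overall` (named vector
#'   `F_IS`, `F_ST`, `F_IT`), `per_locus` (data frame), `pairwise_fst`
#'   (symmetric matrix, zero diagonal, or `NULL`), and `defined` (flag;
#'   `FALSE` when all variance components are zero).
#' @export
wc_fstats <- function(x, pairwise = TRUE) {
  pops <- unique(x$pop)
  if (length(pops) < 2) stop("F-statistics need at least two populations")
  comp <- .wc_components(x)
  A <- sum(comp$a); B <- sum(comp$b); C <- sum(comp$c)
  defined <- (A + B + C) != 0
  overall <- c(
    F_IS = if ((B + C) != 0) 1 - C / (B + C) else NA_real_,
    F_ST = if (defined) A / (A + B + C) else NA_real_,
    F_IT = if (defined) (A + B) / (A + B + C) else NA_real_)
  per_locus <- stats::aggregate(cbind(a, b, c) ~ locus, data = comp, FUN = sum)
  per_locus$F_ST <- with(per_locus, ifelse(a + b + c != 0,
                                           a / (a + b + c), NA_real_))
  pw <- NULL
  if (pairwise) {
    pw <- matrix(0, length(pops), length(pops),
                 dimnames = list(pops, pops))
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in (i + 1):length(pops)) {
        sub <- subset_genotab(x, samples = x$pop %in% pops[c(i, j)])
        cc <- .wc_components(sub)
        tot <- sum(cc$a) + sum(cc$b) + sum(cc$c)
        pw[i, j] <- pw[j, i] <- if (tot != 0) sum(cc$a) / tot else NA_real_
      }
    }
  }
  structure(list(overall = overall, per_locus = per_locus,
                 pairwise_fst = pw, defined = defined),
            class = "fstats")
}

#' @export
print.fstats <- function(x, ...) {
  cat("Weir-Cockerham F-statistics (multi-locus ratio of sums)\n")
  print(round(x$overall, 4))
  if (!is.null(x$pairwise_fst)) {
    cat("Pairwise F_ST:\n")
    print(round(x$pairwise_fst, 4))
  }
  invisible(x)
}

# WC 1984 variance components; one row per locus x allele
.wc_components <- function(x) {
  pops <- unique(x$pop)
  rows_by_pop <- lapply(pops, function(p) which(x$pop == p))
  out <- list()
  for (j in seq_len(n_loci(x))) {
    # per-pop sample sizes (typed individuals) and allele freqs
    typed <- lapply(rows_by_pop, function(rws) {
      ok <- !is.na(x$a1[rws, j])
      rws[ok]
    })
    ni <- lengths(typed)
    use <- ni > 0
    if (sum(use) < 2) next
    ni <- ni[use]
    tt <- typed[use]
    r <- length(ni)
    N <- sum(ni)
    nbar <- N / r
    if (nbar <= 1) next
    nc <- (N - sum(ni^2) / N) / (r - 1)
    alleles <- sort(unique(c(x$a1[unlist(tt), j], x$a2[unlist(tt), j])))
    for (al in alleles) {
      p_i <- vapply(tt, function(rws)
        mean(c(x$a1[rws, j], x$a2[rws, j]) == al), numeric(1))
      h_i <- vapply(tt, function(rws)
        mean(x$a1[rws, j] != x$a2[rws, j] &
               (x$a1[rws, j] == al | x$a2[rws, j] == al)), numeric(1))
      pbar <- sum(ni * p_i) / N
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / N
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      out[[length(out) + 1]] <- data.frame(
        locus = x$loci$name[j], allele = al, a = a, b = b, c = cc)
    }
  }
  if (!length(out))
    return(data.frame(locus = character(), allele = integer(),
                      a = numeric(), b = numeric(), c = numeric()))
  do.call(rbind, out)
}

#' Nei's standard genetic distance
#'
#' Nei (1972) standard distance between populations:
#' `D = -ln( J_xy / sqrt(J_x * J_y) )` with the gene identities `J` summed
#' over loci and alleles before the ratio is taken (ratio of sums, the
#' default) or averaged per locus (`method = "per_locus"`).
#'
#' @param x A [genotab()] with at least two populations.
#' @param method `"ratio_of_sums"` (default) or `"per_locus"`.
#' @return Symmetric distance matrix with zero diagonal; pairs with zero
#'   shared identity give `Inf`.
#' @export
nei_distance <- function(x, method = c("ratio_of_sums", "per_locus")) {
  method <- match.arg(method)
  counts <- .allele_counts(x)
  pops <- names(counts)
  L <- n_loci(x)
  # frequency list per pop per locus, aligned on the union of alleles
  freq <- function(p, j, alleles) {
    cnt <- counts[[p]][[j]]
    f <- stats::setNames(numeric(length(alleles)), alleles)
    if (sum(cnt)) f[names(cnt)] <- as.numeric(cnt) / sum(cnt)
    f
  }
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (k in (i + 1):length(pops)) {
      jxy <- jx <- jy <- numeric(L)
      for (j in seq_len(L)) {
        alleles <- union(names(counts[[pops[i]]][[j]]),
                         names(counts[[pops[k]]][[j]]))
        if (!length(alleles)) { jxy[j] <- NA; next }
        fx <- freq(pops[i], j, alleles)
        fy <- freq(pops[k], j, alleles)
        jxy[j] <- sum(fx * fy); jx[j] <- sum(fx^2); jy[j] <- sum(fy^2)
      }
      ok <- !is.na(jxy)
      Ival <- if (method == "ratio_of_sums")
        sum(jxy[ok]) / sqrt(sum(jx[ok]) * sum(jy[ok]))
      else mean(jxy[ok] / sqrt(jx[ok] * jy[ok]))
      D[i, k] <- D[k, i] <- if (Ival > 0) -log(Ival) else Inf
    }
  }
  D
}

#' Rosenberg informativeness for assignment
#'
#' Per-locus informativeness for assignment to K populations:
#' `I_n = sum_alleles( -pbar * ln(pbar) + sum_pops p_pop * ln(p_pop) / K )`
#' with `pbar` the unweighted mean allele frequency across populations and
#' the convention `0 * ln(0) = 0`. Natural logarithms.
#'
#' @param x A [genotab()] with at least two populations.
#' @return Data frame with columns `locus`, `marker_class`, `I_n`, plus an
#'   attribute `"panel_means"`: named vector of mean I_n per marker class
#'   and overall.
#' @export
informativeness <- function(x) {
  counts <- .allele_counts(x)
  pops <- names(counts)
  if (length(pops) < 2) stop("informativeness needs at least two populations")
  xlnx <- function(v) ifelse(v > 0, v * log(v), 0)
  L <- n_loci(x)
  In <- numeric(L)
  for (j in seq_len(L)) {
    have <- pops[vapply(pops, function(p) sum(counts[[p]][[j]]) > 0,
                        logical(1))]
    K <- length(have)
    if (K < 2) { In[j] <- NA; next }
    alleles <- unique(unlist(lapply(have, function(p)
      names(counts[[p]][[j]]))))
    fmat <- vapply(have, function(p) {
      cnt <- counts[[p]][[j]]
      f <- stats::setNames(numeric(length(alleles)), alleles)
      f[names(cnt)] <- as.numeric(cnt) / sum(cnt)
      f
    }, numeric(length(alleles)))
    fmat <- matrix(fmat, nrow = length(alleles))
    pbar <- rowMeans(fmat)
    In[j] <- sum(-xlnx(pbar) + rowSums(xlnx(fmat)) / K)
  }
  out <- data.frame(locus = x$loci$name,
                    marker_class = x$loci$marker_class, I_n = In)
  means <- c(overall = mean(In, na.rm = TRUE),
             tapply(In, x$loci$marker_class, mean, na.rm = TRUE))
  attr(out, "panel_means") <- means
  out
}
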