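# Independent oracles and small fixture builders used across the suite.

# Build a genotab directly from allele matrices (test shorthand).
make_geno <- function(a1, a2, pop, chrom = NULL, pos = NULL,
                      marker_class = "snp") {
  L <- ncol(a1)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  genotab(a1, a2, paste0("s", seq_len(nrow(a1))), pop,
          data.frame(name = paste0("L", seq_len(L)), chrom = chrom,
                     pos = pos, marker_class = marker_class,
                     stringsAsFactors = FALSE))
}

# One-sample genotype table from a state vector:
# 0 hom-ref, 1 het, 2 hom-alt, NA missing.
geno_from_state <- function(states, pos) {
  a1 <- ifelse(is.na(states), NA_integer_,
               ifelse(states == 1L, 0L, ifelse(states == 2L, 1L, 0L)))
  a2 <- ifelse(is.na(states), NA_integer_,
               ifelse(states == 0L, 0L, 1L))
  make_geno(matrix(a1, 1), matrix(a2, 1), pop = "p", pos = pos)
}

# Brute-force ROH oracle: enumerate every window, keep feasible ones
# (hom endpoints, het/missing budgets, min hom count, min span), drop
# windows contained in a feasible window, then resolve overlaps by
# repeatedly keeping the longest remaining window (ties: left-most).
# state: 0 hom, 1 het, 2 missing; pos: positions.
roh_oracle <- function(state, pos, min_len, min_snps, max_missing,
                       max_het = 0) {
  L <- length(state)
  ch <- cumsum(state == 1L); cm <- cumsum(state == 2L)
  co <- cumsum(state == 0L)
  win <- list()
  for (i in seq_len(L)) {
    if (state[i] != 0L) next
    for (j in i:L) {
      if (state[j] != 0L) next
      nh <- ch[j] - if (i > 1) ch[i - 1] else 0
      nm <- cm[j] - if (i > 1) cm[i - 1] else 0
      if (nh > max_het || nm > max_missing) next
      nhom <- co[j] - if (i > 1) co[i - 1] else 0
      if (nhom < min_snps) next
      if (pos[j] - pos[i] + 1 < min_len) next
      win[[length(win) + 1]] <- c(i, j)
    }
  }
  if (!length(win)) return(data.frame(from = integer(), to = integer()))
  w <- do.call(rbind, win)
  keep <- rep(TRUE, nrow(w))
  for (k in seq_len(nrow(w))) {
    for (m in seq_len(nrow(w))) {
      if (m != k && w[m, 1] <= w[k, 1] && w[m, 2] >= w[k, 2] &&
          (w[m, 1] < w[k, 1] || w[m, 2] > w[k, 2])) keep[k] <- FALSE
    }
  }
  w <- w[keep, , drop = FALSE]
  chosen <- matrix(integer(), 0, 2)
  remaining <- w
  while (nrow(remaining)) {
    len <- remaining[, 2] - remaining[, 1]
    best <- which(len == max(len))
    best <- best[which.min(remaining[best, 1])]
    b <- remaining[best, ]
    chosen <- rbind(chosen, b)
    ov <- remaining[, 1] <= b[2] & remaining[, 2] >= b[1]
    remaining <- remaining[!ov, , drop = FALSE]
  }
  chosen <- chosen[order(chosen[, 1]), , drop = FALSE]
  data.frame(from = chosen[, 1], to = chosen[, 2])
}

# Weir-Cockerham (1984) components for one biallelic locus in two
# populations, written out scalar-by-scalar from the published formulas.
wc_toy_oracle <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  comp_one <- function(pa1, pa2, ha1, ha2) {
    pbar <- (n1 * pa1 + n2 * pa2) / (n1 + n2)
    s2 <- (n1 * (pa1 - pbar)^2 + n2 * (pa2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * ha1 + n2 * ha2) / (n1 + n2)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }
  # both alleles of the biallelic locus contribute components
  z <- comp_one(p1, p2, h1, h2) + comp_one(1 - p1, 1 - p2, h1, h2)
  list(a = z[1], b = z[2], c = z[3], fst = z[1] / sum(z))
}

# Exhaustive Mantel p-value over all permutations of small matrices.
mantel_exhaustive_p <- function(g, d) {
  n <- nrow(g)
  perms <- NULL
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute_all(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ut <- upper.tri(g)
  r_obs <- cor(g[ut], d[ut])
  rs <- vapply(permute_all(seq_len(n)), function(idx)
    cor(g[ut], d[idx, idx][ut]), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# One neutral EHH/iHS haplotype fixture small enough for direct checks.
make_haps <- function(H, pos = NULL, chrom = NULL, ancestral = NULL) {
  L <- ncol(H)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", L)
  haplotab(H, paste0("i", seq_len(nrow(H) / 2)),
           data.frame(name = paste0("L", seq_len(L)), chrom = chrom,
                      pos = pos, marker_class = "snp",
                      stringsAsFactors = FALSE),
           ancestral = ancestral)
}
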