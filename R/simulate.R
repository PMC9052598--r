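#' Simulate a discrete-generation pedigree
#'
#' Random mating within a finite parent pool for a fixed number of discrete
#' generations, optionally forcing full-sib or parent-offspring matings at
#' stated generations to plant individuals with known inbreeding. Ground
#' truth inbreeding is computed with the path-counting algorithm
#' ([inbreeding_paths()]), independently of the recursive engine.
#'
#' @param n_founders Founders in generation 0 (half sires, half dams).
#' @param n_per_gen Individuals born per generation.
#' @param generations Number of generations after the founders.
#' @param n_sires,n_dams Parent pool sizes drawn from the previous
#'   generation (defaults: half the cohort each, i.e. every individual may
#'   breed).
#' @param forced Optional data frame with columns `generation` and `type`
#'   (`"fullsib"` or `"parent_offspring"`); one such mating is planted per
#'   row.
#' @param seed RNG seed (mandatory).
#' @return List with `ped` (a [pedigree()]) and `truth` (list: `F` from path
#'   counting, `pool` sizes, `forced`).
#' @export
sim_pedigree <- function(n_founders = 20, n_per_gen = 20, generations = 5,
                         n_sires = NULL, n_dams = NULL, forced = NULL,
                         seed) {
  set.seed(seed)
  if (is.null(n_sires)) n_sires <- max(1, floor(n_founders / 2))
  if (is.null(n_dams)) n_dams <- max(1, floor(n_founders / 2))
  id <- paste0("G0_", seq_len(n_founders))
  sex <- rep(c("M", "F"), length.out = n_founders)
  recs <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                     sex = sex, gen = 0L, stringsAsFactors = FALSE)
  fullsib_prep <- NULL   # pair of same-parent, opposite-sex sibs to mate
  for (g in seq_len(generations)) {
    prev <- recs[recs$gen == g - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < 1 || length(females) < 1)
      stop("a generation ran out of one sex; enlarge the cohorts")
    pool_s <- sample(males, min(n_sires, length(males)))
    pool_d <- sample(females, min(n_dams, length(females)))
    want_fs <- !is.null(forced) &&
      any(forced$generation == g & forced$type == "fullsib")
    want_po <- !is.null(forced) &&
      any(forced$generation == g & forced$type == "parent_offspring")
    prep_fs_next <- !is.null(forced) &&
      any(forced$generation == g + 1L & forced$type == "fullsib")
    new <- data.frame(id = paste0("G", g, "_", seq_len(n_per_gen)),
                      sire = sample(pool_s, n_per_gen, replace = TRUE),
                      dam = sample(pool_d, n_per_gen, replace = TRUE),
                      sex = sample(rep(c("M", "F"),
                                       length.out = n_per_gen)),
                      gen = g, stringsAsFactors = FALSE)
    k <- 1
    if (want_fs) {
      if (is.null(fullsib_prep))
        stop("forced full-sib mating at generation ", g,
             " is infeasible: no prepared sib pair")
      new$sire[k] <- fullsib_prep[1]; new$dam[k] <- fullsib_prep[2]
      k <- k + 1
    }
    if (want_po) {
      sire0 <- pool_s[1]
      daughters <- prev$id[prev$sex == "F" & !is.na(prev$sire) &
                             prev$sire == sire0]
      if (!length(daughters))
        stop("forced parent-offspring mating at generation ", g,
             " is infeasible: sire ", sire0, " has no daughters")
      new$sire[k] <- sire0; new$dam[k] <- daughters[1]
      k <- k + 1
    }
    if (prep_fs_next) {
      # plant two opposite-sex offspring of one couple
      new$sire[c(k, k + 1)] <- pool_s[1]
      new$dam[c(k, k + 1)] <- pool_d[1]
      new$sex[c(k, k + 1)] <- c("M", "F")
      fullsib_prep <- c(new$id[k], new$id[k + 1])
    } else fullsib_prep <- NULL
    recs <- rbind(recs, new)
  }
  ped <- pedigree(recs$id, recs$sire, recs$dam)
  truth <- list(F = inbreeding_paths(ped),
                pool = c(sires = n_sires, dams = n_dams),
                forced = forced)
  list(ped = ped, truth = truth)
}

#' Simulate drifted breeds
#'
#' K breeds derived from one ancestral allele-frequency pool by independent
#' Wright-Fisher binomial (SNP) or multinomial (microsatellite) drift for
#' `t` generations at size `N`, then genotypes sampled under Hardy-Weinberg
#' within each breed. Ancestral SNP frequencies are Uniform(0.05, 0.95);
#' microsatellite loci get 4-18 alleles with symmetric-Dirichlet ancestral
#' frequencies. Expected pairwise differentiation between two breeds drifted
#' at equal size is `1 - (1 - 1/(2N))^t`.
#'
#' @param n_breeds Number of breeds (default 6).
#' @param n_per_breed Samples per breed (recycled; default 40).
#' @param n_snp,n_microsat Locus counts (defaults 200 and 24).
#' @param N Drift population size per breed (recycled; default 50).
#' @param t Drift generations per breed (recycled; default 20).
#' @param missing_rate Fraction of genotypes set missing (default 0).
#' @param n_chrom Autosomes the SNPs are spread over (default 18).
#' @param chrom_length_bp Length per autosome (default 120 Mb).
#' @param seed RNG seed (mandatory).
#' @return List with `geno` (a [genotab()]) and `truth` (list:
#'   `ancestral_snp_freq`, `breed_snp_freq`, `N`, `t`, `expected_fst`
#'   pairwise matrix).
#' @export
sim_breeds <- function(n_breeds = 6, n_per_breed = 40, n_snp = 200,
                       n_microsat = 24, N = 50, t = 20, missing_rate = 0,
                       n_chrom = 18, chrom_length_bp = 1.2e8, seed) {
  set.seed(seed)
  N <- rep_len(N, n_breeds); t <- rep_len(t, n_breeds)
  n_per_breed <- rep_len(n_per_breed, n_breeds)
  breeds <- paste0("breed", seq_len(n_breeds))
  p0 <- stats::runif(n_snp, 0.05, 0.95)
  ms_k <- if (n_microsat) sample(4:18, n_microsat, replace = TRUE) else integer(0)
  ms_p0 <- lapply(ms_k, function(k) {
    g <- stats::rgamma(k, 1); g / sum(g)      # symmetric Dirichlet(1)
  })
  drift_snp <- function(p, N, t) {
    for (i in seq_len(t)) p <- stats::rbinom(length(p), 2 * N, p) / (2 * N)
    p
  }
  drift_ms <- function(p, N, t) {
    for (i in seq_len(t)) p <- as.numeric(stats::rmultinom(1, 2 * N, p)) / (2 * N)
    p
  }
  snp_freq <- lapply(seq_len(n_breeds), function(b) drift_snp(p0, N[b], t[b]))
  ms_freq <- lapply(seq_len(n_breeds), function(b)
    lapply(ms_p0, function(p) drift_ms(p, N[b], t[b])))
  n_tot <- sum(n_per_breed)
  L <- n_snp + n_microsat
  a1 <- matrix(NA_integer_, n_tot, L)
  a2 <- matrix(NA_integer_, n_tot, L)
  row0 <- 0
  for (b in seq_len(n_breeds)) {
    nb <- n_per_breed[b]
    rows <- row0 + seq_len(nb)
    if (n_snp) {
      pb <- snp_freq[[b]]
      a1[rows, seq_len(n_snp)] <-
        matrix(stats::rbinom(nb * n_snp, 1, rep(pb, each = nb)), nb)
      a2[rows, seq_len(n_snp)] <-
        matrix(stats::rbinom(nb * n_snp, 1, rep(pb, each = nb)), nb)
    }
    for (m in seq_len(n_microsat)) {
      pm <- ms_freq[[b]][[m]]
      sizes <- 100L + 2L * seq_along(pm)     # allele-size style codes
      a1[rows, n_snp + m] <- sample(sizes, nb, replace = TRUE, prob = pm)
      a2[rows, n_snp + m] <- sample(sizes, nb, replace = TRUE, prob = pm)
    }
    row0 <- row0 + nb
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_tot * L) < missing_rate, n_tot)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  chrom <- rep_len(paste0("chr", seq_len(n_chrom)), n_snp)
  pos <- integer(n_snp)
  for (chr in unique(chrom)) {
    jj <- which(chrom == chr)
    pos[jj] <- sort(sample.int(chrom_length_bp, length(jj)))
  }
  ord <- order(match(chrom, paste0("chr", seq_len(n_chrom))), pos)
  loci <- data.frame(name = paste0("snp", seq_len(n_snp))[ord],
                     chrom = chrom[ord], pos = pos[ord],
                     marker_class = "snp", stringsAsFactors = FALSE)
  if (n_microsat)
    loci <- rbind(loci, data.frame(
      name = paste0("ms", seq_len(n_microsat)), chrom = NA_character_,
      pos = NA_integer_, marker_class = "microsatellite",
      stringsAsFactors = FALSE))
  a1 <- cbind(a1[, seq_len(n_snp), drop = FALSE][, ord, drop = FALSE],
              a1[, n_snp + seq_len(n_microsat), drop = FALSE])
  a2 <- cbind(a2[, seq_len(n_snp), drop = FALSE][, ord, drop = FALSE],
              a2[, n_snp + seq_len(n_microsat), drop = FALSE])
  geno <- genotab(a1, a2,
                  paste0("s", seq_len(n_tot)),
                  rep(breeds, times = n_per_breed), loci)
  efst <- outer(seq_len(n_breeds), seq_len(n_breeds), function(i, j) {
    1 - sqrt((1 - 1 / (2 * N[i]))^t[i] * (1 - 1 / (2 * N[j]))^t[j])
  })
  diag(efst) <- 0
  dimnames(efst) <- list(breeds, breeds)
  list(geno = geno,
       truth = list(ancestral_snp_freq = p0, breed_snp_freq = snp_freq,
                    N = N, t = t, expected_fst = efst))
}

#' Simulate a stepping-stone transect of populations
#'
#' A 1-D drift chain: population 1 drifts from the ancestral pool, each next
#' population drifts onward from its neighbour, so genetic divergence grows
#' with transect distance. Geographic coordinates are placed on a constant-
#' latitude transect with `spacing_km` between neighbours.
#'
#' @param n_pops Number of populations (default 6).
#' @param n_per_pop Samples per population (default 30).
#' @param n_snp SNP count (default 200).
#' @param N,t_step Drift size and generations per chain step.
#' @param spacing_km Geographic spacing between neighbours (default 150).
#' @param seed RNG seed.
#' @return List with `geno` ([genotab()]), `geo` (coordinate table) and
#'   `truth` (chain parameters).
#' @export
sim_transect <- function(n_pops = 6, n_per_pop = 30, n_snp = 200, N = 50,
                         t_step = 10, spacing_km = 150, seed) {
  set.seed(seed)
  p <- stats::runif(n_snp, 0.05, 0.95)
  freqs <- vector("list", n_pops)
  for (b in seq_len(n_pops)) {
    for (i in seq_len(t_step))
      p <- stats::rbinom(n_snp, 2 * N, p) / (2 * N)
    freqs[[b]] <- p
  }
  n_tot <- n_pops * n_per_pop
  a1 <- matrix(NA_integer_, n_tot, n_snp)
  a2 <- matrix(NA_integer_, n_tot, n_snp)
  for (b in seq_len(n_pops)) {
    rows <- (b - 1) * n_per_pop + seq_len(n_per_pop)
    pb <- freqs[[b]]
    a1[rows, ] <- matrix(stats::rbinom(n_per_pop * n_snp, 1,
                                       rep(pb, each = n_per_pop)), n_per_pop)
    a2[rows, ] <- matrix(stats::rbinom(n_per_pop * n_snp, 1,
                                       rep(pb, each = n_per_pop)), n_per_pop)
  }
  loci <- data.frame(name = paste0("snp", seq_len(n_snp)), chrom = "chr1",
                     pos = seq_len(n_snp) * 1000L, marker_class = "snp")
  pops <- paste0("pop", seq_len(n_pops))
  geno <- genotab(a1, a2, paste0("s", seq_len(n_tot)),
                  rep(pops, each = n_per_pop), loci)
  # ~1 degree of longitude at 45N is ~78.6 km
  km_per_deg <- 6371 * pi / 180 * cos(45 * pi / 180)
  geo <- data.frame(population = pops, lat = 45,
                    lon = 10 + (seq_len(n_pops) - 1) * spacing_km / km_per_deg)
  list(geno = geno, geo = geo,
       truth = list(N = N, t_step = t_step, spacing_km = spacing_km))
}

#' Simulate recombining haplotypes forward in time
#'
#' Diploid Wright-Fisher population with Poisson recombination, simulated
#' forward from a founder pool in linkage equilibrium. Supports a size
#' trajectory (vector `N`), an optional selective sweep (an allele at a
#' stated locus favoured multiplicatively by `s` per copy until it reaches a
#' target frequency; if it is lost it is re-seeded in one haplotype, i.e.
#' the simulation conditions on establishment), and an optional planted
#' homozygous region (a stated interval copied between the two chromosomes
#' of a stated fraction of final individuals, creating a shared ROH island).
#'
#' @param n_ind Diploid individuals sampled at the end (default: final N).
#' @param n_chrom Number of chromosomes (default 5).
#' @param chrom_length_bp Chromosome length (default 5e6).
#' @param snp_per_chrom Markers per chromosome, evenly spaced (default 100).
#' @param generations Number of generations simulated (default 100).
#' @param N Population size: scalar or vector of length `generations`.
#' @param cm_per_mb Recombination rate (default 1).
#' @param founder_maf_range Founder allele-frequency range
#'   (default `c(0.1, 0.9)`).
#' @param sweep Optional list: `chrom`, `locus` (index within chromosome),
#'   `s`, `target_freq`, and optionally `start_copies` (founder haplotypes
#'   carrying the selected allele, default 1: a hard sweep) or `start_freq`
#'   (standing-variation frequency instead, a soft sweep), and `start_gen`
#'   (default: selection from generation 1).
#' @param planted_roh Optional list: `chrom`, `start_bp`, `end_bp`,
#'   `fraction` of individuals made homozygous over the interval.
#' @param seed RNG seed (mandatory).
#' @return List with `haps` ([haplotab()], ancestral = founder-major
#'   allele), `geno` (unphased [genotab()] view), and `truth` (list:
#'   `N_trajectory`, `sweep` with realised frequency, `planted_roh`,
#'   `founder_freq`).
#' @export
sim_haplotypes <- function(n_ind = NULL, n_chrom = 5, chrom_length_bp = 5e6,
                           snp_per_chrom = 100, generations = 100, N = 100,
                           cm_per_mb = 1,
                           founder_maf_range = c(0.1, 0.9),
                           sweep = NULL, planted_roh = NULL, seed) {
  set.seed(seed)
  Ntraj <- rep_len(N, max(generations, 1L))
  L <- n_chrom * snp_per_chrom
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = snp_per_chrom)
  pos <- rep(round(seq(chrom_length_bp / snp_per_chrom, chrom_length_bp,
                       length.out = snp_per_chrom)), n_chrom)
  chrom_idx <- split(seq_len(L), chrom)[paste0("chr", seq_len(n_chrom))]
  morgans <- chrom_length_bp * cm_per_mb * 1e-8
  p0 <- stats::runif(L, founder_maf_range[1], founder_maf_range[2])
  N0 <- Ntraj[1]
  H <- matrix(stats::rbinom(2 * N0 * L, 1, rep(p0, each = 2 * N0)),
              nrow = 2 * N0)
  sweep_j <- NULL
  if (!is.null(sweep)) {
    sweep_j <- chrom_idx[[sweep$chrom]][sweep$locus]
    sweep_start <- if (!is.null(sweep$start_gen)) sweep$start_gen else 1L
    sweep_active <- TRUE
    if (!is.null(sweep$start_freq)) {          # soft sweep
      p0[sweep_j] <- sweep$start_freq
      H[, sweep_j] <- stats::rbinom(2 * N0, 1, p0[sweep_j])
    } else {                                   # hard sweep from few copies
      k <- if (!is.null(sweep$start_copies)) sweep$start_copies else 1L
      p0[sweep_j] <- k / (2 * N0)
      H[, sweep_j] <- 0L
      H[sample.int(2 * N0, k), sweep_j] <- 1L
    }
  }
  end_gen <- generations
  for (g in seq_len(generations)) {
    Ng <- Ntraj[g]
    n_prev <- nrow(H) / 2
    w <- rep(1, n_prev)
    if (!is.null(sweep_j) && sweep_active && g >= sweep_start) {
      freq <- mean(H[, sweep_j])
      if (freq == 0) {           # lost: re-seed one carrier haplotype
        H[sample.int(2 * n_prev, 1), sweep_j] <- 1L
      } else if (freq >= sweep$target_freq) {
        sweep_active <- FALSE
        if (isTRUE(sweep$sample_at_target) ||
            is.null(sweep$sample_at_target)) {
          end_gen <- g - 1L
          break                  # sample right at sweep completion
        }
      }
      dose <- H[seq(1, 2 * n_prev, 2), sweep_j] +
        H[seq(2, 2 * n_prev, 2), sweep_j]
      w <- (1 + sweep$s)^dose
    }
    parents <- sample.int(n_prev, 2 * Ng, replace = TRUE, prob = w)
    H1 <- H[2 * parents - 1, , drop = FALSE]
    H2 <- H[2 * parents, , drop = FALSE]
    # crossover mask: TRUE where the gamete copies the second haplotype
    M <- matrix(FALSE, 2 * Ng, L)
    for (ci in seq_len(n_chrom)) {
      jj <- chrom_idx[[ci]]
      k <- stats::rpois(2 * Ng, morgans)
      start <- sample.int(2, 2 * Ng, replace = TRUE)
      M[start == 2, jj] <- TRUE            # k = 0 fast path
      for (gm in which(k > 0)) {
        bp <- sort(stats::runif(k[gm], 0, chrom_length_bp))
        seg <- findInterval(pos[jj], bp)
        M[gm, jj] <- ((start[gm] + seg) %% 2L) == 0L
      }
    }
    H1[M] <- H2[M]
    H <- H1
  }
  Nf <- nrow(H) / 2
  if (is.null(n_ind)) n_ind <- Nf
  take <- sample.int(Nf, min(n_ind, Nf))
  rows <- as.vector(rbind(2 * take - 1, 2 * take))
  H <- H[rows, , drop = FALSE]
  n_ind <- length(take)
  planted <- NULL
  if (!is.null(planted_roh)) {
    jj <- which(chrom == planted_roh$chrom & pos >= planted_roh$start_bp &
                  pos <= planted_roh$end_bp)
    chosen <- sample.int(n_ind, round(planted_roh$fraction * n_ind))
    for (i in chosen) H[2 * i, jj] <- H[2 * i - 1, jj]
    planted <- c(planted_roh, list(individuals = chosen, n_snps = length(jj)))
  }
  ids <- paste0("ind", seq_len(n_ind))
  loci <- data.frame(name = paste0(chrom, "_", pos), chrom = chrom,
                     pos = pos, marker_class = "snp",
                     stringsAsFactors = FALSE)
  # random ancestral labels: neutral derived-allele frequencies then span the
  # founder range on both sides, as with outgroup-polarised real data
  ancestral <- as.integer(stats::runif(L) < 0.5)
  if (!is.null(sweep_j)) ancestral[sweep_j] <- 0L  # selected allele derived
  haps <- haplotab(H, ids, loci, ancestral = ancestral)
  truth <- list(N_trajectory = Ntraj[seq_len(end_gen)],
                end_generation = end_gen,
                sweep = if (!is.null(sweep))
                  c(sweep, list(locus_index = sweep_j,
                                pos = pos[sweep_j],
                                realised_freq = mean(H[, sweep_j]))),
                planted_roh = planted,
                founder_freq = p0)
  list(haps = haps, geno = haplo_to_geno(haps), truth = truth)
}
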