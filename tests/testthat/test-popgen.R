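test_that("per-locus statistics match closed forms", {
  # biallelic p = q = 0.5: 4 samples 0/0, 0/1, 1/0, 1/1
  g <- make_geno(rbind(0L, 0L, 1L, 1L), rbind(0L, 1L, 0L, 1L),
                 pop = rep("p", 4))
  st <- locus_stats(g)
  expect_equal(st$H_exp, 0.5)
  expect_equal(st$n_eff, 2)
  expect_equal(st$PIC, 0.375)
  expect_equal(st$H_obs, 0.5)
  expect_equal(st$H_exp_unbiased, 0.5 * 8 / 7)
})

test_that("monomorphic loci have zero diversity and polymorphic flag off", {
  g <- make_geno(matrix(0L, 4, 1), matrix(0L, 4, 1), pop = rep("p", 4))
  st <- locus_stats(g)
  expect_equal(st$H_exp, 0)
  expect_equal(st$PIC, 0)
  expect_equal(st$n_eff, 1)
  expect_false(st$polymorphic)
})

test_that("PIC and effective alleles for k equifrequent alleles", {
  # 4 alleles x 2 copies each among 4 diploids
  g <- make_geno(matrix(c(101L, 102L, 103L, 104L)),
                 matrix(c(101L, 102L, 103L, 104L)),
                 pop = rep("p", 4), marker_class = "microsatellite")
  st <- locus_stats(g)
  expect_equal(st$n_eff, 4)
  expect_equal(st$H_exp, 0.75)
  # 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2 with 6 pairs of (1/4)^2 (1/4)^2
  expect_equal(st$PIC, 1 - 0.25 - 6 * 2 * (1 / 16) * (1 / 16))
  expect_equal(st$PIC, 0.703125)
})

test_that("statistic inequalities hold across random tables", {
  sb <- sim_breeds(n_breeds = 3, n_per_breed = 25, n_snp = 60,
                   n_microsat = 12, N = 40, t = 8, missing_rate = 0.05,
                   seed = 21)
  st <- locus_stats(sb$geno)
  st <- st[st$n_typed > 0, ]
  expect_true(all(st$PIC <= st$H_exp + 1e-12))
  expect_true(all(st$H_exp <= 1 & st$H_exp >= 0))
  expect_true(all(st$n_eff <= st$n_alleles + 1e-9))
})

test_that("nucleotide diversity counts distinct-copy mismatch probability", {
  # one locus, n = 4 allele copies with counts {2, 2}
  g <- make_geno(rbind(0L, 1L), rbind(0L, 1L), pop = c("p", "p"))
  ps <- suppressWarnings(pop_summary(g))
  expect_equal(ps$pi, 1 - (2 * 1 + 2 * 1) / (4 * 3))
  expect_equal(ps$pi, 2 / 3)
  # two copies of the same allele: pi = 0
  g2 <- make_geno(matrix(0L), matrix(0L), pop = "p")
  expect_equal(suppressWarnings(pop_summary(g2))$pi, 0)
})

test_that("private alleles are alleles seen in exactly one population", {
  # allele 2 only in pop A (freq 2/8); allele 3 only in pop B (freq 1/6)
  a1 <- rbind(c(0L), c(2L), c(0L), c(0L), c(3L), c(1L), c(1L))
  a2 <- rbind(c(0L), c(2L), c(1L), c(0L), c(1L), c(1L), c(0L))
  g <- make_geno(a1, a2, pop = c("A", "A", "A", "A", "B", "B", "B"),
                 marker_class = "microsatellite")
  ps <- pop_summary(g)
  expect_equal(ps$private_alleles, c(1L, 1L))
  expect_equal(ps$private_mean_freq[ps$pop == "A"], 2 / 8)
  expect_equal(ps$private_mean_freq[ps$pop == "B"], 1 / 6)
  g1 <- pop_subset(g, "A")
  expect_warning(ps1 <- pop_summary(g1), "single population")
  expect_true(is.na(ps1$private_alleles))
})

test_that("percent polymorphic uses a two-allele floor per population", {
  a1 <- cbind(c(0L, 0L, 0L), c(0L, 0L, 1L))
  g <- make_geno(a1, a1, pop = rep("p", 3))
  ps <- suppressWarnings(pop_summary(g))
  expect_equal(ps$pct_polymorphic, 50)
})

test_that("Weir-Cockerham components match an independent scalar oracle", {
  # 2 pops x 10 samples, crafted genotype counts at one locus
  a1 <- c(rep(0L, 7), rep(1L, 3), rep(0L, 2), rep(1L, 8))
  a2 <- c(rep(0L, 4), rep(1L, 6), rep(0L, 5), rep(1L, 5))
  g <- make_geno(matrix(a1), matrix(a2), pop = rep(c("A", "B"), each = 10))
  fs <- wc_fstats(g, pairwise = FALSE)
  p1 <- mean(c(a1[1:10], a2[1:10]))        # freq of allele 1 in A
  p2 <- mean(c(a1[11:20], a2[11:20]))
  h1 <- mean(a1[1:10] != a2[1:10])
  h2 <- mean(a1[11:20] != a2[11:20])
  oracle <- wc_toy_oracle(p1, p2, h1, h2, 10, 10)
  expect_equal(unname(fs$overall["F_ST"]), oracle$fst, tolerance = 1e-12)
})

test_that("F_ST hits its boundary cases", {
  # fixed for alternative alleles
  g <- make_geno(matrix(rep(c(0L, 1L), each = 8)),
                 matrix(rep(c(0L, 1L), each = 8)),
                 pop = rep(c("A", "B"), each = 8))
  fs <- wc_fstats(g)
  expect_equal(unname(fs$overall["F_ST"]), 1)
  expect_equal(fs$pairwise_fst["A", "B"], 1)
  expect_equal(diag(fs$pairwise_fst), c(A = 0, B = 0))
  # no data variance at all: undefined with flag
  g0 <- make_geno(matrix(0L, 6, 1), matrix(0L, 6, 1),
                  pop = rep(c("A", "B"), each = 3))
  fs0 <- wc_fstats(g0, pairwise = FALSE)
  expect_false(fs0$defined)
})

test_that("identical allele frequencies give near-zero F_ST at n = 200", {
  sb <- sim_breeds(n_breeds = 2, n_per_breed = 200, n_snp = 150,
                   n_microsat = 0, N = 50, t = 0, seed = 14)
  fs <- wc_fstats(sb$geno)
  expect_lt(abs(fs$pairwise_fst[1, 2]), 0.02)
})

test_that("Nei standard distance matches hand arithmetic on a 2-locus toy", {
  # pop A freqs: locus1 (0.75, 0.25), locus2 (0.5, 0.5)
  # pop B freqs: locus1 (0.25, 0.75), locus2 (0.5, 0.5)
  a1 <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L),
              c(1L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
  g <- make_geno(a1, a1, pop = rep(c("A", "B"), each = 4))
  fA <- list(c(0.75, 0.25), c(0.5, 0.5))
  fB <- list(c(0.25, 0.75), c(0.5, 0.5))
  jxy <- sum(unlist(Map(function(x, y) sum(x * y), fA, fB)))
  jx <- sum(unlist(lapply(fA, function(x) sum(x^2))))
  jy <- sum(unlist(lapply(fB, function(x) sum(x^2))))
  D <- nei_distance(g)
  expect_equal(D["A", "B"], -log(jxy / sqrt(jx * jy)))
  expect_equal(D["A", "B"], D["B", "A"])
  # identical profiles: zero distance
  g2 <- make_geno(a1[c(1:4, 1:4), ], a1[c(1:4, 1:4), ],
                  pop = rep(c("A", "B"), each = 4))
  expect_equal(nei_distance(g2)["A", "B"], 0)
})

test_that("informativeness for assignment matches its defining cases", {
  # identical frequencies: I_n = 0
  a1 <- rbind(0L, 1L, 0L, 1L)
  g0 <- make_geno(cbind(a1), cbind(a1), pop = c("A", "A", "B", "B"))
  expect_equal(informativeness(g0)$I_n, 0)
  # fixed difference between two pops: I_n = ln 2
  g1 <- make_geno(matrix(c(0L, 0L, 1L, 1L)), matrix(c(0L, 0L, 1L, 1L)),
                  pop = c("A", "A", "B", "B"))
  expect_equal(informativeness(g1)$I_n, log(2))
  # non-negativity on random tables
  sb <- sim_breeds(n_breeds = 4, n_per_breed = 20, n_snp = 40,
                   n_microsat = 8, N = 40, t = 10, seed = 8)
  In <- informativeness(sb$geno)
  expect_true(all(In$I_n >= -1e-12, na.rm = TRUE))
})

test_that("microsatellite panels are more informative per locus than SNPs", {
  sb <- sim_breeds(n_breeds = 6, n_per_breed = 30, n_snp = 120,
                   n_microsat = 24, N = c(30, 60, 40, 80, 50, 70),
                   t = 15, seed = 61)
  m <- attr(informativeness(sb$geno), "panel_means")
  expect_gt(m["microsatellite"], m["snp"])
})

test_that("allele frequencies sum to one for every population and locus", {
  sb <- sim_breeds(n_breeds = 3, n_per_breed = 20, n_snp = 30,
                   n_microsat = 10, N = 50, t = 5, missing_rate = 0.1,
                   seed = 2)
  cnt <- herdstat:::.allele_counts(sb$geno)
  for (p in names(cnt)) {
    for (tab in cnt[[p]]) {
      if (sum(tab) > 0)
        expect_equal(sum(as.numeric(tab) / sum(tab)), 1, tolerance = 1e-9)
    }
  }
})
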