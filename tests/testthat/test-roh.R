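test_that("a clean homozygous stretch yields exactly one ROH", {
  pos <- seq(0, by = 62000, length.out = 30) + 1L   # spans ~1.8 Mb
  g <- geno_from_state(rep(0L, 30), pos)
  roh <- call_roh(g, min_length_bp = 1e6, min_snps = 25)
  expect_equal(nrow(roh), 1L)
  expect_equal(roh$n_snps, 30L)
  expect_equal(roh$start_bp, pos[1])
  expect_equal(roh$end_bp, pos[30])
  expect_equal(roh$length_bp, pos[30] - pos[1] + 1)
})

test_that("one central heterozygote kills a run that needs 25 SNPs", {
  pos <- seq(0, by = 62000, length.out = 29) + 1L
  st <- rep(0L, 29); st[15] <- 1L                   # 14 homozygous each side
  g <- geno_from_state(st, pos)
  roh <- call_roh(g, min_length_bp = 1e6, min_snps = 25)
  expect_equal(nrow(roh), 0L)
})

test_that("runs are trimmed to homozygous non-missing endpoints", {
  pos <- seq(0, by = 50000, length.out = 32) + 1L
  st <- rep(0L, 32); st[1] <- NA; st[32] <- NA
  g <- geno_from_state(st, pos)
  roh <- call_roh(g, min_length_bp = 1e6, min_snps = 25)
  expect_equal(nrow(roh), 1L)
  expect_equal(roh$start_bp, pos[2])
  expect_equal(roh$end_bp, pos[31])
  expect_equal(roh$n_missing, 0L)
})

test_that("caller equals the brute-force window oracle on random sequences", {
  set.seed(4242)
  min_len <- 3e5; min_snps <- 8; max_miss <- 2
  for (r in 1:200) {
    L <- 50
    st <- sample(c(0L, 0L, 0L, 0L, 1L, NA), L, replace = TRUE)
    pos <- sort(sample.int(3e6, L))
    g <- geno_from_state(st, pos)
    state_codes <- ifelse(is.na(st), 2L, ifelse(st == 1L, 1L, 0L))
    oracle <- roh_oracle(state_codes, pos, min_len, min_snps, max_miss)
    roh <- call_roh(g, min_length_bp = min_len, min_snps = min_snps,
                    max_missing = max_miss)
    expect_equal(nrow(roh), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(roh$start_bp, pos[oracle$from])
      expect_equal(roh$end_bp, pos[oracle$to])
    }
  }
})

test_that("tightening thresholds is monotone in the expected direction", {
  set.seed(77)
  sh <- sim_haplotypes(n_chrom = 2, chrom_length_bp = 5e6,
                       snp_per_chrom = 100, generations = 40, N = 50,
                       seed = 77)
  g <- sh$geno
  base <- nrow(call_roh(g, min_length_bp = 5e5, min_snps = 10,
                        max_missing = 2))
  expect_lte(nrow(call_roh(g, min_length_bp = 1e6, min_snps = 10,
                           max_missing = 2)), base)
  expect_lte(nrow(call_roh(g, min_length_bp = 5e5, min_snps = 20,
                           max_missing = 2)), base)
  expect_gte(nrow(call_roh(g, min_length_bp = 5e5, min_snps = 10,
                           max_missing = 5)), base)
})

test_that("length classes use left-closed boundaries", {
  seg <- structure(
    data.frame(sample = c("s1", "s1", "s1"), chrom = "chr1",
               start_bp = c(1L, 1L, 1L),
               end_bp = c(2400000L, 2500000L, 5000000L),
               n_snps = 30L, n_missing = 0L,
               length_bp = c(2.4e6, 2.5e6, 5e6)),
    samples = "s1", pop = c(s1 = "p"),
    class = c("roh_set", "data.frame"))
  cl <- classify_roh(seg)
  expect_equal(as.character(cl$length_class), c("short", "medium", "long"))
  # partition: class counts sum to total
  expect_equal(sum(table(cl$length_class)), nrow(cl))
})

test_that("F_ROH arithmetic on the reference autosome length", {
  seg <- structure(
    data.frame(sample = "s1", chrom = "chr1", start_bp = 1L,
               end_bp = 233082885L, n_snps = 1000L, n_missing = 0L,
               length_bp = 233082885),
    samples = c("s1", "s2"), pop = c(s1 = "p", s2 = "p"),
    class = c("roh_set", "data.frame"))
  fr <- f_roh(seg)
  expect_equal(fr$F_ROH[fr$sample == "s1"], 0.1)
  expect_equal(fr$F_ROH[fr$sample == "s2"], 0)     # no segments -> 0
  frc <- f_roh(seg, by_class = TRUE)
  expect_equal(frc$F_ROH_short + frc$F_ROH_medium + frc$F_ROH_long,
               frc$F_ROH)
})

test_that("islands: full sharing gives incidence 1, impossible threshold none", {
  pos <- seq(0, by = 50000, length.out = 40) + 1L
  a <- matrix(0L, 6, 40)
  g <- make_geno(a, a, pop = rep("p", 6), pos = pos)
  roh <- call_roh(g, min_length_bp = 1e6, min_snps = 25)
  expect_equal(nrow(roh), 6L)
  isl <- suppressWarnings(roh_islands(roh, g, threshold = 0.5))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$peak_incidence, 1)
  expect_equal(isl$start_bp, pos[1])
  expect_equal(isl$end_bp, pos[40])
  none <- suppressWarnings(roh_islands(roh, g, threshold = 1.01))
  expect_equal(nrow(none), 0L)
})

test_that("inbred pedigree lines carry more ROH than outbred controls", {
  # same marker process, two population sizes: tighter pool -> more ROH
  sh_in <- sim_haplotypes(n_chrom = 3, chrom_length_bp = 5e6,
                          snp_per_chrom = 100, generations = 40, N = 25,
                          seed = 910)
  sh_out <- sim_haplotypes(n_chrom = 3, chrom_length_bp = 5e6,
                           snp_per_chrom = 100, generations = 40, N = 200,
                           seed = 910)
  roh_in <- call_roh(sh_in$geno, min_length_bp = 1e6, min_snps = 20)
  roh_out <- call_roh(sh_out$geno, min_length_bp = 1e6, min_snps = 20)
  f_in <- mean(f_roh(roh_in, 1.5e7)$F_ROH)
  f_out <- mean(f_roh(roh_out, 1.5e7)$F_ROH)
  expect_gt(f_in, f_out)
})
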