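test_that("EHH is 1 at the core and stays 1 for identical carriers", {
  H <- rbind(c(1L, 1L, 1L, 1L, 1L),
             c(1L, 1L, 1L, 1L, 1L),
             c(0L, 0L, 1L, 0L, 0L),
             c(0L, 1L, 1L, 1L, 0L))
  h <- make_haps(H)
  e <- ehh(h, core = 3, core_allele = 1L)
  expect_true(attr(e, "defined"))
  expect_equal(e$ehh[e$side == "core"], 1)
  # haplotypes 1 and 2 are identical throughout; 3 and 4 split later
  expect_equal(min(e$ehh), sum(choose(c(2, 1, 1), 2)) / choose(4, 2))
})

test_that("EHH matches the combinatorial 4/2 split value", {
  # 6 carriers of allele 1 at the core; one SNP out they split 4 / 2
  H <- cbind(rep(1L, 6), c(0L, 0L, 0L, 0L, 1L, 1L))
  h <- make_haps(H)
  e <- ehh(h, core = 1, core_allele = 1L, side = "right")
  expect_equal(e$ehh[e$side == "right"],
               (choose(4, 2) + choose(2, 2)) / choose(6, 2))
  expect_equal(e$ehh[e$side == "right"], 7 / 15)
})

test_that("fewer than two carriers is flagged undefined", {
  H <- cbind(c(1L, 0L, 0L, 0L), rep(0L, 4))
  h <- make_haps(H)
  e <- ehh(h, core = 1, core_allele = 1L)
  expect_false(attr(e, "defined"))
})

test_that("EHH never increases away from the core on complete data", {
  set.seed(88)
  for (r in 1:20) {
    H <- matrix(rbinom(20 * 30, 1, runif(1, 0.2, 0.8)), 20, 30)
    h <- make_haps(H)
    core <- sample(5:25, 1)
    for (al in 0:1) {
      e <- ehh(h, core, al)
      if (!attr(e, "defined")) next
      left <- e$ehh[e$side == "left"]
      right <- e$ehh[e$side == "right"]
      expect_true(all(diff(rev(left)) <= 1e-12))   # outward from core
      expect_true(all(diff(right) <= 1e-12))
    }
  }
})

test_that("a missing call drops the haplotype from that point outward", {
  # 4 carriers; hap 4 has a missing call at the second marker right of core
  H <- cbind(rep(1L, 4), c(0L, 0L, 1L, 0L), c(0L, 0L, 1L, NA),
             c(0L, 0L, 1L, 0L))
  h <- make_haps(H)
  e <- ehh(h, core = 1, core_allele = 1L, side = "right")
  r <- e$ehh[e$side == "right"]
  expect_equal(e$n_haps[e$side == "right"], c(4L, 3L, 3L))
  # after the drop the denominator is C(3,2); groups are {1,2} and {3}
  expect_equal(r[2], (choose(2, 2)) / choose(3, 2))
})

test_that("iHH integrates the EHH curve by trapezoids with truncation", {
  # flat curve cut at exactly 1 Mb each side
  curve <- data.frame(pos = c(-1e6, 0, 1e6) + 5e6,
                      side = c("left", "core", "right"),
                      ehh = c(1, 1, 1), n_haps = 6L)
  attr(curve, "defined") <- TRUE
  v <- ihh(curve, truncation = 0.05)
  expect_equal(v$ihh, 2e6)
  expect_true(v$edge)          # never fell below the cutoff
  # two-point trapezoid: (0,1) -> (1000,0.5) one side
  curve2 <- data.frame(pos = c(5e6, 5e6 + 1000),
                       side = c("core", "right"), ehh = c(1, 0.5),
                       n_haps = 6L)
  attr(curve2, "defined") <- TRUE
  expect_equal(ihh(curve2)$right, 750)
  # refinement: interpolated points do not change the integral
  curve3 <- data.frame(pos = c(5e6, 5e6 + 500, 5e6 + 1000),
                       side = c("core", "right", "right"),
                       ehh = c(1, 0.75, 0.5), n_haps = 6L)
  attr(curve3, "defined") <- TRUE
  expect_equal(ihh(curve3)$right, 750)
})

test_that("truncation stops the integral at the first sub-cutoff point", {
  curve <- data.frame(pos = c(5e6, 5e6 + 1000, 5e6 + 2000, 5e6 + 3000),
                      side = c("core", "right", "right", "right"),
                      ehh = c(1, 0.5, 0.02, 0.5), n_haps = 6L)
  attr(curve, "defined") <- TRUE
  v <- ihh(curve, truncation = 0.05)
  expect_equal(v$right, 750 + 1000 * (0.5 + 0.02) / 2)
  expect_false(v$edge)
})

test_that("unstandardised iHS is antisymmetric in the ancestral labels", {
  set.seed(12)
  sh <- sim_haplotypes(n_chrom = 1, chrom_length_bp = 2e7,
                       snp_per_chrom = 120, generations = 40, N = 60,
                       seed = 12)
  h <- sh$haps
  s1 <- ihs_scan(h, maf = 0.1)
  h2 <- h
  h2$ancestral <- 1L - h$ancestral
  s2 <- ihs_scan(h2, maf = 0.1)
  shared <- intersect(s1$locus[!s1$excluded], s2$locus[!s2$excluded])
  i1 <- s1$uihs[match(shared, s1$locus)]
  i2 <- s2$uihs[match(shared, s2$locus)]
  expect_equal(i1, -i2, tolerance = 1e-12)
})

test_that("standardised scores have mean 0 and sd 1 within bins", {
  sh <- sim_haplotypes(n_chrom = 2, chrom_length_bp = 2e7,
                       snp_per_chrom = 150, generations = 50, N = 80,
                       seed = 29)
  res <- ihs_scan(sh$haps, maf = 0.05)
  for (b in unique(res$bin)) {
    v <- res$ihs[res$bin == b & !res$excluded]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && sd(v) > 0) {
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sd(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("candidate regions merge nearby hits within the window", {
  ihs <- data.frame(locus = paste0("L", 1:5), chrom = "chr1",
                    pos = c(1e6, 1.2e6, 1.4e6, 5e6, 5.1e6),
                    ihs = c(4.5, -4.2, 4.1, 0.2, 4.8))
  reg <- candidate_regions(ihs, threshold = 4, merge_kb = 500)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_snps, c(3L, 1L))
  expect_equal(reg$start_bp, c(1e6, 5.1e6))
})
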