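test_that("inbreeding matches textbook values on crafted pedigrees", {
  # offspring of two unrelated founders
  p1 <- pedigree(c("a", "b", "x"), c(NA, NA, "a"), c(NA, NA, "b"))
  expect_equal(unname(inbreeding(p1)["x"]), 0)
  # offspring of full sibs whose parents are unrelated founders
  p2 <- pedigree(c("a", "b", "s1", "s2", "x"),
                 c(NA, NA, "a", "a", "s1"),
                 c(NA, NA, "b", "b", "s2"))
  expect_equal(unname(inbreeding(p2)["x"]), 0.25)
  # parent-offspring mating
  p3 <- pedigree(c("a", "b", "d", "x"),
                 c(NA, NA, "a", "a"),
                 c(NA, NA, "b", "d"))
  expect_equal(unname(inbreeding(p3)["x"]), 0.25)
  # selfed-like double grandparent (half sibs mated)
  p4 <- pedigree(c("a", "b", "c", "h1", "h2", "x"),
                 c(NA, NA, NA, "a", "a", "h1"),
                 c(NA, NA, NA, "b", "c", "h2"))
  expect_equal(unname(inbreeding(p4)["x"]), 0.125)
})

test_that("recursive inbreeding equals the path-counting oracle on random pedigrees", {
  for (s in 1:30) {
    sp <- sim_pedigree(n_founders = 8, n_per_gen = 10,
                       generations = sample(3:6, 1), n_sires = 3,
                       n_dams = 4, seed = 9000 + s)
    expect_equal(inbreeding(sp$ped), inbreeding_paths(sp$ped),
                 tolerance = 1e-12)
  }
})

test_that("adding an unrelated founder never changes existing F", {
  sp <- sim_pedigree(n_founders = 6, n_per_gen = 8, generations = 4,
                     n_sires = 2, n_dams = 3, seed = 77)
  F1 <- inbreeding(sp$ped)
  ped2 <- pedigree(c(sp$ped$id, "newcomer"), c(sp$ped$sire, NA),
                   c(sp$ped$dam, NA))
  F2 <- inbreeding(ped2)
  expect_equal(F2[names(F1)], F1)
})

test_that("kinship diagonal and parent-offspring entries are consistent", {
  p <- pedigree(c("a", "b", "x"), c(NA, NA, "a"), c(NA, NA, "b"))
  K <- kinship(p)
  expect_equal(unname(diag(K)), rep(0.5, 3))
  expect_equal(K["a", "x"], 0.25)
  expect_equal(K, t(K))
})

test_that("pedigree construction rejects cycles and inserts missing parents", {
  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)), "cycle")
  expect_warning(p <- pedigree("x", "ghost_sire", NA), "founders")
  expect_true("ghost_sire" %in% p$id)
  expect_equal(p$generation[p$id == "x"], 1L)
})

test_that("per-generation inbreeding rate follows the cohort formula", {
  # two founders, full-sib line: F = 0, 0, 0.25, 0.375 along the line
  p <- pedigree(c("a", "b", "s1", "s2", "x1", "x2", "y"),
                c(NA, NA, "a", "a", "s1", "s1", "x1"),
                c(NA, NA, "b", "b", "s2", "s2", "x2"))
  d <- delta_f(p)
  expect_equal(d$mean_F, c(0, 0, 0.25, 0.375))
  expect_equal(d$delta_F[3], 0.25)              # (0.25-0)/(1-0)
  expect_equal(d$delta_F[4], (0.375 - 0.25) / 0.75)
  expect_error(delta_f(pedigree(c("a", "b"), c(NA, NA), c(NA, NA))),
               "single-cohort")
})

test_that("Ne from the inbreeding rate follows 1/(2 dF) with an undefined flag", {
  p <- pedigree(c("a", "b", "s1", "s2", "x1", "x2", "y"),
                c(NA, NA, "a", "a", "s1", "s1", "x1"),
                c(NA, NA, "b", "b", "s2", "s2", "x2"))
  ne1 <- ne_pedigree(p, n_transitions = 1)
  expect_equal(ne1$Ne, 1 / (2 * (0.125 / 0.75)))
  # flat F: rate zero, Ne undefined
  flat <- pedigree(c("a", "b", "c", "d"), c(NA, NA, "a", "a"),
                   c(NA, NA, "b", "b"))
  ne0 <- ne_pedigree(flat)
  expect_false(ne0$defined)
  expect_true(is.na(ne0$Ne))
})

test_that("closed-form Ne arithmetic holds", {
  expect_equal(1 / (2 * 0.01), 50)
  p <- sim_pedigree(n_founders = 12, n_per_gen = 12, generations = 4,
                    n_sires = 5, n_dams = 6, seed = 123)$ped
  ne <- ne_pedigree(p)
  if (ne$defined) expect_equal(ne$Ne, 1 / (2 * ne$delta_F))
})

test_that("pedigree completeness counts complete and equivalent generations", {
  # both parents known, all grandparents unknown
  p1 <- pedigree(c("a", "b", "x"), c(NA, NA, "a"), c(NA, NA, "b"))
  gc1 <- generation_counts(p1)
  expect_equal(gc1$complete[gc1$id == "x"], 1L)
  expect_equal(gc1$equivalent[gc1$id == "x"], 1)
  # full two-generation ancestry
  p2 <- pedigree(c("g1", "g2", "g3", "g4", "a", "b", "x"),
                 c(NA, NA, NA, NA, "g1", "g3", "a"),
                 c(NA, NA, NA, NA, "g2", "g4", "b"))
  gc2 <- generation_counts(p2)
  expect_equal(gc2$complete[gc2$id == "x"], 2L)
  expect_equal(gc2$equivalent[gc2$id == "x"], 2)
  # parents known, exactly one grandparent known: 2*(1/2) + 1*(1/4)
  p3 <- pedigree(c("g1", "a", "b", "x"),
                 c(NA, "g1", NA, "a"), c(NA, NA, NA, "b"))
  gc3 <- generation_counts(p3)
  expect_equal(gc3$complete[gc3$id == "x"], 1L)
  expect_equal(gc3$equivalent[gc3$id == "x"], 1.25)
  # equivalent >= complete everywhere on a random pedigree
  sp <- sim_pedigree(n_founders = 8, n_per_gen = 10, generations = 5,
                     n_sires = 3, n_dams = 4, seed = 55)
  gc <- generation_counts(sp$ped)
  expect_true(all(gc$equivalent >= gc$complete))
})

test_that("forced consanguineous matings plant the expected inbreeding", {
  sp <- sim_pedigree(n_founders = 12, n_per_gen = 12, generations = 4,
                     n_sires = 4, n_dams = 5,
                     forced = data.frame(generation = 3, type = "fullsib"),
                     seed = 31)
  Fv <- inbreeding(sp$ped)
  expect_gte(unname(Fv["G3_1"]), 0.25)   # the forced full-sib offspring
  expect_equal(sp$truth$F, inbreeding_paths(sp$ped))
})
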