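---
title: "Population-genetic methods in herdstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic methods in herdstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdstat)
```

herdstat characterises small, closed livestock populations — local breeds
under conservation management — from three kinds of data: pedigree records,
multiallelic microsatellite panels, and genome-wide SNP genotypes. This
vignette explains the statistical machinery, the defaults and their
rationale, what the built-in simulators emulate, and the numerical
conventions that matter when results are compared across tools.

## Pedigree inbreeding and effective population size

The inbreeding coefficient F of an individual is the probability that its
two alleles at a neutral autosomal locus are identical by descent, which
equals the kinship (coancestry) of its parents. `inbreeding()` evaluates
the classic recursion

* f(x, x) = (1 + F(x)) / 2,
* f(x, y) = (f(x, sire(y)) + f(x, dam(y))) / 2, descending through the
  later-born individual,

with memoisation, so only the kinships actually needed are computed.
Unknown parents are treated as unique, unrelated, non-inbred founders —
the standard assumption, which means estimates are conditional on founder
non-relatedness and will understate inbreeding when founders were in fact
related. `inbreeding_paths()` implements Wright's original path-counting
formulation (sum over common ancestors and non-overlapping path pairs of
(1/2)^(n1+n2+1) (1 + F(ancestor))). It is exponential in pedigree depth and
exists as an independent cross-check: the test suite verifies both
algorithms agree exactly on hundreds of random pedigrees.

Generation cohorts are assigned deterministically: founders are generation
0 and every other animal is one generation after its latest-born known
parent. The per-generation inbreeding rate is
dF_t = (F_t − F_(t−1)) / (1 − F_(t−1)) on cohort means, and
`ne_pedigree()` reports Ne = 1 / (2 dF). Because a single cohort transition
in a small herd is noisy, the default averages the last three transitions
(configurable down to one). Herdbook software offers several dF variants
(cohort-based and regression-on-equivalent-generations); the cohort rule is
the default here because it is deterministic and directly testable, and the
choice is exposed rather than hidden.

Pedigree quality is summarised by complete generations (the deepest g for
which all 2^g ancestors are known) and equivalent complete generations
(sum of (1/2)^depth over all known ancestors); the latter always dominates
the former.

## Allele-frequency statistics

`locus_stats()` reports, per population and locus: observed
heterozygosity, expected heterozygosity 1 − sum(p²) (with the unbiased
2n/(2n−1) correction reported alongside), allele counts, the effective
allele number 1 / sum(p²), and the polymorphism information content
PIC = 1 − sum(p²) − sum_{i<j} 2 p_i² p_j². PIC and the informativeness
measure below use plain frequency-based definitions (no small-sample
correction), matching their published closed forms; per-breed summary
tables default to the unbiased heterozygosity. Null-allele frequency uses
Brookfield's first estimator (He − Ho)/(1 + He) by default, with
Chakraborty's (He − Ho)/(He + Ho) as an option — field tools differ here
and rarely say which they use, so both are explicit.

`pop_summary()` adds private alleles (alleles observed in exactly one
population — only meaningful with two or more populations), their mean
within-population frequency, the percentage of polymorphic loci (a locus
counts as polymorphic when at least two alleles are observed, with no
minor-allele-frequency floor), nucleotide diversity (the probability that
two distinct sampled allele copies differ,
1 − sum n_a(n_a−1) / (n(n−1)), averaged over loci), and the mean major
allele frequency.

F-statistics follow Weir & Cockerham (1984): per locus and allele the
three variance components a (among populations), b (among individuals
within populations) and c (within individuals) are computed from sample
sizes, allele frequencies and heterozygote frequencies, and multi-locus
estimates are ratios of sums over alleles and loci. F_ST at its boundaries
behaves as expected (0 for identical frequencies, 1 for populations fixed
for alternative alleles), and pairwise F_ST simply restricts the estimator
to each population pair. Nei's (1972) standard distance is computed as a
ratio of sums of gene identities across loci (per-locus averaging is an
option; the ratio-of-sums form is the default because it is the variant
most software computes). Natural logarithms are used throughout, both in
Nei's D and in Rosenberg's informativeness for assignment

I_n = sum over alleles ( −p̄ ln p̄ + sum over K populations (p ln p) / K ),

with the 0·ln 0 = 0 convention. Multiallelic markers carry more assignment
information per locus than biallelic SNPs; the simulated six-breed study in
the test suite reproduces that separation of panel means.

## Isolation by distance

`mantel_test()` correlates the upper triangles of two distance matrices
and assesses significance by simultaneous row/column permutation, with the
add-one estimator p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1) — the p-value
can never be zero, and the classic cross-product statistic Z = sum g·d is
reported for reference. `mantel_correlogram()` cuts geographic pair
distances (great-circle, mean Earth radius 6371 km) into classes with
equal pair counts, tests the genetic distance matrix against each class
membership indicator, and flips the sign so positive values mean genetic
similarity within a class. Per-class one-sided p-values are reported raw
and Holm-corrected, since a correlogram is a family of tests.

## Runs of homozygosity

`call_roh()` finds, per individual and chromosome, all maximal stretches
of consecutive SNPs with no heterozygote (configurable), at most five
missing calls, at least 25 homozygous SNPs and a span of at least 1 Mb —
the array-era caller parameterisation for ~45 kb marker spacing. Runs are
trimmed so both endpoints are homozygous non-missing calls: endpoints must
be evidence-backed, and missing calls count toward neither the SNP minimum
nor the endpoints. Intervals are 1-based inclusive with length
end − start + 1, matching the source formats; BED export converts to
0-based half-open. There is no maximum inter-SNP gap by default (an
optional `max_gap` exists because sparse regions can inflate spans).

Two numerical conventions deserve a note. First, length classes are
left-closed: short [1.0, 2.5), medium [2.5, 5.0), long [5.0, Inf) Mb — a
2.5 Mb run is medium. The 1.0 Mb short-class floor equals the caller's
minimum length, so no called run is ever unclassified. Second, when the
missing-call budget makes two maximal candidate windows overlap, the
longer window wins (ties: the left-most), so one individual's segments on
a chromosome never overlap and F_ROH never double-counts. The caller is
verified segment-for-segment against a brute-force oracle that enumerates
every possible window.

F_ROH is the fraction of the autosomal genome covered by an individual's
runs; the default autosome length, 2,330,828,850 bp, is the Sscrofa11.1
autosome total, and per-class F_ROH values add up to the overall value.
ROH islands are maximal stretches of consecutive SNPs whose within-breed
ROH incidence reaches a threshold; the default threshold of 0.5 is a
detection floor (islands of interest in livestock typically show 70–98%
sharing, and the peak incidence is reported per island so stricter
filtering can happen downstream).

## LD-based historical Ne

Sved's relation E[r²] ≈ 1 / (α + 4Nc) links background linkage
disequilibrium at recombination distance c to effective size roughly
1/(2c) generations ago. `pairwise_r2()` computes r² as the squared
Pearson correlation of 0/1/2 dosages (the unphased composite estimator)
for same-chromosome pairs inside a 0.05–4 Mb window after a 0.05 MAF
filter, one population at a time. `ne_from_ld()` bins pairs into 30
log-spaced distance bins, subtracts the finite-sample expectation
β = 1/n (1/(2n) for phased haplotypes) from each bin's mean r², maps mean
distance to Morgans (linear map, 1 cM/Mb default) and applies a
recombination-rate adjustment before inverting Sved's relation with α = 1
(α = 2.2 available for the mutation-adjusted variant). The adjustment
default is the quadratic finite-recombination form c' = d(2 − d)/2
attributed to Sved & Feldman's 1973 treatment; Haldane and Kosambi maps
and no correction are also available, and all agree with the identity map
as c → 0 (unit-tested). The published descriptions of array-era Ne tools
do not pin the exact functional form, so it is a visible, switchable
choice here rather than a hard-coded one. Bins whose adjusted r² would
imply non-positive Ne are flagged rather than reported.

Trajectories are reported oldest (shortest distances) to newest, t
strictly decreasing with bin distance. On a constant-size simulation
(N = 100, ten 5-Mb chromosomes at 1 cM/Mb, 120 generations) the 10–50
generations-ago bins recover N well within the 35% band the test suite
asserts; a step decline (200 → 50 at 20 generations ago) reproduces the
qualitative recent-below-ancient pattern. Estimates at very short
distances (very old t) reflect founder linkage equilibrium in these
simulations and are expected to drift upward; real data has its own
ancient-history caveats.

## EHH, iHH and iHS

For a core SNP and allele, EHH at marker x is the probability that two
random carrier haplotypes are identical at every marker between the core
and x, computed as sum C(n_g, 2) / C(n, 2) over the distinct haplotype
strings. On complete data the curve starts at 1 and never increases
outward (a property test asserts this on random tables). A haplotype with
a missing call inside the interval is dropped from the computation — both
numerator and denominator — from that marker outward on that side; with
missing data the recomputed ratio can in principle tick upward when a
singleton group drops out, which is why the monotonicity guarantee is
stated for complete data only.

iHH integrates the EHH curve over physical distance by trapezoids on each
side, stopping at the first marker below the 0.05 cutoff (that final
trapezoid is included); integration over genetic distance is a known
alternative but physical distance is used here and stated as such. A side
that reaches the edge of the data above the cutoff is integrated to the
edge and flagged — such censored loci stay in the scan but carry the flag.
The unstandardised score ln(iHH_ancestral / iHH_derived) is standardised
to mean 0, sd 1 within 20 equal-width derived-allele-frequency bins
(configurable; tools differ across versions), which removes the strong
frequency dependence of haplotype age. Ancestral alleles must be supplied
explicitly; for real data without outgroup information a major-allele
fallback must be a conscious, labelled decision by the user. Candidate
loci (default |iHS| ≥ 4) are merged into regions within 500 kb.

## The simulators and what passing tests mean

`sim_pedigree()`, `sim_breeds()`, `sim_transect()` and
`sim_haplotypes()` generate every input the pipeline consumes, with ground
truth attached, and are ordinary tested exports, not test scaffolding.
They are deliberately simple Wright–Fisher machinery: discrete
generations, binomial/multinomial drift of breed allele frequencies from a
shared ancestral pool (Uniform(0.05, 0.95) SNP frequencies; 4–18 allele
Dirichlet microsatellites, echoing the ~10 alleles per locus of real
panels), Hardy–Weinberg genotype sampling within breeds, and a
forward-in-time diploid simulator with Poisson recombination for
haplotype-level analyses. A stepping-stone drift chain on a 1-D transect
provides a known positive distance–divergence relation for the
isolation-by-distance tests.

Study-scale defaults mirror a six-breed design with per-breed sample
sizes in the 17–50 range, drift sizes of a few tens, ~24 microsatellites
and SNP maps at array-like density. Test problem sizes (for example ten
5-Mb chromosomes for LD work, or two 100-Mb chromosomes for the neutral
iHS calibration) are chosen so that each statistical property is measured
with adequate replication while the whole suite stays quick to run.

What the simulators do not emulate: real LD block structure and
recombination hotspots, ascertainment bias of SNP arrays, genotyping
error, overlapping generations, migration and admixture between breeds.
Passing recovery tests therefore demonstrates the estimators are correct
under their own model assumptions — not that those assumptions hold in
any particular herdbook population.

Three simulator-side choices matter for interpretation:

* **Sweep conditioning.** A selective sweep starts from a single founder
  copy (hard sweep) unless a standing-variation frequency is requested;
  if the selected allele is lost it is re-seeded in one haplotype, i.e.
  the simulation conditions on establishment, and by default the
  simulation ends the generation the target frequency is reached, so the
  sampled haplotypes carry a fresh sweep. The realised frequency is
  always recorded in the ground truth.
* **Rescaled sweep replicates.** iHS localisation is a large-population
  phenomenon: in a population of effective size ~100 the background
  haplotype homozygosity is as long-ranged as a swept haplotype and no
  method can separate them. The sweep-recovery tests therefore use the
  standard rescaling trick (N → N/λ, s → sλ, r → rλ leaves the dynamics
  invariant): N = 500 with a 20-fold recombination scale emulates a hard
  sweep in a population of ~10,000 at 1 cM/Mb. The neutral calibration,
  by contrast, runs at N = 100 on 100-Mb chromosomes, where the
  standardised neutral scores come out slightly platykurtic (tail
  fraction |iHS| > 2 around 0.04 against the Gaussian 0.0455) — an
  honest property of small populations that the calibration test's band
  accommodates.
* **Random ancestral labels.** The haplotype simulator labels the
  ancestral allele at random (the swept allele is always derived), so
  neutral derived-allele frequencies span the full range as they do in
  outgroup-polarised real data; labelling the major allele ancestral
  would empty the high-frequency bins and distort iHS standardisation.

## Degenerate inputs and tie-breaks

Monomorphic loci carry zero diversity, PIC 0 and effective allele number
1, and are excluded (with a logged count) from LD work. F-statistics with
no variance at all are flagged undefined rather than returned as 0/0.
Populations with identical frequency profiles get Nei distance 0; a pair
with zero shared gene identity gets an infinite distance and a flag.
Constant distance matrices make the Mantel statistic undefined (flagged).
Duplicate-sample resolution drops the later-listed member of a flagged
pair, a deliberate tie-break that is logged. Quantile-based correlogram
classes can collapse under tied distances; collapsed or under-filled
classes are skipped with a warning rather than silently merged.

## Known limitations

Pedigree Ne assumes discrete generations and founder non-relatedness.
The LD-Ne machinery ignores admixture and overlapping generations, and
the linear bp→Morgan map is a first approximation to a real recombination
landscape. iHS needs phased haplotypes and an ancestral-allele assignment,
and its integration is over physical distance. ROH islands are detected
within populations only; no cross-breed consensus regions are computed.
None of the analyses model genotyping error explicitly — quality control
is the caller's responsibility via `filter_genotypes()`.
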