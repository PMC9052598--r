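#' Analysis configuration defaults
#'
#' Bundles the tunable thresholds shared across the pipeline into one
#' validated list, so a whole study can be parameterised in one place and
#' passed around. All values default to the package-wide defaults.
#'
#' @param roh_min_length_bp,roh_min_snps,roh_max_missing,roh_max_het ROH
#'   caller parameters (see [call_roh()]).
#' @param autosome_length_bp Autosome length for F_ROH (default
#'   2,330,828,850 bp, the Sscrofa11.1 autosomes).
#' @param roh_class_bounds_bp Inner ROH length-class boundaries
#'   (default 2.5 and 5 Mb).
#' @param island_threshold ROH island incidence threshold (default 0.5).
#' @param maf MAF floor for LD and iHS analyses (default 0.05).
#' @param ld_min_dist,ld_max_dist LD distance window in bp.
#' @param mantel_permutations Mantel permutation count (default 999).
#' @param duplicate_concordance Duplicate-sample flagging threshold.
#' @param seed RNG seed recorded with the configuration.
#' @return A validated named list of class `analysis_config`.
#' @export
analysis_config <- function(roh_min_length_bp = 1e6, roh_min_snps = 25,
                            roh_max_missing = 5, roh_max_het = 0,
                            autosome_length_bp = 2330828850,
                            roh_class_bounds_bp = c(2.5e6, 5e6),
                            island_threshold = 0.5,
                            maf = 0.05, ld_min_dist = 5e4,
                            ld_max_dist = 4e6,
                            mantel_permutations = 999,
                            duplicate_concordance = 0.95,
                            seed = 1L) {
  cfg <- list(roh_min_length_bp = roh_min_length_bp,
              roh_min_snps = roh_min_snps,
              roh_max_missing = roh_max_missing,
              roh_max_het = roh_max_het,
              autosome_length_bp = autosome_length_bp,
              roh_class_bounds_bp = roh_class_bounds_bp,
              island_threshold = island_threshold,
              maf = maf, ld_min_dist = ld_min_dist,
              ld_max_dist = ld_max_dist,
              mantel_permutations = mantel_permutations,
              duplicate_concordance = duplicate_concordance,
              seed = as.integer(seed))
  pos <- c("roh_min_length_bp", "roh_min_snps", "autosome_length_bp",
           "island_threshold", "ld_min_dist", "ld_max_dist",
           "mantel_permutations", "duplicate_concordance")
  for (nm in pos) if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$roh_max_missing < 0 || cfg$roh_max_het < 0)
    stop("ROH tolerance counts must be non-negative")
  if (any(diff(cfg$roh_class_bounds_bp) <= 0))
    stop("ROH class boundaries must be strictly increasing")
  if (cfg$ld_min_dist >= cfg$ld_max_dist)
    stop("LD window is empty")
  structure(cfg, class = c("analysis_config", "list"))
}
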