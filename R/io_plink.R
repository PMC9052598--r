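#' Read PLINK PED/MAP text files
#'
#' Whitespace-delimited PED (six mandatory columns, then two allele columns
#' per locus) with its companion MAP (chromosome, locus name, genetic
#' position, bp position). Alleles are recoded per locus to integers in
#' first-seen order (the first non-missing allele label encountered becomes
#' code 0, the next distinct label code 1, ...); the PLINK missing allele
#' `"0"` becomes `NA`. The family identifier column is used as the
#' population label.
#'
#' @param ped_path Path to the `.ped` file.
#' @param map_path Path to the `.map` file.
#' @return A [genotab()]; locus order follows the MAP file.
#' @export
read_plink <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chrom", "name", "cm", "pos")
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  L <- nrow(map)
  want <- 6 + 2 * L
  bad <- which(lengths(toks) != want)
  if (length(bad))
    stop("PED row ", bad[1], " has ", lengths(toks)[bad[1]],
         " fields, expected ", want)
  m <- do.call(rbind, toks)
  pop <- m[, 1]
  ids <- m[, 2]
  raw1 <- m[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  raw2 <- m[, 6 + 2 * seq_len(L), drop = FALSE]
  n <- nrow(m)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  alleles <- vector("list", L)
  for (j in seq_len(L)) {
    v <- c(rbind(raw1[, j], raw2[, j]))     # row-major: sample order preserved
    lab <- unique(v[v != "0"])              # first-seen coding
    code <- match(v, lab) - 1L
    a1[, j] <- code[seq(1, 2 * n, by = 2)]
    a2[, j] <- code[seq(2, 2 * n, by = 2)]
    alleles[[j]] <- lab
  }
  loci <- data.frame(name = map$name, chrom = map$chrom, pos = map$pos,
                     marker_class = "snp", stringsAsFactors = FALSE)
  loci$alleles <- alleles
  genotab(a1, a2, ids, pop, loci)
}

#' Write a genotype table as PLINK PED/MAP
#'
#' Inverse of [read_plink()]: integer codes are translated back through the
#' stored allele labels (or printed as code + 1 when no labels are stored),
#' missing calls become `"0 0"`.
#'
#' @param x A [genotab()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_plink <- function(x, ped_path, map_path) {
  L <- n_loci(x)
  map <- data.frame(chrom = x$loci$chrom, name = x$loci$name, cm = 0,
                    pos = ifelse(is.na(x$loci$pos), 0L, x$loci$pos))
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  lab <- x$loci$alleles
  code2lab <- function(code, j) {
    if (is.null(lab) || is.null(lab[[j]])) as.character(code + 1L)
    else lab[[j]][code + 1L]
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_samples(x))) {
    g <- character(2 * L)
    for (j in seq_len(L)) {
      if (is.na(x$a1[i, j])) {
        g[2 * j - 1] <- "0"; g[2 * j] <- "0"
      } else {
        g[2 * j - 1] <- code2lab(x$a1[i, j], j)
        g[2 * j]     <- code2lab(x$a2[i, j], j)
      }
    }
    writeLines(paste(c(x$pop[i], x$sample_ids[i], "0", "0", "0", "-9", g),
                     collapse = " "), con)
  }
  invisible(x)
}
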