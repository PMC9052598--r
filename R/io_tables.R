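#' Read a pedigree CSV
#'
#' Columns `id`, `sire`, `dam`; `0`, `NA` or empty mark unknown parents.
#'
#' @param path CSV path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  names(d) <- tolower(names(d))
  stopifnot(all(c("id", "sire", "dam") %in% names(d)))
  pedigree(d$id, d$sire, d$dam)
}

#' Read a sample-to-population assignment CSV
#'
#' Columns `sample`, `population`.
#'
#' @param path CSV path.
#' @return Named character vector (names = sample ids).
#' @export
read_pop_table <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  names(d) <- tolower(names(d))
  stopifnot(all(c("sample", "population") %in% names(d)))
  stats::setNames(d$population, d$sample)
}

#' Read population geographic coordinates
#'
#' Columns `population`, `lat`, `lon` (decimal degrees).
#'
#' @param path CSV path.
#' @return Data frame with one row per population.
#' @export
read_geo_table <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  stopifnot(all(c("population", "lat", "lon") %in% names(d)))
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180))
    stop("coordinates out of range")
  d
}

#' Write genomic segments as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention on output.
#'
#' @param segments Data frame with columns `chrom`, `start_bp`, `end_bp` and
#'   optionally a `name` column (e.g. ROH segments or islands).
#' @param path Output path.
#' @param name_col Column used for the BED name field (default `"sample"`
#'   when present).
#' @return Invisibly, `segments`.
#' @export
write_bed <- function(segments, path, name_col = NULL) {
  if (is.null(name_col))
    name_col <- intersect(c("sample", "population", "name"),
                          names(segments))[1]
  nm <- if (!is.na(name_col) && !is.null(name_col)) segments[[name_col]]
        else "."
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp,
                    name = nm)
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(segments)
}

#' Write a statistics table as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(x)
}
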