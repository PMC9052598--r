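#' Read a Genepop genotype file
#'
#' Genepop 4 dialect: a title line, one locus name per line (or one
#' comma-separated line), then `POP`-delimited population blocks of
#' `sample_id ,  <genotypes>` rows. Genotypes use a consistent 2- or 3-digit
#' allele coding; allele sizes are kept as the integer codes, `00`/`000`
#' alleles mark the call as missing. Populations are labelled `pop_1`,
#' `pop_2`, ... in file order.
#'
#' @param path Path to the Genepop file.
#' @return A [genotab()] of microsatellite loci (no map positions).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP line")
  locus_lines <- body[seq_len(first_pop - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  recs <- body[seq(first_pop, length(body))]
  pop_idx <- cumsum(toupper(trimws(recs)) == "POP")
  rows <- recs[toupper(trimws(recs)) != "POP"]
  row_pop <- pop_idx[toupper(trimws(recs)) != "POP"]
  ids <- character(length(rows))
  toks <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed Genepop record: ", rows[i])
    ids[i] <- trimws(parts[1])
    toks[[i]] <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                          "[ \t]+")[[1]]
    if (length(toks[[i]]) != L)
      stop("record for ", ids[i], " has ", length(toks[[i]]),
           " genotypes, expected ", L)
  }
  widths <- unique(nchar(unlist(toks)))
  if (length(widths) != 1 || !(widths %in% c(4L, 6L)))
    stop("inconsistent allele digit width in Genepop file")
  w <- widths / 2L
  n <- length(rows)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- toks[[i]]
    x1 <- as.integer(substr(g, 1, w))
    x2 <- as.integer(substr(g, w + 1, 2 * w))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  loci <- data.frame(name = locus_names, chrom = NA_character_,
                     pos = NA_integer_, marker_class = "microsatellite",
                     stringsAsFactors = FALSE)
  genotab(a1, a2, ids, paste0("pop_", row_pop), loci)
}

#' Write a genotype table as a Genepop file
#'
#' Three-digit allele coding; missing calls become `000000`. Samples are
#' grouped into `POP` blocks following the table's population labels (in
#' first-appearance order).
#'
#' @param x A [genotab()] whose allele codes fit in three digits.
#' @param path Output path.
#' @param title Title line (default a short description).
#' @return Invisibly, `x`.
#' @export
write_genepop <- function(x, path, title = "herdstat genepop export") {
  if (max(c(x$a1, x$a2), na.rm = TRUE) > 999)
    stop("allele codes exceed the 3-digit Genepop coding")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci$name, con)
  for (p in unique(x$pop)) {
    writeLines("POP", con)
    for (i in which(x$pop == p)) {
      g <- ifelse(is.na(x$a1[i, ]), "000000",
                  sprintf("%03d%03d", x$a1[i, ], x$a2[i, ]))
      writeLines(paste0(x$sample_ids[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(x)
}
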