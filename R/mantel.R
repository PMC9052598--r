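#' Mantel test between two distance matrices
#'
#' Pearson correlation `r_m` of the upper-triangle entries, with significance
#' from simultaneous row/column permutations of one matrix. The p-value uses
#' the add-one estimator `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`
#' (one-sided "greater" by default), so it can never be exactly zero. The
#' classic cross-product statistic `Z_m = sum_ij g_ij * d_ij` is reported
#' alongside.
#'
#' @param g,d Symmetric matrices with matching dimension (and matching
#'   dimnames when present; `d` is reordered to `g`'s labels).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional RNG seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List of class `mantel_test` with `r`, `Z`, `p_value`, `n_perm`,
#'   `alternative`, and `defined` (`FALSE` when either matrix is constant,
#'   in which case `r` is `NA`).
#' @export
mantel_test <- function(g, d, n_perm = 999, seed = NULL,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 99)
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(g); d <- as.matrix(d)
  if (!all(dim(g) == dim(d))) stop("matrix dimensions differ")
  if (!is.null(rownames(g)) && !is.null(rownames(d))) {
    if (!setequal(rownames(g), rownames(d))) stop("matrix labels differ")
    d <- d[rownames(g), rownames(g)]
  }
  n <- nrow(g)
  ut <- upper.tri(g)
  gv <- g[ut]
  Z <- sum(g * d)
  if (stats::sd(gv) == 0 || stats::sd(d[ut]) == 0) {
    return(structure(list(r = NA_real_, Z = Z, p_value = NA_real_,
                          n_perm = n_perm, alternative = alternative,
                          defined = FALSE), class = "mantel_test"))
  }
  r_obs <- stats::cor(gv, d[ut])
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_perm[b] <- stats::cor(gv, d[idx, idx][ut])
  }
  p <- switch(alternative,
    greater   = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
    less      = (1 + sum(r_perm <= r_obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1))
  structure(list(r = r_obs, Z = Z, p_value = p, n_perm = n_perm,
                 alternative = alternative, defined = TRUE),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, Z = %.4g, p = %.4g (%s, %d permutations)\n",
              x$r, x$Z, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Great-circle distances between populations
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0 km.
#'
#' @param geo Data frame with columns `population`, `lat`, `lon`
#'   (decimal degrees), as from [read_geo_table()].
#' @return Symmetric distance matrix in kilometres.
#' @export
geo_distances <- function(geo) {
  n <- nrow(geo)
  D <- matrix(0, n, n, dimnames = list(geo$population, geo$population))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- geosphere::distHaversine(
        c(geo$lon[i], geo$lat[i]), c(geo$lon[j], geo$lat[j]),
        r = 6371000) / 1000
    }
  }
  D
}

#' Mantel correlogram for isolation by distance
#'
#' Geographic pair distances are cut into `n_classes` classes with equal pair
#' counts (quantile bounds). For each class the Mantel statistic between the
#' genetic distance matrix and the class-membership indicator matrix is
#' computed; its sign is inverted so that positive values mean genetic
#' similarity within the class (positive spatial autocorrelation at that
#' distance). One-sided permutation p-values are reported raw and
#' Holm-corrected.
#'
#' @param g Genetic distance matrix labelled by population.
#' @param geo Geographic coordinate table ([read_geo_table()] layout), or a
#'   precomputed distance matrix in km.
#' @param n_classes Number of distance classes (>= 2; default 5).
#' @param n_perm Permutations per class (default 999).
#' @param seed Optional RNG seed.
#' @return Data frame of class `mantel_correlogram`: per class `class`,
#'   `d_min`, `d_max`, `n_pairs`, `r`, `p_value`, `p_holm` (classes with
#'   fewer than 2 pairs are reported with `NA` and a warning).
#' @export
mantel_correlogram <- function(g, geo, n_classes = 5, n_perm = 999,
                               seed = NULL) {
  stopifnot(n_classes >= 2)
  if (!is.null(seed)) set.seed(seed)
  D <- if (is.matrix(geo)) geo else geo_distances(geo)
  g <- as.matrix(g)
  if (!is.null(rownames(g)) && !is.null(rownames(D)))
    D <- D[rownames(g), rownames(g)]
  n <- nrow(g)
  ut <- upper.tri(g)
  dv <- D[ut]
  br <- unique(stats::quantile(dv, probs = seq(0, 1, length.out = n_classes + 1)))
  if (length(br) - 1 < n_classes)
    warning("tied distances reduced the number of usable classes to ",
            length(br) - 1)
  cls <- cut(dv, breaks = br, include.lowest = TRUE, labels = FALSE)
  gv <- g[ut]
  res <- lapply(seq_len(length(br) - 1), function(k) {
    member <- cls == k
    if (sum(member) < 2 || stats::sd(member) == 0) {
      warning("distance class ", k, " has fewer than 2 usable pairs; skipped")
      return(data.frame(class = k, d_min = br[k], d_max = br[k + 1],
                        n_pairs = sum(member), r = NA_real_,
                        p_value = NA_real_))
    }
    ind <- matrix(0, n, n)
    ind[ut][member] <- 1
    ind <- ind + t(ind)
    r_obs <- -stats::cor(gv, ind[ut])
    r_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      r_perm[b] <- -stats::cor(gv, ind[idx, idx][ut])
    }
    p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
    data.frame(class = k, d_min = br[k], d_max = br[k + 1],
               n_pairs = sum(member), r = r_obs, p_value = p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
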