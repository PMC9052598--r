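#' Pedigree object
#'
#' A sire/dam pedigree stored as a topologically ordered record table with an
#' integer generation cohort per individual (founders are generation 0, every
#' other individual is one generation after its latest-born known parent).
#' Parents referenced but never listed as records are inserted as founders
#' with a warning. Cycles are an error.
#'
#' @param id Character vector of individual identifiers (unique).
#' @param sire,dam Parent identifiers; `NA`, `""` or `"0"` mean unknown.
#' @return An object of class `pedigree`: a data frame with columns `id`,
#'   `sire`, `dam`, `generation`, in topological order (parents before
#'   offspring).
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  clean <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "" | p == "0"] <- NA_character_
    p
  }
  sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(id)) stop("duplicate individual id: ",
                              id[duplicated(id)][1])
  missing_par <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(missing_par)) {
    warning("inserting ", length(missing_par),
            " referenced but unlisted parent(s) as founders")
    id <- c(missing_par, id)
    sire <- c(rep(NA_character_, length(missing_par)), sire)
    dam <- c(rep(NA_character_, length(missing_par)), dam)
  }
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  # Kahn topological sort; also detects cycles
  indeg <- integer(n)
  kids <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) {
      if (!is.na(p)) {
        indeg[k] <- indeg[k] + 1L
        kids[[p]] <- c(kids[[p]], k)
      }
    }
  }
  order_idx <- integer(0)
  queue <- which(indeg == 0L)
  gen <- rep(NA_integer_, n)
  gen[queue] <- 0L
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    order_idx <- c(order_idx, k)
    for (ch in kids[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        gen[ch] <- 1L + max(gen[si[ch]], gen[di[ch]], na.rm = TRUE)
        queue <- c(queue, ch)
      }
    }
  }
  if (length(order_idx) < n) {
    bad <- id[setdiff(seq_len(n), order_idx)][1]
    stop("pedigree contains a cycle involving individual ", bad)
  }
  out <- data.frame(id = id[order_idx], sire = sire[order_idx],
                    dam = dam[order_idx], generation = gen[order_idx],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      max(x$generation) + 1, "generation cohorts\n")
  invisible(x)
}

# parent indices in topological order (NA = unknown)
.ped_parents <- function(ped) {
  list(si = match(ped$sire, ped$id), di = match(ped$dam, ped$id))
}

#' Individual inbreeding coefficients
#'
#' The inbreeding coefficient F of an individual is the probability that its
#' two alleles at a neutral locus are identical by descent, equal to the
#' kinship between its parents. Kinship is computed by the recursive
#' coancestry rules with memoisation: f(x, x) = (1 + F(x)) / 2, and
#' f(x, y) = (f(x, sire(y)) + f(x, dam(y))) / 2 descending through the
#' later-born of the pair; an unknown parent contributes 0 (unknown parents
#' are unique, unrelated, non-inbred founders).
#'
#' @param ped A [pedigree()].
#' @return Named numeric vector of F values in `[0, 1]` (names = ids).
#' @seealso [inbreeding_paths()] for the independent path-counting algorithm.
#' @export
inbreeding <- function(ped) {
  n <- nrow(ped)
  pp <- .ped_parents(ped)
  si <- pp$si; di <- pp$di
  Fv <- numeric(n)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + Fv[a])
    } else {
      # b is later in topological order, so descend through b's parents
      0.5 * (kin(a, si[b]) + kin(a, di[b]))
    }
    memo[[key]] <- val
    val
  }
  for (k in seq_len(n)) Fv[k] <- kin(si[k], di[k])
  stats::setNames(Fv, ped$id)
}

#' Full additive kinship matrix
#'
#' Coancestry (kinship) between all pairs, computed by the same recursion as
#' [inbreeding()].
#'
#' @param ped A [pedigree()].
#' @return Symmetric matrix of kinship coefficients with ids as dimnames.
#' @export
kinship <- function(ped) {
  n <- nrow(ped)
  pp <- .ped_parents(ped)
  si <- pp$si; di <- pp$di
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (b in seq_len(n)) {
    fs <- if (is.na(si[b])) numeric(n) else K[, si[b]]
    fd <- if (is.na(di[b])) numeric(n) else K[, di[b]]
    idx <- seq_len(b - 1)
    K[idx, b] <- K[b, idx] <- 0.5 * (fs[idx] + fd[idx])
    Fb <- if (is.na(si[b]) || is.na(di[b])) 0 else K[si[b], di[b]]
    K[b, b] <- 0.5 * (1 + Fb)
  }
  K
}

#' Inbreeding by exhaustive path counting
#'
#' Wright's original path-counting formulation, implemented independently of
#' the recursive kinship rules: F(i) is the sum over common ancestors A of
#' the sire and dam of i, and over all pairs of ancestral paths that meet
#' only at A, of (1/2)^(n_sire_path + n_dam_path + 1) * (1 + F(A)). Ancestor
#' inbreeding F(A) is resolved in topological order. Exponential in pedigree
#' depth; intended as a cross-check on small pedigrees.
#'
#' @param ped A [pedigree()].
#' @return Named numeric vector of F values.
#' @export
inbreeding_paths <- function(ped) {
  n <- nrow(ped)
  pp <- .ped_parents(ped)
  si <- pp$si; di <- pp$di
  # all ancestor paths from individual k: list of integer vectors,
  # each path starts at k and walks up to some ancestor (inclusive)
  paths_up <- function(k) {
    out <- list(k)
    for (p in c(si[k], di[k])) {
      if (!is.na(p)) {
        for (pp2 in paths_up(p)) out[[length(out) + 1]] <- c(k, pp2)
      }
    }
    out
  }
  Fv <- numeric(n)
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    if (is.na(s) || is.na(d)) next
    ps <- paths_up(s)
    pd <- paths_up(d)
    tot <- 0
    for (a in ps) {
      for (b in pd) {
        anc <- a[length(a)]
        if (anc != b[length(b)]) next
        # paths must share no individual except the common ancestor
        if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
        n1 <- length(a) - 1L
        n2 <- length(b) - 1L
        tot <- tot + 0.5^(n1 + n2 + 1) * (1 + Fv[anc])
      }
    }
    Fv[k] <- tot
  }
  stats::setNames(Fv, ped$id)
}

#' Per-generation inbreeding rate
#'
#' Cohort mean inbreeding F_t is averaged per generation; the inbreeding rate
#' for generation t (t >= 1) is
#' `delta_F_t = (F_t - F_(t-1)) / (1 - F_(t-1))`.
#'
#' @param ped A [pedigree()].
#' @param F Optional precomputed [inbreeding()] vector.
#' @return Data frame with columns `generation`, `n`, `mean_F`, `delta_F`
#'   (`NA` for generation 0).
#' @export
delta_f <- function(ped, F = NULL) {
  if (is.null(F)) F <- inbreeding(ped)
  gens <- sort(unique(ped$generation))
  if (length(gens) < 2)
    stop("inbreeding rate is undefined for a single-cohort pedigree")
  mF <- vapply(gens, function(g) mean(F[ped$generation == g]), numeric(1))
  nG <- vapply(gens, function(g) sum(ped$generation == g), numeric(1))
  dF <- c(NA, (mF[-1] - mF[-length(mF)]) / (1 - mF[-length(mF)]))
  data.frame(generation = gens, n = as.integer(nG), mean_F = mF,
             delta_F = dF)
}

#' Pedigree effective population size
#'
#' `Ne = 1 / (2 * delta_F)`, with the inbreeding rate taken as the mean of
#' the per-generation rates over the last `n_transitions` cohort transitions
#' (default 3, or fewer when the pedigree is shallower) to damp
#' single-cohort sampling noise. A non-positive rate gives an undefined Ne.
#'
#' @param ped A [pedigree()].
#' @param n_transitions Number of most recent cohort transitions averaged
#'   (default 3); use 1 for the final transition only.
#' @return List with elements `Ne` (numeric, `NA` when undefined), `defined`
#'   (logical flag), `delta_F` (the averaged rate) and `rates` (the
#'   per-transition rates used).
#' @export
ne_pedigree <- function(ped, n_transitions = 3) {
  d <- delta_f(ped)
  rates <- d$delta_F[!is.na(d$delta_F)]
  k <- min(n_transitions, length(rates))
  used <- rates[seq(length(rates) - k + 1, length(rates))]
  dF <- mean(used)
  if (dF <= 0)
    return(list(Ne = NA_real_, defined = FALSE, delta_F = dF, rates = used))
  list(Ne = 1 / (2 * dF), defined = TRUE, delta_F = dF, rates = used)
}

#' Pedigree completeness per individual
#'
#' Complete generations: the largest g such that all `2^g` ancestors at depth
#' up to g are known (an individual with an unknown parent has 0). Equivalent
#' complete generations: the sum over every known ancestor of `(1/2)^depth`.
#'
#' @param ped A [pedigree()].
#' @return Data frame with columns `id`, `complete`, `equivalent`.
#' @export
generation_counts <- function(ped) {
  n <- nrow(ped)
  pp <- .ped_parents(ped)
  si <- pp$si; di <- pp$di
  comp <- integer(n)
  eqv <- numeric(n)
  for (k in seq_len(n)) {  # topological order: parents already done
    s <- si[k]; d <- di[k]
    comp[k] <- if (is.na(s) || is.na(d)) 0L
               else 1L + min(comp[s], comp[d])
    eqv[k] <- sum(vapply(c(s, d), function(p)
      if (is.na(p)) 0 else 0.5 * (1 + eqv[p]), numeric(1)))
  }
  data.frame(id = ped$id, complete = comp, equivalent = eqv,
             stringsAsFactors = FALSE)
}
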