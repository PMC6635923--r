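## Weir & Cockerham (1984) theta: variance-component F-statistics for
## co-dominant data, the estimator used throughout the package wherever
## FST is reported.

## Sum the W&C components a (among populations), b (among individuals
## within populations) and c (within individuals) over all alleles of
## all loci. `grps` is a list of n x L x 2 arrays (one per population).
.wcComponents <- function(grps) {
  r0 <- length(grps)
  L <- dim(grps[[1]])[2]
  A <- B <- C <- 0
  for (l in seq_len(L)) {
    mats <- lapply(grps, function(arr) {
      a1 <- arr[, l, 1]; a2 <- arr[, l, 2]
      ok <- !is.na(a1)
      cbind(a1[ok], a2[ok])
    })
    ni <- vapply(mats, nrow, 1L)
    use <- ni > 0
    if (sum(use) < 2) next
    mats <- mats[use]; ni <- ni[use]
    r <- length(mats)
    allAlleles <- sort(unique(unlist(mats)))
    if (length(allAlleles) < 2) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in allAlleles) {
      p <- vapply(mats, function(m) mean(m == al), 0)
      h <- vapply(mats, function(m)
        mean((m[, 1] == al) != (m[, 2] == al)), 0)
      pbar <- sum(ni * p) / (r * nbar)
      s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h) / (r * nbar)
      if (nbar <= 1) next
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
           (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  c(a = A, b = B, c = C)
}

#' Multi-locus Weir--Cockerham theta over a set of groups
#'
#' Ratio of summed variance components `sum(a) / sum(a + b + c)` over all
#' alleles and loci. Negative estimates are reported as computed.
#'
#' @param ds a [GenotypeDataset-class].
#' @param level `"population"` or `"species"`.
#' @return single numeric theta (NA when undefined).
#' @export
weirFst <- function(ds, level = c("population", "species")) {
  grps <- .splitByGroup(ds, match.arg(level))
  if (length(grps) < 2) stop("theta needs at least 2 groups")
  comp <- .wcComponents(grps)
  tot <- sum(comp)
  if (!is.finite(tot) || tot == 0) return(NA_real_)
  unname(comp["a"] / tot)
}

#' Pairwise Weir--Cockerham FST matrix
#'
#' Multi-locus theta for every pair of groups. Pairs with no co-typed
#' polymorphic locus are NA (flagged via attribute `undefined`).
#'
#' @param ds a [GenotypeDataset-class].
#' @param level `"population"` or `"species"`.
#' @return a [DistancePair-class] of kind `"fst"`.
#' @export
pairwiseFst <- function(ds, level = c("population", "species")) {
  level <- match.arg(level)
  grps <- .splitByGroup(ds, level)
  k <- length(grps)
  if (k < 2) stop("pairwise FST needs at least 2 groups")
  m <- matrix(0, k, k, dimnames = list(names(grps), names(grps)))
  und <- character()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    comp <- .wcComponents(grps[c(i, j)])
    tot <- sum(comp)
    th <- if (!is.finite(tot) || tot == 0) NA_real_ else
      unname(comp["a"] / tot)
    if (is.na(th))
      und <- c(und, paste(names(grps)[c(i, j)], collapse = "-"))
    m[i, j] <- m[j, i] <- th
  }
  out <- new("DistancePair", matrix = m, kind = "fst")
  attr(out, "undefined") <- und
  out
}

#' Linearize an FST matrix as FST / (1 - FST)
#'
#' Negative estimates are clamped to 0 before linearization. Entries at
#' or above 1 make the transform infinite; supply `clampAt` (e.g. 0.999)
#' to cap them, otherwise an error explains the remedy.
#'
#' @param fst a [DistancePair-class] of kind `"fst"`.
#' @param clampAt optional numeric < 1.
#' @return a [DistancePair-class] of kind `"linearized_fst"`.
#' @export
linearizeFst <- function(fst, clampAt = NULL) {
  stopifnot(is(fst, "DistancePair"), fst@kind == "fst")
  m <- fst@matrix
  m[m < 0] <- 0
  if (any(m >= 1, na.rm = TRUE)) {
    if (is.null(clampAt))
      stop("FST of 1 cannot be linearized; rerun with clampAt = 0.999")
    m[m >= clampAt] <- clampAt
  }
  new("DistancePair", matrix = m / (1 - m), kind = "linearized_fst")
}

setMethod("show", "DistancePair", function(object) {
  cat("DistancePair (", object@kind, "), ", nrow(object@matrix),
      " groups\n", sep = "")
  print(round(object@matrix, 4))
  invisible(object)
})

#' @describeIn linearizeFst extract the raw matrix of a DistancePair.
#' @param x a [DistancePair-class].
#' @export
distMatrix <- function(x) {
  stopifnot(is(x, "DistancePair"))
  x@matrix
}
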