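## Population-structure surfaces: isolation-by-distance Mantel test,
## shared-allele neighbour-joining, genotype PCA, and directional
## relative migration.

#' Isolation by distance: Mantel test of linearized FST vs geography
#'
#' Correlates `FST / (1 - FST)` with great-circle distance (km) between
#' population coordinates. The Mantel statistic is the Pearson
#' correlation of the off-diagonal vectors; the one-tailed p-value uses
#' the `(hits + 1) / (nPerm + 1)` rule (via `vegan::mantel`).
#'
#' @param fst a [DistancePair-class] of kind `"fst"` (or already
#'   `"linearized_fst"`).
#' @param coords data.frame with columns `pop`, `lat`, `lon`, covering
#'   all populations of `fst`.
#' @param nPerm permutations (default 999).
#' @param seed RNG seed.
#' @param clampAt passed to [linearizeFst()] for FST entries at 1.
#' @return list with `r`, `p`, `nPerm` and the two distance objects.
#' @export
mantelIBD <- function(fst, coords, nPerm = 999, seed = NULL,
                      clampAt = NULL) {
  stopifnot(is(fst, "DistancePair"))
  lin <- if (fst@kind == "fst") linearizeFst(fst, clampAt) else fst
  pops <- rownames(lin@matrix)
  if (!all(pops %in% coords$pop))
    stop("coordinates missing for: ",
         paste(setdiff(pops, coords$pop), collapse = ", "))
  coords <- coords[match(pops, coords$pop), ]
  geo <- geographicDistances(coords)
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(as.dist(lin@matrix), as.dist(geo@matrix),
                      method = "pearson", permutations = nPerm)
  list(r = unname(mt$statistic), p = unname(mt$signif), nPerm = nPerm,
       linearizedFst = lin, geographic = geo)
}

#' Shared-allele distance between individuals
#'
#' `D_sa(i, j) = 1 - mean over co-typed loci of (shared alleles / 2)`,
#' where the shared-allele count of two diploid genotypes is
#' `sum_a min(copies_i(a), copies_j(a))` (0, 1 or 2).
#'
#' @param ds a [GenotypeDataset-class].
#' @return symmetric matrix of distances between individuals.
#' @export
sharedAlleleDistance <- function(ds) {
  a <- ds@alleles
  n <- dim(a)[1]; L <- dim(a)[2]
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sh <- 0; used <- 0
      for (l in seq_len(L)) {
        x1 <- a[i, l, 1]; x2 <- a[i, l, 2]
        y1 <- a[j, l, 1]; y2 <- a[j, l, 2]
        if (is.na(x1) || is.na(y1)) next
        used <- used + 1
        s <- (x1 == y1) + (x2 == y2)
        s2 <- (x1 == y2) + (x2 == y1)
        sh <- sh + max(s, s2) / 2
        ## max over pairings equals sum_a min(copies): both orderings
        ## cover the two possible one-to-one matchings of two copies.
      }
      D[i, j] <- D[j, i] <- if (used > 0) 1 - sh / used else NA_real_
    }
  }
  dimnames(D) <- list(rownames(a), rownames(a))
  D
}

#' Unrooted neighbour-joining tree on the shared-allele distance
#'
#' @param ds a [GenotypeDataset-class] with >= 4 individuals.
#' @param file optional path; when given the tree is also written as
#'   Newick.
#' @return an `ape::phylo` tree; tip labels are
#'   `<species>|<population>|<index>`.
#' @export
sharedAlleleNJ <- function(ds, file = NULL) {
  if (nInd(ds) < 4) stop("neighbour-joining needs at least 4 individuals")
  D <- sharedAlleleDistance(ds)
  labs <- paste(speciesLabels(ds), ds@popLabels, seq_len(nInd(ds)),
                sep = "|")
  dimnames(D) <- list(labs, labs)
  tr <- ape::nj(as.dist(D))
  if (!is.null(file)) ape::write.tree(tr, file)
  tr
}

#' Genotype principal component analysis
#'
#' Individuals are encoded as per-allele dosages (0/1/2 copies per
#' allele per locus), columns are mean-centred (missing calls are
#' mean-imputed per column) and eigen-decomposed. Scores are
#' deterministic up to sign.
#'
#' @param ds a [GenotypeDataset-class] with >= 3 individuals.
#' @return list with `scores` (individuals x PCs), `explained`
#'   (proportion of variance per PC), `sdev`, and the `species` /
#'   `pop` factors for plotting.
#' @export
genotypePCA <- function(ds) {
  if (nInd(ds) < 3) stop("PCA needs at least 3 individuals")
  a <- ds@alleles
  n <- dim(a)[1]; L <- dim(a)[2]
  cols <- list()
  for (l in seq_len(L)) {
    als <- sort(unique(c(a[, l, ])))
    for (al in als) {
      d <- (a[, l, 1] == al) + (a[, l, 2] == al)
      cols[[length(cols) + 1L]] <- d
    }
  }
  X <- do.call(cbind, cols)
  ## mean-impute missing dosages
  for (k in seq_len(ncol(X))) {
    mk <- is.na(X[, k])
    if (any(mk)) X[mk, k] <- mean(X[, k], na.rm = TRUE)
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  ev <- sv$d^2
  expl <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, explained = expl,
       sdev = sv$d / sqrt(max(1, n - 1)),
       species = speciesLabels(ds), pop = ds@popLabels)
}

## Per-locus allele-frequency vectors of a group (named by allele).
.freqList <- function(arr) {
  L <- dim(arr)[2]
  lapply(seq_len(L), function(l) {
    cn <- .alleleCounts(arr, l)
    if (!sum(cn)) return(NULL)
    setNames(as.numeric(cn) / sum(cn), names(cn))
  })
}

## Nei GST or Jost's D between two per-locus frequency lists (plain
## estimators, equal weight per group; used for the pooled-reference
## migration construct where the pool is a frequency mixture).
.freqDifferentiation <- function(fa, fb, metric) {
  HsL <- HtL <- rep(NA_real_, length(fa))
  for (l in seq_along(fa)) {
    if (is.null(fa[[l]]) || is.null(fb[[l]])) next
    als <- union(names(fa[[l]]), names(fb[[l]]))
    pa <- setNames(rep(0, length(als)), als)
    pb <- pa
    pa[names(fa[[l]])] <- fa[[l]]
    pb[names(fb[[l]])] <- fb[[l]]
    HsL[l] <- mean(c(1 - sum(pa^2), 1 - sum(pb^2)))
    HtL[l] <- 1 - sum(((pa + pb) / 2)^2)
  }
  Hs <- mean(HsL, na.rm = TRUE); Ht <- mean(HtL, na.rm = TRUE)
  if (!is.finite(Ht) || Ht <= 0) return(NA_real_)
  if (metric == "gst") {
    (Ht - Hs) / Ht
  } else {                      # Jost's D
    ((Ht - Hs) / (1 - Hs)) * 2  # k/(k-1) with k = 2 groups
  }
}

## mixture of two frequency lists (the hypothetical pool)
.freqPool <- function(fa, fb) {
  lapply(seq_along(fa), function(l) {
    if (is.null(fa[[l]]) || is.null(fb[[l]])) return(NULL)
    als <- union(names(fa[[l]]), names(fb[[l]]))
    pa <- setNames(rep(0, length(als)), als)
    pb <- pa
    pa[names(fa[[l]])] <- fa[[l]]
    pb[names(fb[[l]])] <- fb[[l]]
    (pa + pb) / 2
  })
}

#' Directional relative migration (pooled-reference method)
#'
#' For each ordered pair of groups (a, b) a hypothetical migrant pool
#' of the two is formed (equal-weight mixture of their allele
#' frequencies); the differentiation between the donor group and the
#' pool is converted into a relative number-of-migrants analogue
#' `Nm = 0.25 (1/d - 1)` and the full directed matrix is rescaled to a
#' maximum of 1. A group whose genes dominate the shared pool (low
#' differentiation from it, typically the more diverse group) is
#' inferred to be the main donor, so low `d(a, pool)` gives a large
#' migration a -> b.
#'
#' @param ds a [GenotypeDataset-class].
#' @param metric `"gst"` (Nei) or `"d"` (Jost).
#' @param level `"species"` (default) or `"population"`.
#' @param nBoot optional bootstrap replicates over individuals; when
#'   > 0, attribute `"boot"` holds the replicate array.
#' @param seed RNG seed for the bootstrap.
#' @return directed matrix `m[a, b]` = relative migration a -> b
#'   (diagonal NA, max 1); monomorphic pairs are NA.
#' @export
relativeMigration <- function(ds, metric = c("gst", "d"),
                              level = c("species", "population"),
                              nBoot = 0, seed = NULL) {
  metric <- match.arg(metric); level <- match.arg(level)
  grps <- .splitByGroup(ds, level)
  k <- length(grps)
  if (k < 2) stop("relative migration needs at least 2 groups")
  one <- function(grps) {
    m <- matrix(NA_real_, k, k, dimnames = list(names(grps), names(grps)))
    fl <- lapply(grps, .freqList)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pool <- .freqPool(fl[[i]], fl[[j]])
      dI <- .freqDifferentiation(fl[[i]], pool, metric)
      dJ <- .freqDifferentiation(fl[[j]], pool, metric)
      toNm <- function(d) {
        if (is.na(d)) return(NA_real_)
        d <- max(d, 1e-6)
        0.25 * (1 / d - 1)
      }
      m[i, j] <- toNm(dI)   # i -> j: donor i vs pool
      m[j, i] <- toNm(dJ)
    }
    mx <- max(m, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) m / mx else m
  }
  res <- one(grps)
  if (nBoot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- array(NA_real_, dim = c(k, k, nBoot))
    for (b in seq_len(nBoot)) {
      gb <- lapply(grps, function(arr) {
        idx <- sample.int(dim(arr)[1], replace = TRUE)
        arr[idx, , , drop = FALSE]
      })
      boot[, , b] <- one(gb)
    }
    attr(res, "boot") <- boot
  }
  res
}
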