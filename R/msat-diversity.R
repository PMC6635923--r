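## Nuclear-microsatellite diversity statistics: observed/expected
## heterozygosity, rarefied allelic richness, private alleles and the
## inbreeding coefficient FIS. Missing calls are excluded per locus
## (pairwise-complete); a locus with no calls in a group is skipped for
## that group.

## Per-group allele count table for one locus: named integer vector of
## gene-copy counts. `arr` is an n x L x 2 array.
.alleleCounts <- function(arr, locus) {
  x <- c(arr[, locus, 1], arr[, locus, 2])
  x <- x[!is.na(x)]
  if (!length(x)) return(integer())
  table(x)
}

## Ho and unbiased He per locus for one group's array; NA where a locus
## has no data.
.hetOneGroup <- function(arr) {
  L <- dim(arr)[2]
  Ho <- He <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    a1 <- arr[, l, 1]; a2 <- arr[, l, 2]
    ok <- !is.na(a1)
    if (!any(ok)) next
    Ho[l] <- mean(a1[ok] != a2[ok])
    cnt <- table(c(a1[ok], a2[ok]))
    He[l] <- .neiUnbiased(cnt)
    if (is.na(He[l])) He[l] <- 0  # single gene copy: treat as fixed
  }
  list(Ho = Ho, He = He)
}

#' Observed and expected heterozygosity
#'
#' Per group (population, or species with individuals pooled), `Ho` is
#' the fraction of heterozygous calls and `He` is Nei's unbiased expected
#' heterozygosity `(2n/(2n-1)) (1 - sum p_i^2)` per locus, averaged over
#' loci. Missing calls are excluded per locus; loci with no data in a
#' group are skipped.
#'
#' @param ds a [GenotypeDataset-class].
#' @param level `"population"` or `"species"`.
#' @return data.frame with columns `group`, `n`, `Ho`, `He`.
#' @examples
#' a <- array(c(100L, 100L, 100L, 102L), dim = c(2, 1, 2))
#' heterozygosities(GenotypeDataset(a, pop = c("p1", "p1")))
#' @export
heterozygosities <- function(ds, level = c("population", "species")) {
  level <- match.arg(level)
  grps <- .splitByGroup(ds, level)
  out <- lapply(names(grps), function(g) {
    h <- .hetOneGroup(grps[[g]])
    data.frame(group = g, n = dim(grps[[g]])[1],
               Ho = mean(h$Ho, na.rm = TRUE),
               He = mean(h$He, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies:
#' `A_R(locus) = sum_a [1 - C(N - N_a, g) / C(N, g)]`, reported as the
#' mean over loci per group. `g = "auto"` uses the smallest non-missing
#' gene-copy count over all groups and loci (so every locus/group can be
#' rarefied to the same depth); the value actually used is returned as an
#' attribute.
#'
#' @param ds a [GenotypeDataset-class].
#' @param g rarefaction size in gene copies (>= 2), or `"auto"`.
#' @param level `"population"` or `"species"`.
#' @return named numeric of per-group richness, attribute `g`.
#' @export
allelicRichness <- function(ds, g = "auto",
                            level = c("population", "species")) {
  level <- match.arg(level)
  grps <- .splitByGroup(ds, level)
  L <- nLoci(ds)
  copyCounts <- sapply(grps, function(arr)
    sapply(seq_len(L), function(l) sum(!is.na(arr[, l, ]))))
  if (identical(g, "auto")) {
    g <- min(copyCounts[copyCounts > 0])
  }
  g <- as.integer(g)
  if (g < 2) stop("rarefaction size g must be at least 2 gene copies")
  if (g > min(copyCounts[copyCounts > 0]))
    stop("g exceeds the smallest per-locus sample (",
         min(copyCounts[copyCounts > 0]), " gene copies)")
  ar <- sapply(grps, function(arr) {
    perLocus <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      cnt <- .alleleCounts(arr, l)
      if (!length(cnt)) next
      N <- sum(cnt)
      perLocus[l] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
    }
    mean(perLocus, na.rm = TRUE)
  })
  attr(ar, "g") <- g
  ar
}

#' Private alleles per group
#'
#' An allele is private to a group when it occurs in that group and in no
#' other group at the same locus. Returns the number of private
#' (locus, allele) pairs per group.
#'
#' @param ds a [GenotypeDataset-class].
#' @param level `"population"` or `"species"`.
#' @return named integer vector.
#' @export
privateAlleles <- function(ds, level = c("population", "species")) {
  level <- match.arg(level)
  grps <- .splitByGroup(ds, level)
  if (length(grps) < 2) stop("private alleles need at least 2 groups")
  L <- nLoci(ds)
  res <- setNames(integer(length(grps)), names(grps))
  for (l in seq_len(L)) {
    present <- lapply(grps, function(arr) names(.alleleCounts(arr, l)))
    allA <- unlist(present)
    uni <- names(which(table(allA) == 1L))
    for (g in names(grps)) {
      res[g] <- res[g] + sum(present[[g]] %in% uni)
    }
  }
  res
}

#' Inbreeding coefficient FIS
#'
#' Multilocus `FIS = 1 - mean(Ho) / mean(He)` per group, with Nei's
#' unbiased He. Negative values indicate heterozygote excess.
#'
#' @param ds a [GenotypeDataset-class].
#' @param level `"population"` or `"species"`.
#' @return named numeric vector.
#' @export
fisCoefficient <- function(ds, level = c("population", "species")) {
  level <- match.arg(level)
  h <- heterozygosities(ds, level)
  setNames(ifelse(h$He > 0, 1 - h$Ho / h$He, NA_real_), h$group)
}

#' Combined per-population and per-species diversity report
#'
#' Assembles sample size, Ho, He, rarefied allelic richness, private
#' allele count and FIS per population, plus pooled per-species rows.
#'
#' @param ds a [GenotypeDataset-class].
#' @param g rarefaction size for [allelicRichness()].
#' @return data.frame, one row per population then per species, with a
#'   `level` column.
#' @export
diversityReport <- function(ds, g = "auto") {
  mk <- function(level) {
    h <- heterozygosities(ds, level)
    ar <- allelicRichness(ds, g, level)
    ap <- if (length(unique(speciesMap(ds)[h$group])) >= 1 &&
              nrow(h) >= 2) privateAlleles(ds, level)
          else setNames(rep(NA_integer_, nrow(h)), h$group)
    fis <- fisCoefficient(ds, level)
    data.frame(level = level, h,
               AR = unname(ar[h$group]), AP = unname(ap[h$group]),
               FIS = unname(fis[h$group]))
  }
  pop <- mk("population")
  if (nlevels(speciesLabels(ds)) >= 2) rbind(pop, mk("species")) else pop
}
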