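## Hierarchical analysis of molecular variance (Excoffier-style
## sums-of-squares over squared inter-unit distances).
##
## For microsatellites the units are gene copies and the distance is
## allele identity (0/1), summed over loci (FST-like, matching the
## frequency-based estimates reported for nSSRs). For cpDNA the units
## are individuals and the squared distance is the pairwise number of
## differing characters between their haplotypes.

## ---- microsatellite engine -------------------------------------------

## Flatten a GenotypeDataset into valid gene copies:
##  gid: global allele id (unique per locus x allele), lid: locus id,
##  iid: individual id, locusOfGid: locus of each global allele id.
.msatCopies <- function(ds) {
  a <- ds@alleles
  n <- dim(a)[1]; L <- dim(a)[2]
  val <- c(a[, , 1], a[, , 2])                 # (ind x locus) twice
  iid <- rep(rep(seq_len(n), L), 2L)
  lid <- rep(rep(seq_len(L), each = n), 2L)
  ok <- !is.na(val)
  val <- val[ok]; iid <- iid[ok]; lid <- lid[ok]
  key <- paste(lid, val)
  gid <- match(key, unique(key))
  locusOfGid <- lid[!duplicated(key)]
  list(gid = gid, lid = lid, iid = iid, locusOfGid = locusOfGid,
       K = length(locusOfGid), n = n, L = L)
}

## Total within-set SS for a partition of individuals: sum over sets and
## loci of [C(m,2) - sum_a C(c_a,2)] / m with m the set's gene copies at
## the locus.
.msatSS <- function(cp, setOfInd, S) {
  setCopy <- setOfInd[cp$iid]
  cnt <- tabulate(cp$gid + (setCopy - 1L) * cp$K, nbins = cp$K * S)
  cntM <- matrix(cnt, nrow = cp$K, ncol = S)
  same <- rowsum(cntM * (cntM - 1) / 2, cp$locusOfGid)   # L x S
  m <- rowsum(cntM, cp$locusOfGid)                       # L x S
  ss <- ifelse(m > 1, (m * (m - 1) / 2 - same) / m, 0)
  sum(ss)
}

## ---- cpDNA engine ----------------------------------------------------

## hapOfInd: haplotype index per individual; D: squared-distance matrix.
.cpSS <- function(hapOfInd, D, setOfInd, S) {
  H <- nrow(D)
  cnt <- tabulate(hapOfInd + (setOfInd - 1L) * H, nbins = H * S)
  cntM <- matrix(cnt, nrow = H, ncol = S)
  ss <- 0
  for (s in seq_len(S)) {
    c_s <- cntM[, s]
    m <- sum(c_s)
    if (m > 1) ss <- ss + (crossprod(c_s, D %*% c_s) / 2) / m
  }
  as.numeric(ss)
}

## ---- shared variance-component algebra -------------------------------

## One-level: sets = populations. unitsPerPop counted in the same units
## as the SS (gene copies or individuals).
.amovaOneLevel <- function(ssT, ssWP, unitsPerPop) {
  P <- length(unitsPerPop); N <- sum(unitsPerPop)
  ssAP <- ssT - ssWP
  dfAP <- P - 1; dfWP <- N - P
  msAP <- ssAP / dfAP; msWP <- ssWP / dfWP
  nprime <- (N - sum(unitsPerPop^2) / N) / (P - 1)
  sc <- msWP
  sb <- (msAP - sc) / nprime
  list(table = data.frame(
         source = c("Among populations", "Within populations"),
         df = c(dfAP, dfWP), SS = c(ssAP, ssWP), MS = c(msAP, msWP)),
       sigma2 = c(among_pops = sb, within_pops = sc))
}

.amovaTwoLevel <- function(ssT, ssWG, ssWP, unitsPerPop, groupOfPop) {
  P <- length(unitsPerPop); N <- sum(unitsPerPop)
  gs <- split(unitsPerPop, groupOfPop)
  G <- length(gs)
  ng <- vapply(gs, sum, 0)
  ssAG <- ssT - ssWG
  ssAP <- ssWG - ssWP
  dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
  msAG <- ssAG / dfAG; msAP <- ssAP / dfAP; msWP <- ssWP / dfWP
  sumSq <- vapply(gs, function(x) sum(x^2), 0)
  nprime  <- (N - sum(sumSq / ng)) / (P - G)
  ndprime <- (sum(sumSq / ng) - sum(unitsPerPop^2) / N) / (G - 1)
  ntprime <- (N - sum(ng^2) / N) / (G - 1)
  sc <- msWP
  sb <- (msAP - sc) / nprime
  sa <- (msAG - sc - ndprime * sb) / ntprime
  list(table = data.frame(
         source = c("Among species", "Among populations within species",
                    "Within populations"),
         df = c(dfAG, dfAP, dfWP), SS = c(ssAG, ssAP, ssWP),
         MS = c(msAG, msAP, msWP)),
       sigma2 = c(among_species = sa, among_pops = sb, within_pops = sc))
}

.finishAmova <- function(core, nPerm, permStats, obsPhi, hierarchy) {
  s2raw <- core$sigma2
  s2 <- pmax(s2raw, 0)
  if (any(s2raw < 0))
    warning("negative variance component clamped to zero")
  pct <- 100 * s2 / sum(s2)
  tot <- sum(s2)
  phi <- if (length(s2) == 3) {
    c(PhiCT = s2[[1]] / tot,
      PhiSC = s2[[2]] / (s2[[2]] + s2[[3]]),
      PhiST = (s2[[1]] + s2[[2]]) / tot)
  } else c(PhiST = s2[[1]] / tot)
  pvals <- if (!is.null(permStats)) {
    vapply(names(permStats), function(k)
      (sum(permStats[[k]] >= obsPhi[[k]] - 1e-12) + 1) /
        (length(permStats[[k]]) + 1), 0)
  } else NULL
  structure(list(table = cbind(core$table, sigma2 = s2,
                               percent = pct),
                 sigma2raw = s2raw, phi = phi, p = pvals,
                 nPerm = nPerm, hierarchy = hierarchy),
            class = "peony_amova")
}

#' @export
print.peony_amova <- function(x, ...) {
  cat("AMOVA (", x$hierarchy, ")\n", sep = "")
  tb <- x$table
  tb$percent <- round(tb$percent, 2)
  print(tb, row.names = FALSE, digits = 5)
  cat("Phi:", paste(names(x$phi), round(x$phi, 4), collapse = "  "), "\n")
  if (!is.null(x$p))
    cat("P (", x$nPerm, " permutations): ",
        paste(names(x$p), signif(x$p, 3), collapse = "  "), "\n", sep = "")
  invisible(x)
}

## Raw phi statistics (no clamping) from a variance-component vector,
## used inside permutation loops.
.phiFromSigma <- function(s2) {
  tot <- sum(s2)
  if (length(s2) == 3) {
    c(PhiCT = s2[[1]] / tot,
      PhiSC = s2[[2]] / (s2[[2]] + s2[[3]]),
      PhiST = (s2[[1]] + s2[[2]]) / tot)
  } else c(PhiST = s2[[1]] / tot)
}

## ---- front-ends ------------------------------------------------------

#' @describeIn amova AMOVA on a microsatellite [GenotypeDataset-class].
#'   Units are gene copies, distance is allele identity summed over loci
#'   (FST-like). `hierarchy = "species/population"` gives the
#'   three-level analysis (among species / among populations within
#'   species / within populations); `"population"` the one-level
#'   analysis. Significance by permuting individuals (PhiST among all
#'   populations; PhiSC within species) and whole populations among
#'   species (PhiCT).
#' @param hierarchy `"species/population"` or `"population"`.
#' @param nPerm number of permutations (0 = none).
#' @param seed RNG seed for the permutations.
#' @export
setMethod("amova", "GenotypeDataset",
  function(x, hierarchy = c("species/population", "population"),
           nPerm = 10000, seed = NULL) {
    hierarchy <- match.arg(hierarchy)
    if (!is.null(seed)) set.seed(seed)
    cp <- .msatCopies(x)
    popOf <- as.integer(x@popLabels)
    P <- nlevels(x@popLabels)
    unitsPerPop <- 2 * tabulate(popOf, P)
    ssT <- .msatSS(cp, rep(1L, cp$n), 1L)
    ssWP <- .msatSS(cp, popOf, P)
    if (hierarchy == "population") {
      core <- .amovaOneLevel(ssT, ssWP, unitsPerPop)
      obs <- .phiFromSigma(core$sigma2)
      perm <- NULL
      if (nPerm > 0) {
        st <- numeric(nPerm)
        for (b in seq_len(nPerm)) {
          po <- popOf[sample.int(cp$n)]
          ssWPp <- .msatSS(cp, po, P)
          st[b] <- .phiFromSigma(
            .amovaOneLevel(ssT, ssWPp, unitsPerPop)$sigma2)[["PhiST"]]
        }
        perm <- list(PhiST = st)
      }
      return(.finishAmova(core, nPerm, perm, obs, hierarchy))
    }
    spOfPop <- speciesMap(x)[levels(x@popLabels)]
    grpOf <- as.integer(factor(spOfPop))
    G <- max(grpOf)
    if (G < 2) stop("species/population hierarchy needs >= 2 species")
    if (P == G)
      stop("every species has a single population; the nested stratum ",
           "is empty - use hierarchy = \"population\"")
    setG <- grpOf[popOf]
    ssWG <- .msatSS(cp, setG, G)
    core <- .amovaTwoLevel(ssT, ssWG, ssWP, unitsPerPop, grpOf)
    obs <- .phiFromSigma(core$sigma2)
    perm <- NULL
    if (nPerm > 0) {
      stST <- stSC <- stCT <- numeric(nPerm)
      for (b in seq_len(nPerm)) {
        ## PhiST: individuals permuted among all populations
        po <- popOf[sample.int(cp$n)]
        s2 <- .amovaTwoLevel(ssT, .msatSS(cp, grpOf[po], G),
                             .msatSS(cp, po, P), unitsPerPop,
                             grpOf)$sigma2
        stST[b] <- .phiFromSigma(s2)[["PhiST"]]
        ## PhiSC: individuals permuted among populations within species
        po2 <- popOf
        for (g in seq_len(G)) {
          ig <- which(setG == g)
          po2[ig] <- popOf[ig][sample.int(length(ig))]
        }
        s2 <- .amovaTwoLevel(ssT, ssWG, .msatSS(cp, po2, P),
                             unitsPerPop, grpOf)$sigma2
        stSC[b] <- .phiFromSigma(s2)[["PhiSC"]]
        ## PhiCT: whole populations permuted among species
        grpPerm <- grpOf[sample.int(P)]
        s2 <- .amovaTwoLevel(ssT, .msatSS(cp, grpPerm[popOf], G), ssWP,
                             unitsPerPop, grpPerm)$sigma2
        stCT[b] <- .phiFromSigma(s2)[["PhiCT"]]
      }
      perm <- list(PhiCT = stCT, PhiSC = stSC, PhiST = stST)
    }
    .finishAmova(core, nPerm, perm, obs, hierarchy)
  })

#' @describeIn amova AMOVA on a [HaplotypeTable-class]; units are
#'   individuals and the squared inter-individual distance is the number
#'   of differing characters between their haplotypes (requires the
#'   `diffs` slot).
#' @export
setMethod("amova", "HaplotypeTable",
  function(x, hierarchy = c("species/population", "population"),
           nPerm = 10000, seed = NULL) {
    hierarchy <- match.arg(hierarchy)
    if (!length(x@diffs)) stop("haplotype distance matrix required")
    if (!is.null(seed)) set.seed(seed)
    cnt <- x@counts
    D <- x@diffs[colnames(cnt), colnames(cnt), drop = FALSE]
    P <- nrow(cnt)
    ## expand individuals: for pop p, counts row p
    hapOf <- unlist(lapply(seq_len(P), function(p)
      rep(seq_len(ncol(cnt)), cnt[p, ])))
    popOf <- rep(seq_len(P), rowSums(cnt))
    n <- length(hapOf)
    unitsPerPop <- rowSums(cnt)
    ssT <- .cpSS(hapOf, D, rep(1L, n), 1L)
    ssWP <- .cpSS(hapOf, D, popOf, P)
    if (hierarchy == "population") {
      core <- .amovaOneLevel(ssT, ssWP, unitsPerPop)
      obs <- .phiFromSigma(core$sigma2)
      perm <- NULL
      if (nPerm > 0) {
        st <- numeric(nPerm)
        for (b in seq_len(nPerm)) {
          po <- popOf[sample.int(n)]
          st[b] <- .phiFromSigma(.amovaOneLevel(
            ssT, .cpSS(hapOf, D, po, P), unitsPerPop)$sigma2)[["PhiST"]]
        }
        perm <- list(PhiST = st)
      }
      return(.finishAmova(core, nPerm, perm, obs, hierarchy))
    }
    spOfPop <- x@speciesMap[rownames(cnt)]
    grpOf <- as.integer(factor(spOfPop))
    G <- max(grpOf)
    if (G < 2) stop("species/population hierarchy needs >= 2 species")
    if (P == G)
      stop("every species has a single population; the nested stratum ",
           "is empty - use hierarchy = \"population\"")
    setG <- grpOf[popOf]
    ssWG <- .cpSS(hapOf, D, setG, G)
    core <- .amovaTwoLevel(ssT, ssWG, ssWP, unitsPerPop, grpOf)
    obs <- .phiFromSigma(core$sigma2)
    perm <- NULL
    if (nPerm > 0) {
      stST <- stSC <- stCT <- numeric(nPerm)
      for (b in seq_len(nPerm)) {
        po <- popOf[sample.int(n)]
        s2 <- .amovaTwoLevel(ssT, .cpSS(hapOf, D, grpOf[po], G),
                             .cpSS(hapOf, D, po, P),
                             unitsPerPop, grpOf)$sigma2
        stST[b] <- .phiFromSigma(s2)[["PhiST"]]
        po2 <- popOf
        for (g in seq_len(G)) {
          ig <- which(setG == g)
          po2[ig] <- popOf[ig][sample.int(length(ig))]
        }
        s2 <- .amovaTwoLevel(ssT, ssWG, .cpSS(hapOf, D, po2, P),
                             unitsPerPop, grpOf)$sigma2
        stSC[b] <- .phiFromSigma(s2)[["PhiSC"]]
        grpPerm <- grpOf[sample.int(P)]
        s2 <- .amovaTwoLevel(ssT, .cpSS(hapOf, D, grpPerm[popOf], G),
                             ssWP, unitsPerPop, grpPerm)$sigma2
        stCT[b] <- .phiFromSigma(s2)[["PhiCT"]]
      }
      perm <- list(PhiCT = stCT, PhiSC = stSC, PhiST = stST)
    }
    .finishAmova(core, nPerm, perm, obs, hierarchy)
  })
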