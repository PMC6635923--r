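## Synthetic-data generators with known ground truth: microsatellite
## datasets from the coalescent engine, cpDNA alignments realizing a
## requested haplotype partition, and climate/occurrence sets with
## species-shifted niches.

#' Synthetic microsatellite dataset with recorded truth
#'
#' Thin wrapper around [simulateScenario()] that validates the scenario
#' id and stores the generating configuration as a
#' [TruthRecord-class].
#'
#' @param scenarioId scenario id (validated against the step's
#'   catalogue).
#' @param params a [ScenarioParams-class].
#' @param sampleConfig named diploid counts per population (>= 2 each).
#' @param nLoci number of loci (default 22).
#' @param seed integer seed.
#' @param step scenario-selection round (default 2).
#' @param speciesOf optional population -> lineage map.
#' @return list with `dataset` ([GenotypeDataset-class]) and `truth`
#'   ([TruthRecord-class]).
#' @export
makeMicrosatTruth <- function(scenarioId, params, sampleConfig,
                              nLoci = 22, seed, step = 2,
                              speciesOf = NULL) {
  spec <- scenarioSpec(scenarioId, step)   # validates the id
  if (any(sampleConfig < 2))
    stop("every population needs at least 2 diploid individuals")
  ds <- simulateScenario(spec, params, sampleConfig, nLoci, seed,
                         speciesOf = speciesOf)
  truth <- new("TruthRecord", scenarioId = as.integer(scenarioId),
               step = as.integer(step), params = params,
               seed = as.integer(seed),
               sampleSizes = setNames(as.integer(sampleConfig),
                                      names(sampleConfig)))
  list(dataset = ds, truth = truth)
}

#' Synthetic cpDNA alignment realizing a haplotype count map
#'
#' Haplotypes are placed on a random attachment genealogy: each new
#' haplotype differs from a randomly chosen existing one by at least
#' one new mutation, and the requested total number of mutations is
#' spread over the edges (infinite-sites: every mutation hits a fresh
#' column, so the alignment has exactly `nMutations` substitution
#' columns). Optionally one contiguous 5-bp indel is carried by one
#' non-root haplotype lineage. Collapsing the emitted alignment with
#' [collapseHaplotypes()] recovers exactly the requested count map.
#'
#' @param haplotypeCounts named list: population -> named integer
#'   vector (haplotype id -> count, all >= 1).
#' @param nSites alignment columns before the indel (default 2075).
#' @param nMutations substitution columns (default 37); must be at
#'   least the number of distinct haplotypes minus 1 and below
#'   `nSites`.
#' @param includeIndel add the single indel (default TRUE).
#' @param seed integer seed.
#' @param speciesMap named character population -> species; defaults to
#'   one species.
#' @return list with `alignment` (named character vector of gapped
#'   sequences), `assignments` (data.frame sample/pop/species) and
#'   `truth` (haplotype -> sequence map).
#' @export
makeCpdnaTruth <- function(haplotypeCounts, nSites = 2075,
                           nMutations = 37, includeIndel = TRUE,
                           seed, speciesMap = NULL) {
  set.seed(seed)
  haps <- unique(unlist(lapply(haplotypeCounts, names)))
  H <- length(haps)
  if (nMutations >= nSites)
    stop("nMutations must be smaller than nSites")
  if (H > nMutations + 1)
    stop("cannot realize ", H, " distinct haplotypes with ",
         nMutations, " mutations (need at least H - 1)")
  if (any(unlist(haplotypeCounts) < 1))
    stop("all requested counts must be >= 1")
  ## random attachment genealogy over haplotypes
  parent <- c(NA_integer_,
              if (H > 1) vapply(2:H, function(i)
                sample.int(i - 1, 1), 1L))
  edgeMut <- rep(0L, H)
  if (H > 1) {
    edgeMut[2:H] <- 1L
    extra <- nMutations - (H - 1)
  } else extra <- nMutations
  if (extra > 0 && H > 1) {
    add <- table(sample(2:H, extra, replace = TRUE))
    edgeMut[as.integer(names(add))] <-
      edgeMut[as.integer(names(add))] + as.integer(add)
  }
  ## note: with H == 1 any extra mutations are dropped (monomorphic)
  sites <- sample.int(nSites, sum(edgeMut))
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, nSites, replace = TRUE)
  seqM <- matrix(rep(root, H), nrow = H, byrow = TRUE)
  used <- 0L
  for (i in seq_len(H)) {
    if (i > 1) seqM[i, ] <- seqM[parent[i], ]
    if (edgeMut[i] > 0) {
      for (s in sites[used + seq_len(edgeMut[i])]) {
        seqM[i, s] <- sample(setdiff(bases, seqM[i, s]), 1)
      }
      used <- used + edgeMut[i]
    }
  }
  seqs <- apply(seqM, 1, paste, collapse = "")
  names(seqs) <- haps
  ## indel: a 5-bp gap carried by one non-root lineage (and its
  ## descendants)
  if (includeIndel && H > 1) {
    carrier <- sample(2:H, 1)
    inSub <- rep(FALSE, H)
    for (i in seq_len(H)) {
      j <- i
      while (!is.na(j)) {
        if (j == carrier) { inSub[i] <- TRUE; break }
        j <- parent[j]
      }
    }
    pos <- sample(setdiff(seq_len(nSites - 5L), unlist(lapply(sites,
                  function(s) (s - 5L):s))), 1)
    gap <- paste(rep("-", 5), collapse = "")
    for (i in which(inSub))
      substr(seqs[i], pos, pos + 4L) <- gap
  }
  ## emit individuals
  samples <- character(); pops <- character(); aln <- character()
  for (p in names(haplotypeCounts)) {
    v <- haplotypeCounts[[p]]
    for (h in names(v)) {
      for (k in seq_len(v[[h]])) {
        id <- paste(p, h, k, sep = "_")
        samples <- c(samples, id)
        pops <- c(pops, p)
        aln <- c(aln, seqs[[h]])
      }
    }
  }
  names(aln) <- samples
  if (is.null(speciesMap))
    speciesMap <- setNames(rep("sp1", length(haplotypeCounts)),
                           names(haplotypeCounts))
  assignments <- data.frame(sample = samples, pop = pops,
                            species = unname(speciesMap[pops]),
                            stringsAsFactors = FALSE)
  list(alignment = aln, assignments = assignments, truth = seqs)
}

#' Synthetic climate/occurrence dataset with species-shifted niches
#'
#' Occurrence climate values are multivariate normal around per-species
#' centroids separated by `centroidShifts` (in units of the
#' within-species SD, applied to the first axis by default or given as
#' a full species x variable matrix). Background points describe the
#' environment available across the study region: uniform over the
#' bounding box of all species' occurrences pooled, inflated by 25%
#' (each species' background sample is drawn from this common region,
#' so background divergence reflects sampling noise rather than the
#' planted centroid shift). Optionally `nRedundant` of the `nVars`
#' columns are near-duplicates of signal columns (correlation > 0.99),
#' to exercise the correlation filter.
#'
#' @param nSpecies number of species (default 3).
#' @param centroidShifts scalar, per-species vector, or species x
#'   variable matrix of centroid offsets (within-species SD units).
#' @param nOccurrences per-species occurrence count (recycled).
#' @param nBackground per-species background count (recycled).
#' @param nVars total climate variables.
#' @param seed integer seed.
#' @param nRedundant how many of `nVars` are near-copies (default 0).
#' @param withinSD within-species climate SD (default 1).
#' @return a [NicheDataset-class].
#' @export
makeNicheTruth <- function(nSpecies = 3, centroidShifts = 0,
                           nOccurrences = 30, nBackground = 200,
                           nVars = 8, seed, nRedundant = 0,
                           withinSD = 1) {
  if (nVars < 2) stop("nVars must be at least 2")
  if (!all(is.finite(centroidShifts))) stop("shifts must be finite")
  set.seed(seed)
  nOcc <- rep(nOccurrences, length.out = nSpecies)
  nBg <- rep(nBackground, length.out = nSpecies)
  nBase <- nVars - nRedundant
  if (nBase < 2) stop("nRedundant leaves fewer than 2 base variables")
  shifts <- matrix(0, nSpecies, nBase)
  if (is.matrix(centroidShifts)) {
    shifts[, seq_len(min(nBase, ncol(centroidShifts)))] <-
      centroidShifts[, seq_len(min(nBase, ncol(centroidShifts)))]
  } else {
    sv <- rep(centroidShifts, length.out = nSpecies)
    shifts[, 1] <- sv * (seq_len(nSpecies) - 1)
  }
  spNames <- paste0("sp", seq_len(nSpecies))
  vnames <- paste0("var", seq_len(nVars))
  occ <- list()
  for (s in seq_len(nSpecies)) {
    X <- sapply(seq_len(nBase), function(j)
      rnorm(nOcc[s], mean = shifts[s, j], sd = withinSD))
    X <- matrix(X, nrow = nOcc[s])
    lat <- rnorm(nOcc[s], 33 + s, 0.8)
    lon <- rnorm(nOcc[s], 106 + 2 * s, 0.8)
    occ[[s]] <- data.frame(species = spNames[s], lat = lat, lon = lon,
                           X)
  }
  occ <- do.call(rbind, occ)
  ## common background region: pooled bounding box inflated 25%
  pooled <- as.matrix(occ[, -(1:3), drop = FALSE])
  infl <- apply(pooled, 2, function(v) {
    r <- range(v)
    pad <- 0.25 * max(diff(r), 1e-6)
    c(r[1] - pad, r[2] + pad)
  })
  bg <- list()
  for (s in seq_len(nSpecies)) {
    B <- sapply(seq_len(nBase), function(j)
      runif(nBg[s], infl[1, j], infl[2, j]))
    bg[[s]] <- data.frame(species = spNames[s],
                          matrix(B, nrow = nBg[s]))
  }
  bg <- do.call(rbind, bg)
  colnames(occ)[-(1:3)] <- vnames[seq_len(nBase)]
  colnames(bg)[-1] <- vnames[seq_len(nBase)]
  if (nRedundant > 0) {
    srcs <- rep(seq_len(nBase), length.out = nRedundant)
    for (k in seq_len(nRedundant)) {
      vn <- vnames[nBase + k]
      occ[[vn]] <- occ[[vnames[srcs[k]]]] +
        rnorm(nrow(occ), 0, withinSD * 0.01)
      bg[[vn]] <- bg[[vnames[srcs[k]]]] +
        rnorm(nrow(bg), 0, withinSD * 0.01)
    }
  }
  new("NicheDataset", occurrences = occ, background = bg,
      varNames = vnames)
}

setMethod("show", "NicheDataset", function(object) {
  cat("NicheDataset:", nrow(object@occurrences), "occurrences,",
      nrow(object@background), "background points,",
      length(object@varNames), "climate variables,",
      length(unique(object@occurrences$species)), "species\n")
  invisible(object)
})
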