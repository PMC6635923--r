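## Shared fixture builders (all data generated in code).

## tiny two-population dataset with hand-checkable numbers
toyTwoPops <- function() {
  ## pop1: (100,100) (100,102) (102,102) (100,102)
  ## pop2: (102,102) (102,102) (100,102) (102,102)
  g <- rbind(c(100L, 100L), c(100L, 102L), c(102L, 102L), c(100L, 102L),
             c(102L, 102L), c(102L, 102L), c(100L, 102L), c(102L, 102L))
  a <- array(NA_integer_, dim = c(8, 1, 2))
  a[, 1, 1] <- g[, 1]; a[, 1, 2] <- g[, 2]
  GenotypeDataset(a, pop = rep(c("p1", "p2"), each = 4))
}

## three-species dataset with strong planted divergence
plantedTrio <- function(seed = 1, nLoci = 10, n = 12,
                        pops = c(J = "J", Q = "Q", R = "R")) {
  par <- scenarioParams(NJ = 2000, NQ = 2000, NR = 2000, A1 = 2000,
                        A2 = 2000, t1 = 4000, t2 = 12000, mu = 5e-4)
  cfg <- setNames(rep(n, length(pops)), names(pops))
  simulateScenario(scenarioSpec(1, 2), par, cfg, nLoci, seed,
                   speciesOf = pops)
}

## panmictic dataset split into k pseudo-populations
panmicticPops <- function(seed, k = 6, n = 8, nLoci = 6, N = 2000,
                          mu = 5e-4) {
  par <- scenarioParams(N, N, N, N, N, 1e-6, 2e-6, mu)
  labs <- paste0("p", seq_len(k))
  cfg <- setNames(rep(n, k), labs)
  spOf <- setNames(rep(c("J", "Q", "R"), length.out = k), labs)
  ds <- simulateScenario(scenarioSpec(1, 2), par, cfg, nLoci, seed,
                         speciesOf = spOf)
  ## relabel everything as one species so grouping is purely by pop
  ds@speciesMap[] <- "sp1"
  ds
}

## forward-time Wright-Fisher source/sink pair: 'a' large and stable,
## 'b' small and receiving migrants from 'a' at rate m each generation
sourceSinkPair <- function(seed, nLoci = 10, gens = 60, m = 0.25,
                           Na = 400, Nb = 60, nSample = 30) {
  set.seed(seed)
  K <- 8  # alleles per locus
  sampleGenotypes <- function(freqs, n) {
    t(sapply(seq_len(2 * n), function(i)
      apply(freqs, 2, function(p) sample.int(K, 1, prob = p))))
  }
  fa <- matrix(0, K, nLoci); fb <- matrix(0, K, nLoci)
  for (l in seq_len(nLoci)) {
    fa[, l] <- as.numeric(rmultinom(1, 200, rep(1 / K, K))) / 200
    fb[, l] <- as.numeric(rmultinom(1, 200, rep(1 / K, K))) / 200
  }
  for (g in seq_len(gens)) {
    for (l in seq_len(nLoci)) {
      fa[, l] <- as.numeric(rmultinom(1, 2 * Na, fa[, l])) / (2 * Na)
      mix <- (1 - m) * fb[, l] + m * fa[, l]
      fb[, l] <- as.numeric(rmultinom(1, 2 * Nb, mix)) / (2 * Nb)
    }
  }
  drawPop <- function(fr, n) {
    a <- array(NA_integer_, dim = c(n, nLoci, 2))
    for (l in seq_len(nLoci)) {
      a[, l, 1] <- 100L + sample.int(K, n, TRUE, prob = fr[, l])
      a[, l, 2] <- 100L + sample.int(K, n, TRUE, prob = fr[, l])
    }
    a
  }
  aA <- drawPop(fa, nSample); aB <- drawPop(fb, nSample)
  arr <- array(NA_integer_, dim = c(2 * nSample, nLoci, 2))
  arr[seq_len(nSample), , ] <- aA
  arr[nSample + seq_len(nSample), , ] <- aB
  GenotypeDataset(arr, pop = rep(c("a", "b"), each = nSample),
                  speciesMap = c(a = "a", b = "b"))
}

## haplotype table built directly from counts + distances
tableFromCounts <- function(counts, diffs, speciesMap = NULL,
                            seqLength = 100L) {
  if (is.null(speciesMap))
    speciesMap <- setNames(rep("sp1", nrow(counts)), rownames(counts))
  new("HaplotypeTable", haplotypes = character(), diffs = diffs,
      counts = counts, speciesMap = speciesMap,
      seqLength = as.integer(seqLength))
}
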