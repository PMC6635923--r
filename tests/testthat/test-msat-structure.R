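test_that("Mantel r = 1 for affinely related matrices", {
  set.seed(1)
  k <- 6
  coords <- data.frame(pop = paste0("p", 1:k),
                       lat = runif(k, 30, 36), lon = runif(k, 104, 112))
  geo <- distMatrix(geographicDistances(coords))
  ## linearized-FST matrix as a positive affine map of geography
  aff <- 0.1 + 0.002 * geo
  diag(aff) <- 0
  lin <- new("DistancePair", matrix = aff, kind = "linearized_fst")
  mt <- mantelIBD(lin, coords, nPerm = 99, seed = 5)
  expect_equal(mt$r, 1, tolerance = 1e-10)
  expect_lte(mt$p, 0.05)
})

test_that("Mantel p-values are reproducible and in (0, 1]", {
  ds <- panmicticPops(seed = 3, k = 5, n = 8, nLoci = 5)
  coords <- data.frame(pop = levels(popLabels(ds)),
                       lat = c(30, 32, 34, 36, 33),
                       lon = c(105, 107, 109, 111, 108))
  fst <- pairwiseFst(ds)
  m1 <- suppressWarnings(mantelIBD(fst, coords, nPerm = 99, seed = 9))
  m2 <- suppressWarnings(mantelIBD(fst, coords, nPerm = 99, seed = 9))
  expect_identical(m1$p, m2$p)
  expect_gt(m1$p, 0)
  expect_lte(m1$p, 1)
})

test_that("shared-allele distance and NJ behave on planted structure", {
  ## two clones are at distance zero
  a <- array(c(100L, 100L, 102L, 102L, 100L, 100L, 102L, 104L),
             dim = c(2, 2, 2))
  a[1, , ] <- a[2, , ] <- cbind(c(100L, 102L), c(100L, 102L))
  ds2 <- GenotypeDataset(a, pop = c("p", "p"))
  expect_equal(sharedAlleleDistance(ds2)[1, 2], 0)

  ## NJ recovers a 4-taxon additive topology: ((1,2),(3,4))
  ds <- plantedTrio(seed = 21, nLoci = 12, n = 5)
  tr <- sharedAlleleNJ(ds)
  expect_s3_class(tr, "phylo")
  sp <- sub("\\|.*", "", tr$tip.label)
  for (s in c("J", "Q", "R")) {
    expect_true(ape::is.monophyletic(tr, tr$tip.label[sp == s]))
  }
})

test_that("genotype PCA separates planted species and is well formed", {
  ds <- plantedTrio(seed = 13, nLoci = 12, n = 10)
  pc <- genotypePCA(ds)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  ## separation of two species on PC1 in within-species SD units
  s1 <- pc$scores[pc$species == "J", 1]
  s3 <- pc$scores[pc$species == "R", 1]
  sdw <- sqrt(mean(c(var(s1), var(s3))))
  expect_gt(abs(mean(s1) - mean(s3)) / sdw, 3)

  ## identical individuals: zero variance, no crash
  a <- array(100L, dim = c(4, 3, 2))
  pc0 <- genotypePCA(GenotypeDataset(a, pop = rep("p", 4)))
  expect_equal(max(pc0$sdev), 0)
})

test_that("relative migration is scaled, symmetric for twins and
           asymmetric for a source-sink pair", {
  ds <- plantedTrio(seed = 17, nLoci = 10, n = 12)
  m <- relativeMigration(ds)
  expect_equal(max(m, na.rm = TRUE), 1)

  ## island-model-like pair: same size, same history -> ratio near 1
  ratios <- sapply(1:10, function(i) {
    d <- plantedTrio(seed = 100 + i, nLoci = 10, n = 15)
    mm <- relativeMigration(d)
    mm["J", "Q"] / mm["Q", "J"]
  })
  expect_gt(mean(ratios > 0.8 & ratios < 1.25), 0.5)
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.4)

  ## forward-simulated source (a) -> sink (b): inferred migration into
  ## the sink should exceed the reverse direction in most replicates
  wins <- sapply(1:10, function(i) {
    d <- sourceSinkPair(seed = 200 + i, nLoci = 20)
    mm <- relativeMigration(d, level = "population")
    mm["a", "b"] > mm["b", "a"]
  })
  expect_gte(mean(wins), 0.8)
})
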