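test_that("heterozygosities match hand-enumerated values", {
  ## {(100,100), (100,102)}: Ho = 0.5; He = (4/3)(1 - (0.75^2 + 0.25^2))
  a <- array(c(100L, 100L, 100L, 102L), dim = c(2, 1, 2))
  h <- heterozygosities(GenotypeDataset(a, pop = c("p", "p")))
  expect_equal(h$Ho, 0.5)
  expect_equal(h$He, (4 / 3) * (1 - (0.75^2 + 0.25^2)))
  expect_equal(h$He, 0.5)

  ## monomorphic population
  am <- array(100L, dim = c(5, 2, 2))
  hm <- heterozygosities(GenotypeDataset(am, pop = rep("p", 5)))
  expect_equal(hm$Ho, 0)
  expect_equal(hm$He, 0)

  ## all heterozygotes (100,102) x n: Ho = 1, He = (2n/(2n-1)) * 0.5
  for (n in c(3, 7)) {
    ah <- array(c(rep(100L, n), rep(102L, n)), dim = c(n, 1, 2))
    hh <- heterozygosities(GenotypeDataset(ah, pop = rep("p", n)))
    expect_equal(hh$Ho, 1)
    expect_equal(hh$He, (2 * n / (2 * n - 1)) * 0.5)
  }
})

test_that("missing calls are excluded per locus", {
  a <- array(c(100L, 100L, NA, 100L, 102L, NA), dim = c(3, 1, 2))
  h <- heterozygosities(GenotypeDataset(a, pop = rep("p", 3)))
  expect_equal(h$Ho, 0.5)   # only the two typed individuals count
  expect_equal(h$n, 3)
})

test_that("allelic richness follows the rarefaction formula", {
  ## fixed locus: A_R = 1 for any g
  am <- array(100L, dim = c(4, 1, 2))
  dsm <- GenotypeDataset(am, pop = rep("p", 4))
  expect_equal(as.vector(allelicRichness(dsm, g = 4)), 1)

  ## N = 4 copies, counts {3, 1}, g = 2 -> 1.5
  a <- array(c(100L, 100L, 100L, 102L), dim = c(2, 1, 2))
  ds <- GenotypeDataset(a, pop = c("p", "p"))
  expect_equal(as.vector(allelicRichness(ds, g = 2)), 1.5)

  ## g = N recovers the observed allele count
  expect_equal(as.vector(allelicRichness(ds, g = 4)), 2)

  expect_error(allelicRichness(ds, g = 1), "at least 2")
  expect_error(allelicRichness(ds, g = 10), "exceeds")
})

test_that("private alleles are exactly the planted unique ones", {
  ## pop1 carries private allele 110 at locus 1; pop2 private 130 at
  ## locus 2; allele 100 shared everywhere
  a <- array(100L, dim = c(6, 2, 2))
  a[1, 1, 2] <- 110L
  a[4, 2, 2] <- 130L
  a[2, 1, 2] <- 104L; a[5, 1, 2] <- 104L  # shared non-private allele
  ds <- GenotypeDataset(a, pop = rep(c("p1", "p2"), each = 3))
  ap <- privateAlleles(ds)
  expect_equal(unname(ap["p1"]), 1L)
  expect_equal(unname(ap["p2"]), 1L)
})

test_that("FIS is negative under heterozygote excess", {
  n <- 10
  ah <- array(c(rep(100L, n), rep(102L, n)), dim = c(n, 1, 2))
  fis <- fisCoefficient(GenotypeDataset(ah, pop = rep("p", n)))
  expect_lt(fis[["p"]], 0)   # Ho = 1 > He
  expect_gte(fis[["p"]], -1)
})

test_that("diversityReport assembles population and species rows", {
  ds <- plantedTrio(seed = 5, nLoci = 6, n = 8)
  rep <- diversityReport(ds)
  expect_true(all(c("population", "species") %in% rep$level))
  expect_true(all(rep$Ho >= 0 & rep$Ho <= 1))
  expect_true(all(rep$He >= 0 & rep$He <= 1))
  expect_true(all(rep$AR >= 1, na.rm = TRUE))
})
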