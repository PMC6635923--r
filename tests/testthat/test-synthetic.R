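test_that("generators are deterministic under fixed seeds", {
  p <- scenarioParams(1000, 1000, 1000, 1000, 1000, 300, 900, 5e-4)
  m1 <- makeMicrosatTruth(1, p, c(J = 4, Q = 4, R = 4), 3, seed = 5)
  m2 <- makeMicrosatTruth(1, p, c(J = 4, Q = 4, R = 4), 3, seed = 5)
  expect_identical(alleles(m1$dataset), alleles(m2$dataset))

  req <- list(P1 = c(A = 2, B = 3))
  c1 <- makeCpdnaTruth(req, nSites = 100, nMutations = 4, seed = 9)
  c2 <- makeCpdnaTruth(req, nSites = 100, nMutations = 4, seed = 9)
  expect_identical(c1$alignment, c2$alignment)

  n1 <- makeNicheTruth(2, 1, 10, 50, 4, seed = 13)
  n2 <- makeNicheTruth(2, 1, 10, 50, 4, seed = 13)
  expect_identical(n1@occurrences, n2@occurrences)
  expect_identical(n1@background, n2@background)
})

test_that("microsatellite truth validates inputs and records truth", {
  p <- scenarioParams(1000, 1000, 1000, 1000, 1000, 300, 900, 5e-4)
  expect_error(makeMicrosatTruth(9, p, c(J = 3, Q = 3, R = 3), 2,
                                 seed = 1), "valid ids")
  expect_error(makeMicrosatTruth(1, p, c(J = 1, Q = 3, R = 3), 2,
                                 seed = 1), "at least 2")
  mk <- makeMicrosatTruth(1, p, c(J = 3, Q = 4, R = 5), 6, seed = 2)
  expect_s4_class(mk$truth, "TruthRecord")
  expect_equal(mk$truth@scenarioId, 1L)
  expect_equal(unname(mk$truth@sampleSizes), c(3L, 4L, 5L))
  expect_equal(nLoci(mk$dataset), 6)
  expect_equal(unname(table(popLabels(mk$dataset))), c(3L, 4L, 5L),
               ignore_attr = TRUE)
})

test_that("cpDNA truth rejects unrealizable requests", {
  expect_error(makeCpdnaTruth(list(P = c(A = 2)), nSites = 10,
                              nMutations = 12, seed = 1),
               "smaller than nSites")
  req9 <- list(P = setNames(rep(1, 9), paste0("H", 1:9)))
  expect_error(makeCpdnaTruth(req9, nSites = 100, nMutations = 5,
                              seed = 1), "distinct haplotypes")
  expect_error(makeCpdnaTruth(list(P = c(A = 0, B = 2)), nSites = 100,
                              nMutations = 5, seed = 1), ">= 1")
})

test_that("single-haplotype truth gives Hd = 0", {
  cp <- makeCpdnaTruth(list(P = c(H = 12)), nSites = 150,
                       nMutations = 0, includeIndel = FALSE, seed = 2)
  ht <- collapseHaplotypes(cp$alignment, cp$assignments)
  expect_equal(unname(haplotypeDiversity(ht)[["P"]]), 0)
})

test_that("deep species splits leave more FST between than within", {
  ## statistical fidelity: scenario 1 with a large t2, replicated
  p <- scenarioParams(2000, 2000, 2000, 2000, 2000, 3000, 15000, 5e-4)
  cfg <- c(J1 = 6, J2 = 6, Q1 = 6, R1 = 6, R2 = 6)
  spOf <- c(J1 = "J", J2 = "J", Q1 = "Q", R1 = "R", R2 = "R")
  between <- within <- numeric(20)
  for (i in 1:20) {
    mk <- makeMicrosatTruth(1, p, cfg, 6, seed = 300 + i,
                            speciesOf = spOf)
    f <- distMatrix(pairwiseFst(mk$dataset))
    between[i] <- mean(c(f["J1", "R1"], f["J1", "R2"],
                         f["J2", "R1"], f["J2", "R2"]))
    within[i] <- mean(c(f["J1", "J2"], f["R1", "R2"]))
  }
  expect_gt(mean(between), mean(within))
})

test_that("niche truth exposes the correlation-filter scenario", {
  ## 19 candidate variables, 11 of them near-duplicates: 8 survive
  nd <- makeNicheTruth(3, 1, 30, 100, nVars = 19, seed = 4,
                       nRedundant = 11)
  kept <- filterCorrelated(nd@background[, nd@varNames])
  expect_equal(length(kept), 8)
})
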