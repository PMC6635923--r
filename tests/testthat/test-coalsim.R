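test_that("scenario catalogue and parameter validation", {
  expect_equal(nrow(scenarioCatalogue(1)), 6)
  expect_equal(nrow(scenarioCatalogue(2)), 2)
  expect_error(scenarioSpec(7, 1), "valid ids: 1, 2, 3, 4, 5, 6")
  expect_error(scenarioSpec(3, 2), "valid ids: 1, 2")
  expect_error(scenarioParams(100, 100, 100, 100, 100,
                              5000, 4000, 5e-4), "t1")
  expect_error(scenarioParams(-5, 100, 100, 100, 100,
                              100, 400, 5e-4), "positive")
  ## an impossible merge schedule is rejected with the event named
  bad <- scenarioSpec(1, 2)
  bad@merge2 <- c(2L, 1L)  # lineage 2 was removed at t1
  expect_error(simulateScenario(bad,
    scenarioParams(100, 100, 100, 100, 100, 10, 20, 5e-4),
    c(J = 3, Q = 3, R = 3), 2, seed = 1), "impossible merge")
})

test_that("fixed seeds reproduce datasets exactly", {
  p <- scenarioParams(500, 400, 600, 300, 800, 200, 900, 5e-4)
  s <- scenarioSpec(1, 2)
  d1 <- simulateScenario(s, p, c(J = 5, Q = 5, R = 5), 4, seed = 99)
  d2 <- simulateScenario(s, p, c(J = 5, Q = 5, R = 5), 4, seed = 99)
  d3 <- simulateScenario(s, p, c(J = 5, Q = 5, R = 5), 4, seed = 100)
  expect_identical(alleles(d1), alleles(d2))
  expect_false(identical(alleles(d1), alleles(d3)))
})

test_that("degenerate histories behave as expected", {
  s <- scenarioSpec(1, 2)
  ## immediate merges: panmixia, FST near zero on average
  p0 <- scenarioParams(2000, 2000, 2000, 2000, 2000, 1e-6, 2e-6, 5e-4)
  fst <- sapply(1:30, function(i) {
    ds <- simulateScenario(s, p0, c(J = 8, Q = 8, R = 8), 5, seed = i)
    weirFst(ds, "species")
  })
  expect_lt(abs(mean(fst)), 0.02)

  ## no mutation: monomorphic, He = 0
  pm <- scenarioParams(2000, 2000, 2000, 2000, 2000, 100, 500, 1e-12)
  dm <- simulateScenario(s, pm, c(J = 5, Q = 5, R = 5), 6, seed = 3)
  h <- heterozygosities(dm)
  expect_true(all(h$He == 0))
  expect_equal(length(unique(as.vector(alleles(dm)))), 1)
})

test_that("prior draws honour t1 < t2 and uniform moments", {
  pr <- defaultPriors()
  d <- drawParams(pr, 10000, seed = 6)
  expect_true(all(d$t1 < d$t2))
  se <- (1e-3 - 1e-4) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(d$mu) - 5.5e-4), 3 * se)
  d2 <- drawParams(pr, 100, seed = 7)
  d3 <- drawParams(pr, 100, seed = 7)
  expect_identical(d2, d3)
})

test_that("locus order is exchangeable for summary statistics", {
  ds <- plantedTrio(seed = 41, nLoci = 8, n = 8)
  s1 <- summarizeDataset(ds)
  perm <- sample(8)
  ds2 <- ds
  ds2@alleles <- ds@alleles[, perm, , drop = FALSE]
  expect_equal(summarizeDataset(ds2), s1, tolerance = 1e-12)
})

test_that("between-species FST grows with the deep split time", {
  s <- scenarioSpec(1, 2)
  meanFst <- sapply(c(500, 4000, 20000), function(t2) {
    mean(sapply(1:12, function(i) {
      p <- scenarioParams(1500, 1500, 1500, 1500, 1500, 400, t2, 5e-4)
      ds <- simulateScenario(s, p, c(J = 8, Q = 8, R = 8), 5,
                             seed = 7000 + 100 * log(t2) + i)
      distMatrix(pairwiseFst(ds, "species"))["J", "R"]
    }))
  })
  expect_true(all(diff(meanFst) > 0))
})

test_that("single-population equilibrium matches Ohta-Kimura", {
  ## quick version (one setting; the acceptance suite covers three)
  s <- scenarioSpec(1, 2)
  N <- 1000; mu <- 3e-4
  p <- scenarioParams(N, N, N, N, N, 1e-6, 2e-6, mu)
  ds <- simulateScenario(s, p, c(J = 26, Q = 2, R = 2), 150, seed = 55)
  pool <- ds[speciesLabels(ds) == "J"]
  heL <- peonypop:::.hetOneGroup(alleles(pool))$He
  se <- sd(heL) / sqrt(length(heL))
  expect_lt(abs(mean(heL) - smmEquilibriumHe(N, mu)), 3 * se)
})

test_that("step-2 scenarios differ in distribution only through A1", {
  ## scaled-down version of the KS invariant (seeded, 60 reps)
  sc <- c(J = 25, Q = 20, R = 25)
  s1 <- scenarioSpec(1, 2); s2 <- scenarioSpec(2, 2)
  run <- function(p, base) sapply(1:60, function(i) {
    summarizeDataset(simulateScenario(
      if (base) s1 else s2, p, sc, 8, seed = 3000 * (1 + base) + i)
    )[["He_R"]]
  })
  pDiff <- scenarioParams(1690, 4910, 5090, 200, 9520, 2430, 5030, 5e-4)
  ks <- suppressWarnings(ks.test(run(pDiff, TRUE), run(pDiff, FALSE)))
  expect_lt(ks$p.value, 0.01)
})
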