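test_that("summary statistics match the brute-force oracle", {
  ds <- plantedTrio(seed = 31, nLoci = 6, n = 7)
  expect_equal(unname(summarizeDataset(ds)), oracleSummary(ds),
               tolerance = 1e-10)
})

test_that("summary statistics hit their closed-form cases", {
  ## identical groups: FST ~ 0, (delta mu)^2 ~ 0
  arr <- alleles(plantedTrio(seed = 8, nLoci = 5, n = 6))
  one <- arr[1:6, , , drop = FALSE]
  a <- array(NA_integer_, dim = c(18, 5, 2))
  for (k in 0:2) a[6 * k + 1:6, , ] <- one
  ds <- GenotypeDataset(a, pop = rep(c("J", "Q", "R"), each = 6),
                        speciesMap = c(J = "J", Q = "Q", R = "R"))
  s <- summarizeDataset(ds)
  ## unbiased theta for identical groups is at or below zero
  expect_lte(s[["FST_JQ"]], 0.001)
  expect_gt(s[["FST_JQ"]], -0.5)
  expect_lt(s[["dmu2_JR"]], 1e-20)

  ## groups fixed at 100 vs 104: (delta mu)^2 = 16
  af <- array(NA_integer_, dim = c(9, 1, 2))
  af[1:3, 1, ] <- 100L; af[4:6, 1, ] <- 104L; af[7:9, 1, ] <- 104L
  sm <- c(J = "J", Q = "Q", R = "R")
  dsf <- GenotypeDataset(af, pop = rep(c("J", "Q", "R"), each = 3),
                         speciesMap = sm)
  expect_equal(unname(summarizeDataset(dsf)[["dmu2_JQ"]]), 16)

  ## group size guard
  expect_error(summarizeDataset(
    GenotypeDataset(af[c(1, 4:9), , , drop = FALSE],
                    pop = c("J", "Q", "Q", "Q", "R", "R", "R"),
                    speciesMap = sm)),
    "at least 2")
})

test_that("reference tables have the right shape and are seeded", {
  pr <- defaultPriors()
  cfg <- c(J = 5, Q = 5, R = 5)
  t1 <- buildReference(1:2, pr, 10, cfg, 3, seed = 21, step = 2)
  expect_equal(length(t1@scenario), 20)
  expect_equal(sort(unique(t1@scenario)), 1:2)
  t2 <- buildReference(1:2, pr, 10, cfg, 3, seed = 21, step = 2)
  expect_identical(t1@stats, t2@stats)
  ## six step-1 scenarios
  t6 <- buildReference(1:6, pr, 5, cfg, 2, seed = 4, step = 1)
  expect_equal(length(t6@scenario), 30)
})

test_that("scenario choice is normalized, informative when it can be,
           uninformative when it cannot", {
  pr <- defaultPriors()
  cfg <- c(J = 10, Q = 10, R = 10)
  tab <- buildReference(1:2, pr, 250, cfg, 6, seed = 31, step = 2)

  ## strongly divergent observation generated under scenario 1
  pTrue <- scenarioParams(2000, 2000, 15000, 200, 2000, 1500, 30000,
                          5e-4)
  obs <- summarizeDataset(simulateScenario(scenarioSpec(1, 2), pTrue,
                                           cfg, 6, seed = 77))
  ch <- suppressWarnings(chooseScenario(obs, tab, tolerance = 0.05))
  expect_equal(sum(ch$posterior), 1, tolerance = 1e-9)
  expect_true(all(ch$posterior >= 0))

  ## statistics independent of the scenario id: probabilities near 1/k.
  ## A1 = NR makes the two step-2 scenarios demographically identical.
  pSame <- scenarioParams(1500, 1500, 1500, 1500, 1500, 500, 3000, 5e-4)
  stats <- t(sapply(1:120, function(i)
    summarizeDataset(simulateScenario(
      scenarioSpec(1 + i %% 2, 2), pSame, cfg, 5, seed = 500 + i))))
  tabU <- new("ReferenceTable", scenario = rep(1:2, 60),
              params = matrix(1, 120, 8,
                              dimnames = list(NULL, rownames(pr@bounds))),
              stats = stats, step = 2L, seed = 1L,
              priorBounds = pr@bounds)
  obsU <- summarizeDataset(simulateScenario(scenarioSpec(1, 2), pSame,
                                            cfg, 5, seed = 999))
  chU <- suppressWarnings(chooseScenario(obsU, tabU, tolerance = 0.5))
  expect_equal(sum(chU$posterior), 1, tolerance = 1e-9)
  expect_true(all(abs(chU$posterior - 0.5) < 0.35))
})

test_that("parameter estimation: prior limit and self-assignment", {
  pr <- defaultPriors()
  cfg <- c(J = 8, Q = 8, R = 8)
  tab <- buildReference(1, pr, 400, cfg, 5, seed = 41, step = 2)

  ## tolerance 1, no adjustment: posterior is the prior
  obs <- tab@stats[17, ]
  post <- suppressWarnings(
    estimateParams(obs, tab, 1, tolerance = 1, adjust = FALSE))
  ks <- suppressWarnings(
    ks.test(post$sample[, "NJ"], "punif", 10, 1e5))
  expect_gt(ks$p.value, 0.01)

  ## self-assignment: each median inside the central 50% of the
  ## retained draws
  postS <- suppressWarnings(
    estimateParams(obs, tab, 1, tolerance = 0.1, adjust = FALSE))
  med <- postS$summary[match(colnames(postS$sample),
                             postS$summary$parameter), "median"]
  for (j in seq_along(med)) {
    qs <- quantile(postS$sample[, j], c(0.25, 0.75))
    expect_gte(med[j], qs[[1]] - 1e-9)
    expect_lte(med[j], qs[[2]] + 1e-9)
  }
  ## times also reported in years (x 10)
  s <- postS$summary
  expect_equal(s$median[s$parameter == "t1_years"],
               10 * s$median[s$parameter == "t1"])
})

test_that("posterior model check flags misfit and passes self-fit", {
  pr <- defaultPriors()
  cfg <- c(J = 8, Q = 8, R = 8)
  tab <- buildReference(1, pr, 500, cfg, 5, seed = 51, step = 2)
  pTrue <- scenarioParams(3000, 3000, 3000, 3000, 3000, 800, 4000, 4e-4)
  spec <- scenarioSpec(1, 2)
  obs <- summarizeDataset(simulateScenario(spec, pTrue, cfg, 5,
                                           seed = 61))
  post <- suppressWarnings(estimateParams(obs, tab, 1,
                                          tolerance = 0.1))
  mc <- modelCheck(obs, post, spec, cfg, 5, nRep = 80, seed = 71)
  expect_true(all(mc$pTail >= 0 & mc$pTail <= 1))
  ## the fitted model should reproduce nearly all of its own statistics
  expect_lte(sum(mc$pTail < 0.05), 2)

  ## grossly different observation: at least one extreme statistic
  pFar <- scenarioParams(80000, 30, 80000, 50000, 60, 90000, 99000,
                         9.9e-4)
  obsFar <- summarizeDataset(simulateScenario(spec, pFar, cfg, 5,
                                              seed = 81))
  mcFar <- modelCheck(obsFar, post, spec, cfg, 5, nRep = 60, seed = 91)
  expect_lt(min(mcFar$pTail), 0.05)
})

test_that("confidence errors sit near chance for identical scenarios", {
  pr <- defaultPriors()
  cfg <- c(J = 8, Q = 8, R = 8)
  ## force indistinguishability: reference rows for both scenarios are
  ## simulated from scenario 1 only (identical generating process)
  t1 <- buildReference(1, pr, 150, cfg, 4, seed = 61, step = 2)
  tab <- new("ReferenceTable",
             scenario = rep(1:2, each = 75),
             params = t1@params, stats = t1@stats, step = 2L,
             seed = 61L, priorBounds = pr@bounds)
  ce <- suppressWarnings(
    confidenceErrors(tab, 1, pr, cfg, 4, nPods = 20,
                     tolerance = 0.2, seed = 71))
  expect_gte(ce$typeI, 0); expect_lte(ce$typeI, 1)
  expect_gte(ce$typeII, 0); expect_lte(ce$typeII, 1)
  ## k = 2 indistinguishable: both errors should hover near 1/2
  expect_gt(ce$typeI, 0.15); expect_lt(ce$typeI, 0.85)
  expect_gt(ce$typeII, 0.15); expect_lt(ce$typeII, 0.85)
})
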