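test_that("Tajima's D matches an explicit textbook evaluation", {
  ## n = 4, one singleton site
  seqs <- c("AAAA", "AAAA", "AAAA", "AAAT")
  td <- tajimasD(seqs)
  n <- 4; S <- 1
  pi <- (3 * 1 + 3 * 0) / 6
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(td$D, expected, tolerance = 1e-12)

  ## no variation: flagged undefined
  t0 <- tajimasD(rep("ACGT", 5))
  expect_true(is.na(t0$D))
  expect_match(t0$flag, "segregating")
  expect_true(is.na(tajimasD(c("AA", "AT", "AA"))$D))  # n < 4
})

test_that("neutral constant-size simulations give Tajima's D near 0", {
  set.seed(123)
  d <- replicate(400, {
    sim <- peonypop:::.coalInfSites(20, 0, 5, 5)
    if (sim$S < 1) return(NA_real_)
    n <- 20
    a1 <- sum(1 / 1:19); a2 <- sum(1 / (1:19)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (sim$pi - sim$S / a1) /
      sqrt(c1 / a1 * sim$S + c2 / (a1^2 + a2) * sim$S * (sim$S - 1))
  })
  expect_gt(mean(d, na.rm = TRUE), -0.35)
  expect_lt(mean(d, na.rm = TRUE), 0.1)
})

test_that("Ewens probabilities match the Stirling-number oracle", {
  for (n in c(3, 5, 6)) for (theta in c(0.5, 1, 2.5)) {
    expect_equal(peonypop:::.ewensK(n, theta), oracleEwens(n, theta),
                 tolerance = 1e-12)
  }
  ## n = 5, k = 2, theta = 1: S' = P(K >= 2) = 96/120, Fs = ln(4)
  fs <- peonypop:::.fsFromTheta(5, 2, 1)
  expect_equal(fs$Sprime, 96 / 120, tolerance = 1e-12)
  expect_equal(fs$Fs, log((96 / 120) / (24 / 120)), tolerance = 1e-12)
})

test_that("Fu's Fs guards degenerate cases and flags structure", {
  ## single haplotype: S' = 1, +Inf guard
  f1 <- fusFs(rep("ACGT", 6))
  expect_true(is.infinite(f1$Fs))
  expect_false(is.null(f1$flag))

  ## two deeply divergent clusters: few haplotypes, large theta -> Fs > 0
  seqs <- c(rep("AAAAAAAAAA", 8), rep("TTTTTTTTTT", 8))
  f2 <- fusFs(seqs)
  expect_gt(f2$Fs, 0)
  expect_equal(f2$k, 2)
})

test_that("mismatch machinery: mass conservation, raggedness, oracle", {
  ## histogram mass equals C(n,2)
  req <- list(P = c(A = 4, B = 3, C = 3))
  cp <- makeCpdnaTruth(req, nSites = 200, nMutations = 9, seed = 3)
  ht <- collapseHaplotypes(cp$alignment, cp$assignments)
  mf <- mismatchFit(ht, "sp1", nBoot = 0, seed = 1)
  expect_equal(sum(mf$observed), choose(10, 2))

  ## bimodal two-spike distribution is ragged
  spiky <- c(10, 0, 0, 0, 0, 12)
  smooth <- c(4, 5, 5, 4, 2, 2)
  expect_gt(raggedness(spiky), raggedness(smooth))

  ## optimizer never worse than a coarse grid search by > 1e-6
  obs <- c(2, 5, 8, 6, 3, 1, 0, 1)
  fit <- peonypop:::.fitMismatch(obs, nStarts = 10)
  obsRel <- obs / sum(obs)
  grid <- expand.grid(tau = seq(0.2, 6, length.out = 12),
                      theta0 = seq(0.05, 3, length.out = 8),
                      theta1 = seq(0.5, 30, length.out = 10))
  gbest <- min(apply(grid, 1, function(g)
    peonypop:::.mismatchSSD(as.numeric(g), obsRel)))
  expect_lte(fit$value, gbest + 1e-6)
})

test_that("expected mismatch curve has the right limits", {
  ## tau = 0: equilibrium at theta0
  e0 <- mismatchExpected(0, 2, 10, 20)
  geo <- 2^(0:20) / 3^(1:21)
  expect_equal(e0, geo, tolerance = 1e-10)
  ## tau large: equilibrium at theta1
  eInf <- mismatchExpected(500, 2, 4, 15)
  geo1 <- 4^(0:15) / 5^(1:16)
  expect_equal(eInf, geo1, tolerance = 1e-6)
  expect_true(all(e0 >= 0) && sum(e0) <= 1 + 1e-9)
})

test_that("mismatch bootstrap p-values are seeded and sane", {
  set.seed(5)
  sim <- peonypop:::.coalInfSites(25, 8, 0.5, 25)   # strong expansion
  h <- sim$hist
  m1 <- mismatchFit(h, nBoot = 40, nStarts = 5, seed = 11)
  m2 <- mismatchFit(h, nBoot = 40, nStarts = 5, seed = 11)
  expect_identical(m1$pSSD, m2$pSSD)
  expect_gt(m1$pSSD, 0); expect_lte(m1$pSSD, 1)
  expect_gt(m1$pRag, 0); expect_lte(m1$pRag, 1)
  ## the expansion model fits its own data
  expect_gt(m1$pSSD, 0.05)
})
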