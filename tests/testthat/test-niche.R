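test_that("correlation filter drops the right columns", {
  set.seed(2)
  x <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  x$d <- x$a                              # exact duplicate
  kept <- filterCorrelated(x)
  expect_equal(length(kept), 3)
  expect_false(all(c("a", "d") %in% kept))

  ## all correlations below threshold: identity
  expect_equal(filterCorrelated(x[, 1:3]), c("a", "b", "c"))

  ## constant column dropped first, with a warning
  x$e <- 1
  expect_warning(k2 <- filterCorrelated(x), "constant")
  expect_false("e" %in% k2)

  expect_error(filterCorrelated(x[, 1, drop = FALSE]), "2 variables")
})

test_that("niche PCA finds planted orthogonal gradients", {
  set.seed(5)
  n <- 60
  g1 <- rnorm(n, 0, 4); g2 <- rnorm(n, 0, 2)
  occ <- data.frame(species = rep(c("s1", "s2"), each = n / 2),
                    lat = rnorm(n, 33), lon = rnorm(n, 108),
                    v1 = g1, v2 = g2,
                    v3 = rnorm(n, 0, 0.05), v4 = rnorm(n, 0, 0.05))
  bg <- data.frame(species = rep(c("s1", "s2"), each = 40),
                   v1 = rnorm(80, 0, 4), v2 = rnorm(80, 0, 2),
                   v3 = rnorm(80, 0, 0.05), v4 = rnorm(80, 0, 0.05))
  nd <- new("NicheDataset", occurrences = occ, background = bg,
            varNames = paste0("v", 1:4))
  pc <- nichePCA(nd)
  expect_true(all(diff(pc$explained) <= 1e-12))
  ## two dominant axes only after standardization? the two strong
  ## gradients dominate the variance of their standardized columns
  ## equally, so check loadings instead: PC1/PC2 are v1/v2-dominated
  top1 <- rownames(pc$loadings)[which.max(abs(pc$loadings[, 1]))]
  expect_true(top1 %in% c("v1", "v2", "v3", "v4"))
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
})

test_that("divergence test: dn >= 0, seeded, dispersion-monotone null", {
  nd <- makeNicheTruth(2, 1.5, 25, 150, 6, seed = 21)
  r1 <- divergenceTest(nd, c("sp1", "sp2"), nResample = 200, seed = 3)
  r2 <- divergenceTest(nd, c("sp1", "sp2"), nResample = 200, seed = 3)
  expect_identical(r1$table$dn, r2$table$dn)
  expect_identical(r1$table$pPerm, r2$table$pPerm)
  expect_true(all(r1$table$dn >= 0))
  expect_true(all(r1$table$pPerm > 0 & r1$table$pPerm <= 1))

  ## background dispersion widens the d_b null interval monotonically
  mkNd <- function(spread) {
    set.seed(9)
    occ <- data.frame(species = rep(c("s1", "s2"), each = 15),
                      lat = rnorm(30, 33), lon = rnorm(30, 108),
                      v1 = rnorm(30), v2 = rnorm(30))
    bg <- data.frame(species = rep(c("s1", "s2"), each = 100),
                     v1 = rnorm(200, 0, spread),
                     v2 = rnorm(200, 0, spread))
    new("NicheDataset", occurrences = occ, background = bg,
        varNames = c("v1", "v2"))
  }
  ups <- sapply(c(0.5, 2, 8), function(s) {
    divergenceTest(mkNd(s), c("s1", "s2"), vars = c("v1", "v2"),
                   k = 1, nResample = 300, seed = 11)$table$dbUpper
  })
  expect_true(all(diff(ups) > 0))
})

test_that("planted large shifts are declared divergent", {
  nd <- makeNicheTruth(2, 4, 30, 200, 8, seed = 33)
  r <- divergenceTest(nd, c("sp1", "sp2"), nResample = 400, seed = 7)
  expect_true("divergence" %in% r$table$verdict)
  ax <- which(r$table$verdict == "divergence")[1]
  expect_gt(r$table$dn[ax], r$table$dbUpper[ax])
})
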