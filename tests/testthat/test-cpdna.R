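test_that("collapsing merges identical sequences and codes indels", {
  asg <- data.frame(sample = c("s1", "s2", "s3"),
                    pop = "p1", species = "sp")
  ## three identical sequences -> one haplotype
  aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGTACGT")
  ht <- collapseHaplotypes(aln, asg)
  expect_equal(ncol(hapCounts(ht)), 1)
  expect_equal(sum(hapCounts(ht)), 3)

  ## a 5-bp gap counts as a single difference
  aln2 <- c(s1 = "ACGTACGTAC", s2 = "AC-----TAC", s3 = "ACGTACGTAC")
  ht2 <- collapseHaplotypes(aln2, asg)
  expect_equal(ncol(hapCounts(ht2)), 2)
  expect_equal(unname(hapDiffs(ht2)["H1", "H2"]), 1)
  expect_equal(ht2@seqLength, 6L)  # 5 gap columns collapsed to 1

  ## ambiguity codes become missing, with a warning
  aln3 <- c(s1 = "ACGT", s2 = "ACRT", s3 = "ACTT")
  expect_warning(ht3 <- collapseHaplotypes(aln3, asg), "ambiguity")
  expect_equal(unname(hapDiffs(ht3)["H1", "H2"]), 0)
})

test_that("synthetic alignments collapse back to the requested counts", {
  req <- list(P1 = c(A = 3, B = 7), P2 = c(B = 2, C = 5, D = 1))
  cp <- makeCpdnaTruth(req, nSites = 400, nMutations = 11, seed = 31,
                       speciesMap = c(P1 = "s1", P2 = "s2"))
  ht <- collapseHaplotypes(cp$alignment, cp$assignments)
  expect_equal(ncol(hapCounts(ht)), 4)
  for (p in names(req)) {
    expect_equal(sort(as.integer(hapCounts(ht)[p,
                    hapCounts(ht)[p, ] > 0])),
                 sort(unname(req[[p]])))
  }

  ## the in-study configuration: 18 haplotypes, 2075 sites, 37
  ## substitution columns plus one indel
  counts18 <- setNames(lapply(1:18, function(i)
    setNames(sample(1:4, 1), paste0("H", i))), paste0("pop", 1:18))
  set.seed(8)
  cp18 <- makeCpdnaTruth(counts18, nSites = 2075, nMutations = 37,
                         includeIndel = TRUE, seed = 77)
  ht18 <- collapseHaplotypes(cp18$alignment, cp18$assignments)
  expect_equal(ncol(hapCounts(ht18)), 18)
})

test_that("haplotype diversity follows Nei's unbiased formula", {
  expect_equal(round(haplotypeDiversity(c(1, 14)), 3), 0.133)
  expect_equal(haplotypeDiversity(c(1, 1, 1)), 1)
  expect_equal(haplotypeDiversity(c(10)), 0)    # monomorphic
  expect_true(is.na(haplotypeDiversity(c(1))))  # n < 2 flagged
  ## n = 2 distinct: maximal
  expect_equal(haplotypeDiversity(c(1, 1)), 1)
})

test_that("nucleotide diversity equals brute-force pair enumeration", {
  ## 2 individuals differing at 1 of 100 sites -> 0.01
  cnt <- matrix(c(1L, 1L), 1, 2,
                dimnames = list("p", c("H1", "H2")))
  D <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("H1", "H2"), c("H1", "H2")))
  expect_equal(unname(nucleotideDiversity(tableFromCounts(cnt, D))),
               0.01)

  ## random table: formula vs explicit enumeration over individuals
  set.seed(4)
  cnt2 <- matrix(rpois(6, 3) + 1L, 2, 3,
                 dimnames = list(c("pA", "pB"), c("H1", "H2", "H3")))
  D2 <- matrix(0, 3, 3, dimnames = dimnames(cnt2)[c(2, 2)])
  D2[upper.tri(D2)] <- c(2, 5, 3); D2 <- D2 + t(D2)
  tb <- tableFromCounts(cnt2, D2, seqLength = 50)
  pi <- nucleotideDiversity(tb)
  for (p in rownames(cnt2)) {
    hap <- rep(colnames(cnt2), cnt2[p, ])
    n <- length(hap); tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      tot <- tot + D2[hap[i], hap[j]]
    expect_equal(unname(pi[p]), tot / choose(n, 2) / 50)
  }
})

test_that("NST equals GST for equidistant haplotypes and detects
           planted phylogeographic structure", {
  cnt <- matrix(c(6L, 2L, 1L,
                  1L, 5L, 3L), 2, 3, byrow = TRUE,
                dimnames = list(c("pA", "pB"), c("H1", "H2", "H3")))
  Deq <- matrix(3, 3, 3, dimnames = dimnames(cnt)[c(2, 2)])
  diag(Deq) <- 0
  gn <- gstNst(tableFromCounts(cnt, Deq), nPerm = 49, seed = 1)
  expect_equal(gn$gst, gn$nst, tolerance = 1e-12)

  ## planted: similar haplotypes co-occur within populations
  cntP <- matrix(c(5L, 4L, 4L, 3L, 0L, 0L, 0L, 0L,
                   0L, 0L, 0L, 0L, 4L, 5L, 3L, 4L), 2, 8,
                 byrow = TRUE,
                 dimnames = list(c("pA", "pB"), paste0("H", 1:8)))
  DP <- matrix(9, 8, 8, dimnames = dimnames(cntP)[c(2, 2)])
  DP[1:4, 1:4] <- 1; DP[5:8, 5:8] <- 1; diag(DP) <- 0
  gp <- gstNst(tableFromCounts(cntP, DP), nPerm = 399, seed = 2)
  expect_gt(gp$nst, gp$gst)
  expect_lt(gp$p, 0.05)

  ## undefined when everything is fixed for one haplotype
  cntF <- matrix(c(5L, 4L), 2, 1,
                 dimnames = list(c("pA", "pB"), "H1"))
  DF <- matrix(0, 1, 1, dimnames = list("H1", "H1"))
  gf <- gstNst(tableFromCounts(cntF, DF), nPerm = 9)
  expect_true(is.na(gf$gst) || is.na(gf$nst))
  expect_false(is.null(gf$flag))
})

test_that("minimum-spanning network recovers planted topologies", {
  ## two haplotypes: a single edge at their distance
  cnt <- matrix(c(3L, 2L), 1, 2, dimnames = list("p", c("H1", "H2")))
  D <- matrix(c(0, 4, 4, 0), 2, 2,
              dimnames = list(c("H1", "H2"), c("H1", "H2")))
  net <- haplotypeNetwork(tableFromCounts(cnt, D))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 4)

  ## star: centre H1 with 4 satellites at 1 step (satellites at 2)
  haps <- paste0("H", 1:5)
  DS <- matrix(2, 5, 5, dimnames = list(haps, haps))
  DS[1, ] <- DS[, 1] <- 1; diag(DS) <- 0
  cntS <- matrix(rep(2L, 5), 1, 5, dimnames = list("p", haps))
  netS <- haplotypeNetwork(tableFromCounts(cntS, DS))
  mst <- netS$edges[netS$edges$steps == 1, ]
  expect_equal(nrow(mst), 4)
  expect_true(all(mst$from == "H1" | mst$to == "H1"))
  expect_gte(nrow(netS$edges), 4)   # spanning property
})
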