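## Independent oracles, written from the published formulas in plain
## scalar code so they share nothing with the package implementations.

## Weir & Cockerham (1984) theta for one locus, two or more populations
## given as lists of 2-column genotype matrices.
oracleWcTheta <- function(pops) {
  r <- length(pops)
  ni <- vapply(pops, nrow, 1L)
  alleles <- sort(unique(unlist(pops)))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p <- vapply(pops, function(m) mean(m == al), 0)
    h <- vapply(pops, function(m)
      mean(rowSums(m == al) == 1L), 0)
    pbar <- sum(ni * p) / (r * nbar)
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

## Excoffier sums of squares from an explicit unit-level squared
## distance matrix and a population assignment.
oracleAmovaSS <- function(d2, popOf) {
  ssWithin <- function(idx) {
    n <- length(idx)
    if (n < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / n
  }
  pops <- unique(popOf)
  list(ssT = ssWithin(seq_along(popOf)),
       ssWP = sum(vapply(pops, function(p)
         ssWithin(which(popOf == p)), 0)))
}

## unsigned Stirling numbers of the first kind by the textbook
## recurrence |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)|
oracleStirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1  # s(0,0)
  for (m in 1:n) for (k in 1:m) {
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  }
  s[n + 1, 2:(n + 1)]   # |s(n, 1..n)|
}

## Ewens P(K = k) directly from Stirling numbers
oracleEwens <- function(n, theta) {
  st <- oracleStirling(n)
  rising <- prod(theta + 0:(n - 1))
  st * theta^seq_len(n) / rising
}

## brute-force 12-statistic summary for a 3-species dataset
oracleSummary <- function(ds) {
  arr <- alleles(ds)
  sp <- speciesLabels(ds)
  lv <- levels(sp)
  L <- dim(arr)[2]
  nAll <- He <- numeric(3)
  for (s in 1:3) {
    idx <- which(sp == lv[s])
    na <- he <- numeric(L)
    for (l in seq_len(L)) {
      x <- c(arr[idx, l, 1], arr[idx, l, 2])
      tab <- table(x)
      na[l] <- length(tab)
      n <- sum(tab)
      he[l] <- n / (n - 1) * (1 - sum((tab / n)^2))
    }
    nAll[s] <- mean(na); He[s] <- mean(he)
  }
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  fst <- dmu <- numeric(3)
  for (k in 1:3) {
    i1 <- which(sp == lv[prs[[k]][1]]); i2 <- which(sp == lv[prs[[k]][2]])
    num <- den <- 0
    d <- numeric(L)
    for (l in seq_len(L)) {
      m1 <- cbind(arr[i1, l, 1], arr[i1, l, 2])
      m2 <- cbind(arr[i2, l, 1], arr[i2, l, 2])
      th <- oracleWcThetaComponents(list(m1, m2))
      num <- num + th[1]; den <- den + sum(th)
      d[l] <- (mean(m1) - mean(m2))^2
    }
    fst[k] <- num / den
    dmu[k] <- mean(d)
  }
  c(nAll, He, fst, dmu)
}

oracleWcThetaComponents <- function(pops) {
  r <- length(pops)
  ni <- vapply(pops, nrow, 1L)
  alleles <- sort(unique(unlist(pops)))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p <- vapply(pops, function(m) mean(m == al), 0)
    h <- vapply(pops, function(m) mean(rowSums(m == al) == 1L), 0)
    pbar <- sum(ni * p) / (r * nbar)
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h) / (r * nbar)
    A <- A + (nbar / nc) * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    B <- B + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  c(A, B, C)
}
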