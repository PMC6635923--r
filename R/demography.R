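## Neutrality tests and mismatch-distribution demography on cpDNA
## sequence groups (species pooled across their populations, following
## the per-species reporting convention).

## Expand a HaplotypeTable group into one sequence per individual.
.groupSequences <- function(x, group, level = c("species", "population")) {
  level <- match.arg(level)
  cnt <- x@counts
  if (level == "species") {
    sp <- x@speciesMap[rownames(cnt)]
    cnt <- rowsum(cnt, sp)
  }
  if (!group %in% rownames(cnt)) stop("unknown group: ", group)
  v <- cnt[group, ]
  if (!length(x@haplotypes)) stop("haplotype sequences required")
  rep(unname(x@haplotypes[colnames(cnt)]), v)
}

## S (segregating columns) and mean pairwise differences of a set of
## aligned sequences ('N' treated as missing).
.seqStats <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  segr <- apply(m, 2, function(col) {
    col <- col[col != "N"]
    length(unique(col)) > 1
  })
  S <- sum(segr)
  pd <- 0
  npair <- n * (n - 1) / 2
  dv <- numeric(npair)
  idx <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "N" & m[j, ] != "N"
    dv[idx] <- sum(m[i, ok] != m[j, ok])
    idx <- idx + 1
  }
  list(n = n, S = S, pi = mean(dv), pairDiffs = dv,
       k = length(unique(seqs)))
}

#' Tajima's D
#'
#' Standard D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)) with the usual
#' a1, a2, b1, b2, c1, c2, e1, e2 constants. Undefined (NA, flagged)
#' when there is no segregating site or n < 4.
#'
#' @param x character vector of aligned sequences, or a
#'   [HaplotypeTable-class].
#' @param group,level when `x` is a table: which group to test
#'   (default: species level).
#' @param nSim if > 0, a p-value is computed as the fraction of neutral
#'   constant-size coalescent simulations (theta fixed at the observed
#'   mean pairwise difference) with simulated D <= observed.
#' @param seed RNG seed for the simulations.
#' @return list with `D`, `S`, `pi`, `n`, optional `p`, `flag`.
#' @export
tajimasD <- function(x, group = NULL, level = "species", nSim = 0,
                     seed = NULL) {
  seqs <- if (is(x, "HaplotypeTable"))
    .groupSequences(x, group, level) else x
  st <- .seqStats(seqs)
  res <- list(D = NA_real_, S = st$S, pi = st$pi, n = st$n, flag = NULL)
  if (st$n < 4) { res$flag <- "n < 4"; return(res) }
  if (st$S < 1) { res$flag <- "no segregating sites"; return(res) }
  n <- st$n
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  res$D <- (st$pi - st$S / a1) /
    sqrt(e1 * st$S + e2 * st$S * (st$S - 1))
  if (nSim > 0) {
    if (!is.null(seed)) set.seed(seed)
    sims <- replicate(nSim, {
      h <- .coalInfSites(n, tau = 0, theta0 = st$pi, theta1 = st$pi)
      if (h$S < 1) return(NA_real_)
      (h$pi - h$S / a1) / sqrt(e1 * h$S + e2 * h$S * (h$S - 1))
    })
    sims <- sims[!is.na(sims)]
    res$p <- (sum(sims <= res$D) + 1) / (length(sims) + 1)
  }
  res
}

#' Fu's Fs
#'
#' With theta estimated by the mean pairwise difference, `S' = P(K >=
#' k_obs | theta, n)` under the Ewens sampling formula (computed with a
#' numerically stable recurrence equivalent to unsigned Stirling numbers
#' of the first kind), and `Fs = ln(S' / (1 - S'))`. Degenerate cases
#' (k = 1, or S' indistinguishable from 0/1) are guarded and flagged.
#'
#' @inheritParams tajimasD
#' @param nSim if > 0, p-value as the fraction of neutral simulations
#'   with Fs <= observed.
#' @return list with `Fs`, `k`, `thetaPi`, `n`, optional `p`, `flag`.
#' @export
fusFs <- function(x, group = NULL, level = "species", nSim = 0,
                  seed = NULL) {
  seqs <- if (is(x, "HaplotypeTable"))
    .groupSequences(x, group, level) else x
  st <- .seqStats(seqs)
  fs <- .fsFromTheta(st$n, st$k, st$pi)
  res <- c(list(n = st$n, k = st$k, thetaPi = st$pi), fs)
  if (nSim > 0 && is.finite(fs$Fs)) {
    if (!is.null(seed)) set.seed(seed)
    sims <- replicate(nSim, {
      h <- .coalInfSites(st$n, tau = 0, theta0 = st$pi,
                         theta1 = st$pi)
      v <- .fsFromTheta(st$n, h$k, h$pi)$Fs
      if (is.finite(v)) v else NA_real_
    })
    sims <- sims[!is.na(sims)]
    res$p <- (sum(sims <= fs$Fs) + 1) / (length(sims) + 1)
  }
  res
}

## P(K = k) under Ewens via the stable recurrence
## q_{m+1}(k) = (m q_m(k) + theta q_m(k-1)) / (theta + m).
.ewensK <- function(n, theta) {
  q <- 1                                # q_1: P(K=1)=1
  if (n == 1) return(q)
  for (m in seq_len(n - 1)) {
    qNew <- numeric(m + 1)
    qNew[seq_len(m)] <- m * q / (theta + m)
    qNew[2:(m + 1)] <- qNew[2:(m + 1)] + theta * q / (theta + m)
    q <- qNew
  }
  q                                     # vector over k = 1..n
}

.fsFromTheta <- function(n, k, theta) {
  if (k <= 1 || theta <= 0)
    return(list(Fs = Inf, Sprime = 1,
                flag = "k = 1 or theta = 0: Fs undefined (+Inf guard)"))
  pk <- .ewensK(n, theta)
  Sp <- sum(pk[k:n])
  if (Sp >= 1 - 1e-12)
    return(list(Fs = Inf, Sprime = 1, flag = "S' ~ 1: +Inf guard"))
  if (Sp <= 1e-300)
    return(list(Fs = -Inf, Sprime = 0, flag = "S' ~ 0: -Inf guard"))
  list(Fs = log(Sp / (1 - Sp)), Sprime = Sp, flag = NULL)
}

## ---- two-epoch infinite-sites coalescent -----------------------------
## Time is measured in mutational units (expected pairwise differences);
## a pair coalesces at rate 1/theta, so k lineages at rate C(k,2)/theta,
## and each lineage mutates at rate 1/2 per unit. theta = theta1 more
## recently than tau, theta0 beyond. Returns pairwise-difference
## statistics of the n sampled sequences.
.coalInfSites <- function(n, tau, theta0, theta1) {
  ## mutation counts from each leaf to the current top of its lineage
  memb <- lapply(seq_len(n), function(i) i)   # leaves per lineage
  muts <- lapply(seq_len(n), function(i) 0)   # per-leaf mutation counts
  D <- matrix(0, n, n)
  t <- 0; k <- n; S <- 0
  repeat {
    if (k == 1) break
    th <- if (t < tau) theta1 else theta0
    rate <- k * (k - 1) / 2 / th
    dt <- rexp(1, rate)
    if (t < tau && t + dt > tau) {      # epoch switch: redraw beyond tau
      dtOld <- tau - t
      ## memoryless: advance to tau, continue in old epoch
      dt <- dtOld
      tNew <- tau
      ## add mutations for the elapsed time, no coalescence
      for (li in seq_along(memb)) {
        m <- rpois(1, dt / 2)
        if (m > 0) {
          S <- S + m
          muts[[li]] <- muts[[li]] + m
        }
      }
      t <- tNew
      next
    }
    ## mutations during dt on each lineage
    for (li in seq_along(memb)) {
      m <- rpois(1, dt / 2)
      if (m > 0) {
        S <- S + m
        muts[[li]] <- muts[[li]] + m
      }
    }
    t <- t + dt
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    ## distances across the merging clades
    for (a in seq_along(memb[[i]])) for (b in seq_along(memb[[j]])) {
      D[memb[[i]][a], memb[[j]][b]] <-
        D[memb[[j]][b], memb[[i]][a]] <-
        muts[[i]][a] + muts[[j]][b]
    }
    memb[[i]] <- c(memb[[i]], memb[[j]])
    muts[[i]] <- c(muts[[i]], muts[[j]])
    memb[[j]] <- NULL; muts[[j]] <- NULL
    k <- k - 1
  }
  dv <- D[upper.tri(D)]
  grp <- integer(n); grp[1] <- 1L; ng <- 1L
  for (i in 2:n) {
    hit <- which(vapply(seq_len(i - 1),
                        function(j) D[i, j] == 0, TRUE))[1]
    if (!is.na(hit)) grp[i] <- grp[hit]
    else { ng <- ng + 1L; grp[i] <- ng }
  }
  list(pairDiffs = dv, pi = mean(dv), S = S, k = max(grp),
       hist = tabulate(dv + 1, nbins = max(dv) + 1))
}

## ---- sudden-expansion mismatch model ---------------------------------

#' Expected mismatch distribution under sudden expansion
#'
#' Exact two-epoch pairwise-coalescent probabilities of observing `j`
#' differences: an expansion at mutational time `tau` changed the scaled
#' size from `theta0` (ancestral) to `theta1` (current). Obtained by
#' integrating the Poisson mixture over the two-epoch coalescence-time
#' density (regularized incomplete gamma + Poisson/geometric
#' convolution), rather than the classical small-theta approximation.
#'
#' @param tau,theta0,theta1 non-negative model parameters.
#' @param maxD largest difference class.
#' @return numeric vector of probabilities for 0..maxD differences.
#' @export
mismatchExpected <- function(tau, theta0, theta1, maxD) {
  j <- 0:maxD
  lam <- (theta1 + 1) / theta1
  recent <- if (theta1 > 0)
    exp(j * log(theta1) - (j + 1) * log(1 + theta1)) *
      pgamma(lam * tau, shape = j + 1)
  else as.numeric(j == 0) * (tau > 0)
  geo <- if (theta0 > 0)
    exp(j * log(theta0) - (j + 1) * log(1 + theta0))
  else c(1, rep(0, maxD))
  pois <- dpois(j, tau)
  conv <- stats::convolve(pois, rev(geo), type = "open")[seq_len(maxD + 1)]
  old <- exp(-if (theta1 > 0) tau / theta1 else Inf * (tau > 0)) * conv
  if (tau == 0) old <- geo
  p <- recent + old
  p[p < 0] <- 0
  p
}

## SSD objective on relative frequencies, expectation renormalized over
## the observed support.
.mismatchSSD <- function(par, obsRel) {
  maxD <- length(obsRel) - 1
  e <- mismatchExpected(par[1], par[2], par[3], maxD)
  s <- sum(e)
  if (s <= 0) return(Inf)
  e <- e / s
  sum((obsRel - e)^2)
}

#' Harpending's raggedness index
#'
#' `r = sum (x_{i+1} - x_i)^2` over adjacent relative frequencies of the
#' difference classes 0..maxD.
#'
#' @param counts histogram of pairwise differences (class 0 first).
#' @export
raggedness <- function(counts) {
  x <- counts / sum(counts)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least squares on relative frequencies over (tau, theta0, theta1)
#' (bounded Nelder--Mead in log space with random multi-starts), with
#' parametric-bootstrap p-values for the SSD and raggedness
#' goodness-of-fit statistics: replicates are simulated under the fitted
#' expansion with a two-epoch coalescent, the model is refitted to each,
#' and `p = (#{stat_rep >= stat_obs} + 1) / (nBoot + 1)`.
#'
#' @param x a [HaplotypeTable-class] (with sequences) or a numeric
#'   histogram of pairwise differences (class 0 first).
#' @param group,level group selection when `x` is a table.
#' @param nBoot bootstrap replicates (default 1000; 0 = no p-values).
#' @param nStarts random restarts for the optimizer (default 10).
#' @param seed RNG seed.
#' @return object of class `peony_mismatch`: observed histogram, `tau`,
#'   `theta0`, `theta1`, `ssd`, `raggedness`, `pSSD`, `pRag`, `n`,
#'   `flags`.
#' @export
mismatchFit <- function(x, group = NULL, level = "species",
                        nBoot = 1000, nStarts = 10, seed = NULL) {
  if (is(x, "HaplotypeTable")) {
    seqs <- .groupSequences(x, group, level)
    st <- .seqStats(seqs)
    n <- st$n
    if (n < 4) stop("mismatch analysis needs n >= 4")
    obs <- tabulate(st$pairDiffs + 1, nbins = max(st$pairDiffs) + 1)
  } else {
    obs <- as.numeric(x)
    n <- round((1 + sqrt(1 + 8 * sum(obs))) / 2)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- .fitMismatch(obs, nStarts)
  ssdObs <- fit$value
  ragObs <- raggedness(obs)
  pSSD <- pRag <- NA_real_
  if (nBoot > 0) {
    ssdB <- ragB <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      sim <- .coalInfSites(n, fit$par[1], fit$par[2], fit$par[3])
      h <- sim$hist
      refit <- .fitMismatch(h, nStarts = 2, init = fit$par)
      ssdB[b] <- refit$value
      ragB[b] <- raggedness(h)
    }
    pSSD <- (sum(ssdB >= ssdObs) + 1) / (nBoot + 1)
    pRag <- (sum(ragB >= ragObs) + 1) / (nBoot + 1)
  }
  flags <- character()
  if (fit$par[3] < fit$par[2])
    flags <- c(flags, "theta1 < theta0 at optimum (contraction-like fit)")
  if (!fit$converged) flags <- c(flags, "optimizer did not converge")
  structure(list(observed = obs, tau = fit$par[1],
                 theta0 = fit$par[2], theta1 = fit$par[3],
                 ssd = ssdObs, raggedness = ragObs,
                 pSSD = pSSD, pRag = pRag, n = n, flags = flags),
            class = "peony_mismatch")
}

## log-space Nelder-Mead with multi-start; init optionally supplies a
## known good start.
.fitMismatch <- function(obs, nStarts, init = NULL) {
  obsRel <- obs / sum(obs)
  maxD <- length(obs) - 1
  mean0 <- sum((0:maxD) * obsRel)
  obj <- function(u) .mismatchSSD(exp(u), obsRel)
  starts <- list(log(c(max(mean0, 0.5), 0.1 + 0.1 * mean0,
                       max(1, 2 * mean0))))
  if (!is.null(init)) starts <- c(list(log(pmax(init, 1e-3))), starts)
  extra <- max(0, nStarts - length(starts))
  for (s in seq_len(extra)) {
    starts[[length(starts) + 1L]] <-
      log(c(runif(1, 0.1, max(2 * mean0, 2)),
            runif(1, 0.01, max(mean0, 1)),
            runif(1, 0.5, max(4 * mean0, 4))))
  }
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("mismatch optimization failed from all starts")
  list(par = exp(best$par), value = best$value,
       converged = best$convergence == 0)
}

#' @export
print.peony_mismatch <- function(x, ...) {
  cat("Sudden-expansion mismatch fit (n =", x$n, ")\n")
  cat(sprintf("  tau = %.3f  theta0 = %.3f  theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.4f (p = %s)   raggedness = %.4f (p = %s)\n",
              x$ssd, format(x$pSSD, digits = 3),
              x$raggedness, format(x$pRag, digits = 3)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "),
                           "\n")
  invisible(x)
}

#' Per-species neutrality and mismatch report
#'
#' Convenience wrapper running Tajima's D, Fu's Fs and the mismatch fit
#' for each species of a haplotype table (individuals pooled across the
#' species' populations).
#'
#' @param x a [HaplotypeTable-class] with sequences.
#' @param nSim simulations for the D / Fs p-values.
#' @param nBoot bootstrap replicates for the mismatch p-values.
#' @param seed RNG seed.
#' @return data.frame, one row per species: D, pD, Fs, pFs, SSD, pSSD,
#'   raggedness, pRag.
#' @export
demographyReport <- function(x, nSim = 1000, nBoot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- unique(unname(x@speciesMap[rownames(x@counts)]))
  rows <- lapply(sp, function(s) {
    d <- tajimasD(x, s, nSim = nSim)
    f <- fusFs(x, s, nSim = nSim)
    m <- mismatchFit(x, s, nBoot = nBoot)
    data.frame(species = s, D = d$D,
               pD = if (!is.null(d$p)) d$p else NA_real_,
               Fs = f$Fs, pFs = if (!is.null(f$p)) f$p else NA_real_,
               SSD = m$ssd, pSSD = m$pSSD,
               raggedness = m$raggedness, pRag = m$pRag)
  })
  do.call(rbind, rows)
}
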