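## Climatic niche divergence: correlation-based variable filtering,
## standardized PCA over occurrence + background points, and the
## background (d_b) versus observed (d_n) centroid-divergence test.

#' Greedy correlation filter for climate variables
#'
#' While any absolute pairwise Pearson correlation is at or above the
#' threshold, the variable with the largest mean absolute correlation
#' to all others is dropped (ties broken deterministically by dropping
#' the later column). Constant columns are dropped first with a
#' warning.
#'
#' @param x numeric matrix or data.frame of candidate variables.
#' @param threshold correlation threshold (default 0.8).
#' @return character vector of retained variable names.
#' @export
filterCorrelated <- function(x, threshold = 0.8) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 variables")
  keep <- colnames(x)
  const <- vapply(x, function(v) sd(v) == 0 || !is.finite(sd(v)), TRUE)
  if (any(const)) {
    warning("constant variables dropped: ",
            paste(keep[const], collapse = ", "))
    keep <- keep[!const]
  }
  repeat {
    if (length(keep) < 2) break
    C <- abs(cor(x[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) < threshold) break
    mc <- rowMeans(C)
    worst <- which(mc == max(mc))
    drop <- keep[worst[length(worst)]]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Standardized PCA of a niche dataset
#'
#' Z-score standardized principal components computed jointly over
#' occurrence and background points (of the selected species).
#'
#' @param nd a [NicheDataset-class].
#' @param vars variables to use (default: all; pass the output of
#'   [filterCorrelated()] to reduce first).
#' @param species optional subset of species.
#' @return list with `occScores`, `bgScores` (with species columns),
#'   `loadings`, `explained`, `vars`.
#' @export
nichePCA <- function(nd, vars = NULL, species = NULL) {
  stopifnot(is(nd, "NicheDataset"))
  if (is.null(vars)) vars <- nd@varNames
  if (length(vars) < 2) stop("need at least 2 retained variables")
  occ <- nd@occurrences; bg <- nd@background
  if (!is.null(species)) {
    occ <- occ[occ$species %in% species, ]
    bg <- bg[bg$species %in% species, ]
  }
  X <- rbind(as.matrix(occ[, vars, drop = FALSE]),
             as.matrix(bg[, vars, drop = FALSE]))
  if (nrow(X) < length(vars))
    warning("fewer points than variables; PCA limited to available rank")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  nOcc <- nrow(occ)
  list(occScores = data.frame(species = occ$species,
                              pc$x[seq_len(nOcc), , drop = FALSE]),
       bgScores = data.frame(species = bg$species,
                             pc$x[-seq_len(nOcc), , drop = FALSE]),
       loadings = pc$rotation, explained = ev / sum(ev), vars = vars,
       occMeta = occ[, c("species", "lat", "lon")])
}

#' Background vs observed niche divergence test for a species pair
#'
#' On each of the first `k` PCA axes (joint standardized PCA of the
#' pair's occurrences and background points), the observed divergence
#' `d_n` is the absolute difference of the species' occurrence-score
#' means. The null distribution of background divergence `d_b`
#' resamples each species' background points with replacement (sample
#' size = its occurrence count) and records the absolute centroid
#' difference; its 2.5--97.5% interval is reported. `d_n` itself is
#' tested against a species-label permutation null across occurrences.
#' Verdicts per axis: `"divergence"` when `d_n` exceeds the upper d_b
#' bound and the permutation test rejects; `"conservatism"` when `d_n`
#' falls below the lower bound; otherwise `"none"`.
#'
#' @param nd a [NicheDataset-class].
#' @param pair character vector of two species.
#' @param vars variables (default: [filterCorrelated()] on the pooled
#'   background at 0.8).
#' @param k number of axes (default 2).
#' @param nResample background resamples / permutations (default 1000).
#' @param seed RNG seed.
#' @param alpha significance level for the permutation test.
#' @return object of class `peony_niche`: per-axis data.frame plus the
#'   PCA summaries (explained variance, top loadings, geographic
#'   correlations of the scores).
#' @export
divergenceTest <- function(nd, pair, vars = NULL, k = 2,
                           nResample = 1000, seed = NULL,
                           alpha = 0.05) {
  stopifnot(is(nd, "NicheDataset"), length(pair) == 2)
  if (is.null(vars))
    vars <- filterCorrelated(nd@background[nd@background$species %in%
                                             pair, nd@varNames])
  if (!is.null(seed)) set.seed(seed)
  pc <- nichePCA(nd, vars, species = pair)
  k <- min(k, sum(pc$explained > 1e-12))
  occA <- pc$occScores[pc$occScores$species == pair[1], -1, drop = FALSE]
  occB <- pc$occScores[pc$occScores$species == pair[2], -1, drop = FALSE]
  bgA <- pc$bgScores[pc$bgScores$species == pair[1], -1, drop = FALSE]
  bgB <- pc$bgScores[pc$bgScores$species == pair[2], -1, drop = FALSE]
  if (nrow(occA) < 3 || nrow(occB) < 3)
    stop("need >= 3 occurrences per species")
  nA <- nrow(occA); nB <- nrow(occB)
  rows <- list()
  for (ax in seq_len(k)) {
    sdAx <- sd(c(occA[, ax], occB[, ax]))
    if (!is.finite(sdAx) || sdAx < 1e-12) next   # degenerate axis
    dn <- abs(mean(occA[, ax]) - mean(occB[, ax]))
    db <- replicate(nResample, {
      a <- mean(sample(bgA[, ax], nA, replace = TRUE))
      b <- mean(sample(bgB[, ax], nB, replace = TRUE))
      abs(a - b)
    })
    dbq <- quantile(db, c(0.025, 0.975), names = FALSE)
    pooled <- c(occA[, ax], occB[, ax])
    perm <- replicate(nResample, {
      sh <- sample(pooled)
      abs(mean(sh[seq_len(nA)]) - mean(sh[nA + seq_len(nB)]))
    })
    pPerm <- (sum(perm >= dn - 1e-12) + 1) / (nResample + 1)
    verdict <- if (dn > dbq[2] && pPerm <= alpha) "divergence"
               else if (dn < dbq[1]) "conservatism"
               else "none"
    top <- names(sort(abs(pc$loadings[, ax]), decreasing = TRUE))[
      seq_len(min(3, nrow(pc$loadings)))]
    rows[[ax]] <- data.frame(
      axis = paste0("PC", ax), dn = dn, dbLower = dbq[1],
      dbUpper = dbq[2], pPerm = pPerm, verdict = verdict,
      explained = pc$explained[ax],
      topLoadings = paste(top, collapse = ","))
  }
  tab <- do.call(rbind, rows)
  ## geographic correlations of occurrence scores
  geo <- NULL
  meta <- pc$occMeta
  if (nrow(meta) == nA + nB) {
    geo <- do.call(rbind, lapply(seq_len(k), function(ax) {
      sc <- c(occA[, ax], occB[, ax])
      data.frame(axis = paste0("PC", ax),
                 rLat = cor(sc, meta$lat), rLon = cor(sc, meta$lon))
    }))
  }
  structure(list(pair = pair, table = tab, geographic = geo,
                 vars = vars, nResample = nResample),
            class = "peony_niche")
}

#' @export
print.peony_niche <- function(x, ...) {
  cat("Niche divergence test:", paste(x$pair, collapse = " vs "), "\n")
  tb <- x$table
  tb$dn <- round(tb$dn, 3)
  tb$dbLower <- round(tb$dbLower, 3); tb$dbUpper <- round(tb$dbUpper, 3)
  tb$explained <- round(100 * tb$explained, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}
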