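## Chloroplast haplotype analysis: collapsing aligned sequences into
## haplotypes (indels recoded as single binary characters), diversity
## statistics, GST/NST permutation test and a minimum-spanning haplotype
## network.

#' @rdname accessors
#' @export
setMethod("hapCounts", "HaplotypeTable", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("hapDiffs", "HaplotypeTable", function(x) x@diffs)
#' @rdname accessors
#' @export
setMethod("hapSequences", "HaplotypeTable", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("speciesMap", "HaplotypeTable", function(x) x@speciesMap)

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", ncol(object@counts), "haplotypes,",
      nrow(object@counts), "populations,",
      sum(object@counts), "individuals\n")
  if (length(object@diffs))
    cat("  pairwise differences available (", object@seqLength,
        " columns)\n", sep = "")
  invisible(object)
})

#' Collapse an alignment into a haplotype table
#'
#' Contiguous alignment columns sharing an identical gap-presence
#' pattern are recoded as a single binary character (`A` = gap absent,
#' `T` = gap present), following the convention of coding indels as
#' substitutions. Identical recoded sequences are merged; haplotype ids
#' `H1`, `H2`, ... are assigned in order of first appearance. IUPAC
#' ambiguity codes are treated as missing for difference counting (with
#' a warning).
#'
#' @param alignment character matrix (rows = sequences; see
#'   [readAlignmentFasta()]), a named character vector of aligned
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @param assignments data.frame with columns `sample`, `pop`,
#'   `species`; every sequence must be assigned.
#' @return a [HaplotypeTable-class].
#' @export
collapseHaplotypes <- function(alignment, assignments) {
  if (is(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (is.character(alignment) && is.null(dim(alignment))) {
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
    alignment <- m
  }
  if (is.null(rownames(alignment)))
    stop("alignment sequences must be named")
  if (!all(c("sample", "pop", "species") %in% colnames(assignments)))
    stop("assignments needs columns sample, pop, species")
  miss <- setdiff(rownames(alignment), assignments$sample)
  if (length(miss))
    stop("unassigned sequences: ", paste(head(miss), collapse = ", "))
  ## ---- indel recoding ------------------------------------------------
  isGap <- alignment == "-"
  gapCols <- which(colSums(isGap) > 0)
  keep <- rep(TRUE, ncol(alignment))
  if (length(gapCols)) {
    pat <- apply(isGap[, gapCols, drop = FALSE], 2, paste, collapse = "")
    runId <- cumsum(c(TRUE, diff(gapCols) != 1L | pat[-1] != pat[-length(pat)]))
    for (rid in unique(runId)) {
      colsRun <- gapCols[runId == rid]
      first <- colsRun[1]
      alignment[, first] <- ifelse(isGap[, first], "T", "A")
      if (length(colsRun) > 1) keep[colsRun[-1]] <- FALSE
    }
  }
  alignment <- alignment[, keep, drop = FALSE]
  ## ---- ambiguity handling -------------------------------------------
  amb <- !(alignment %in% c("A", "C", "G", "T", "N"))
  if (any(amb)) {
    warning(sum(amb), " ambiguity codes treated as missing")
    alignment[amb] <- "N"
  }
  ## ---- merge identical sequences ------------------------------------
  seqStr <- apply(alignment, 1, paste, collapse = "")
  uni <- unique(seqStr)
  hapIds <- paste0("H", seq_along(uni))
  hapOf <- hapIds[match(seqStr, uni)]
  hapSeq <- setNames(uni, hapIds)
  H <- length(uni)
  ## ---- pairwise differences (N = missing) ---------------------------
  D <- matrix(0, H, H, dimnames = list(hapIds, hapIds))
  hm <- do.call(rbind, strsplit(uni, ""))
  if (H > 1) for (i in seq_len(H - 1)) for (j in (i + 1):H) {
    ok <- hm[i, ] != "N" & hm[j, ] != "N"
    D[i, j] <- D[j, i] <- sum(hm[i, ok] != hm[j, ok])
  }
  ## ---- counts --------------------------------------------------------
  idx <- match(rownames(alignment), assignments$sample)
  pop <- as.character(assignments$pop[idx])
  pops <- unique(assignments$pop)
  cnt <- matrix(0L, length(pops), H, dimnames = list(pops, hapIds))
  for (k in seq_along(pop))
    cnt[pop[k], hapOf[k]] <- cnt[pop[k], hapOf[k]] + 1L
  spMap <- setNames(as.character(assignments$species),
                    as.character(assignments$pop))
  spMap <- spMap[!duplicated(names(spMap))]
  new("HaplotypeTable", haplotypes = hapSeq, diffs = D,
      counts = cnt, speciesMap = spMap,
      seqLength = ncol(alignment))
}

#' @describeIn haplotypeDiversity Nei's unbiased haplotype diversity
#'   `Hd = n/(n-1) (1 - sum p_i^2)` from a vector of haplotype counts.
#' @export
setMethod("haplotypeDiversity", "numeric", function(x, ...) {
  x <- x[x > 0]
  n <- sum(x)
  if (n < 2) {
    out <- NA_real_
    attr(out, "flag") <- "undefined for n < 2"
    return(out)
  }
  unname(n / (n - 1) * (1 - sum((x / n)^2)))
})

#' @describeIn haplotypeDiversity per-population and pooled per-species
#'   haplotype diversity from a [HaplotypeTable-class]. Species-level
#'   values pool individuals across the species' populations.
#' @param level `"population"` or `"species"`.
#' @export
setMethod("haplotypeDiversity", "HaplotypeTable",
  function(x, level = c("population", "species"), ...) {
    level <- match.arg(level)
    cnt <- x@counts
    if (level == "species") {
      sp <- x@speciesMap[rownames(cnt)]
      cnt <- rowsum(cnt, sp)
    }
    setNames(apply(cnt, 1, function(v) haplotypeDiversity(as.numeric(v))),
             rownames(cnt))
  })

#' Nucleotide diversity from a haplotype table
#'
#' `pi = sum_{i<j} d(h_i, h_j) / C(n,2) / L` over all individual pairs
#' in a group, computed from haplotype counts and the pairwise
#' difference matrix.
#'
#' @param x a [HaplotypeTable-class] with `diffs`.
#' @param level `"population"` or `"species"` (pooled).
#' @param seqLength alignment length; defaults to the table's.
#' @return named numeric per group.
#' @export
nucleotideDiversity <- function(x, level = c("population", "species"),
                                seqLength = NULL) {
  stopifnot(is(x, "HaplotypeTable"))
  if (!length(x@diffs)) stop("pairwise differences required")
  level <- match.arg(level)
  if (is.null(seqLength)) seqLength <- x@seqLength
  cnt <- x@counts
  if (level == "species") {
    sp <- x@speciesMap[rownames(cnt)]
    cnt <- rowsum(cnt, sp)
  }
  D <- x@diffs[colnames(cnt), colnames(cnt)]
  apply(cnt, 1, function(v) {
    n <- sum(v)
    if (n < 2) return(NA_real_)
    tot <- as.numeric(crossprod(v, D %*% v)) / 2
    tot / choose(n, 2) / seqLength
  })
}

## Pons & Petit estimators for one set of populations. `cnt`: pops x
## haplotypes counts; `D`: haplotype distance matrix (NULL -> identity
## distance, i.e. the GST limit).
.ponsPetit <- function(cnt, D = NULL) {
  cnt <- cnt[rowSums(cnt) >= 2, , drop = FALSE]
  K <- nrow(cnt)
  if (K < 2) return(NA_real_)
  n_k <- rowSums(cnt)
  p <- cnt / n_k
  if (is.null(D)) D <- 1 - diag(ncol(cnt))
  vk <- vapply(seq_len(K), function(k) {
    n_k[k] / (n_k[k] - 1) *
      as.numeric(crossprod(p[k, ], D %*% p[k, ]))
  }, 0)
  vS <- mean(vk)
  nTilde <- K / sum(1 / n_k)
  xbar <- colMeans(p)
  vT <- as.numeric(crossprod(xbar, D %*% xbar)) + vS / (nTilde * K)
  if (vT <= 0) return(NA_real_)
  1 - vS / vT
}

#' GST and NST with a phylogeographic-structure permutation test
#'
#' `GST` uses haplotype frequencies only; `NST` additionally weights by
#' haplotype pairwise distances (Pons & Petit estimators; populations
#' with fewer than 2 individuals are dropped). `NST > GST` indicates
#' that closely related haplotypes co-occur within populations
#' (phylogeographic structure); significance is assessed by permuting
#' haplotype identities in the distance matrix and recomputing NST
#' (one-tailed, `(hits + 1)/(nPerm + 1)`).
#'
#' @param x a [HaplotypeTable-class] with `diffs`.
#' @param species optional species label: restrict to its populations.
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `gst`, `nst`, `p`, `nPerm`; NA statistics (with a
#'   `flag`) when all populations are fixed for one haplotype.
#' @export
gstNst <- function(x, species = NULL, nPerm = 10000, seed = NULL) {
  stopifnot(is(x, "HaplotypeTable"))
  if (!length(x@diffs)) stop("pairwise differences required")
  cnt <- x@counts
  if (!is.null(species)) {
    keep <- x@speciesMap[rownames(cnt)] == species
    cnt <- cnt[keep, , drop = FALSE]
  }
  cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  D <- x@diffs[colnames(cnt), colnames(cnt)]
  gst <- .ponsPetit(cnt)
  nst <- .ponsPetit(cnt, D)
  if (is.na(gst) || is.na(nst)) {
    return(structure(list(gst = gst, nst = nst, p = NA_real_,
                          nPerm = nPerm,
                          flag = "undefined (no haplotype variation or < 2 usable populations)"),
                     class = "peony_gstnst"))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  H <- ncol(cnt)
  for (b in seq_len(nPerm)) {
    perm <- sample.int(H)
    nstP <- .ponsPetit(cnt, D[perm, perm])
    if (!is.na(nstP) && nstP >= nst - 1e-12) hits <- hits + 1L
  }
  structure(list(gst = gst, nst = nst,
                 p = (hits + 1) / (nPerm + 1), nPerm = nPerm,
                 flag = NULL),
            class = "peony_gstnst")
}

#' @export
print.peony_gstnst <- function(x, ...) {
  cat("GST =", round(x$gst, 4), " NST =", round(x$nst, 4), "\n")
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  else cat("P(NST > GST) =", signif(x$p, 3), "(", x$nPerm,
           "permutations )\n")
  invisible(x)
}

#' Minimum-spanning haplotype network
#'
#' Returns every edge that occurs in at least one minimum spanning tree
#' of the haplotype distance graph (all MST edges plus tied-weight
#' alternatives), so alternative equally parsimonious connections are
#' retained.
#'
#' @param x a [HaplotypeTable-class] with `diffs` and >= 2 haplotypes.
#' @return list with `edges` (data.frame `from`, `to`, `steps`) and
#'   `nodeSizes` (total count per haplotype).
#' @export
haplotypeNetwork <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  if (!length(x@diffs)) stop("pairwise differences required")
  cnt <- x@counts
  haps <- colnames(cnt)[colSums(cnt) > 0]
  H <- length(haps)
  if (H < 2) stop("network needs at least 2 haplotypes")
  D <- x@diffs[haps, haps]
  ## Kruskal over weight classes; an edge belongs to some MST iff its
  ## endpoints are in different components of the graph restricted to
  ## strictly smaller weights.
  comp <- seq_len(H)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- data.frame(from = character(), to = character(),
                      steps = numeric())
  ij <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[ij]
  o <- order(w)
  ij <- ij[o, , drop = FALSE]; w <- w[o]
  k <- 1
  while (k <= length(w)) {
    klass <- which(abs(w - w[k]) < 1e-9)
    klass <- klass[klass >= k]
    sel <- integer()
    for (e in klass) {
      ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
      if (ri != rj)
        sel <- c(sel, e)
    }
    for (e in sel) {
      edges <- rbind(edges, data.frame(
        from = haps[ij[e, 1]], to = haps[ij[e, 2]], steps = w[e]))
    }
    for (e in sel) {
      ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
      if (ri != rj) comp[ri] <- rj
    }
    k <- max(klass) + 1
  }
  list(edges = edges,
       nodeSizes = colSums(x@counts)[haps])
}

#' Write a haplotype network as Graphviz DOT
#'
#' @param net result of [haplotypeNetwork()].
#' @param file output path.
#' @export
writeNetworkDot <- function(net, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("graph haplotypes {", con)
  for (h in names(net$nodeSizes))
    writeLines(sprintf('  %s [width=%.2f];', h,
                       0.3 + 0.1 * sqrt(net$nodeSizes[[h]])), con)
  for (i in seq_len(nrow(net$edges)))
    writeLines(sprintf('  %s -- %s [label="%g"];',
                       net$edges$from[i], net$edges$to[i],
                       net$edges$steps[i]), con)
  writeLines("}", con)
  invisible(file)
}
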