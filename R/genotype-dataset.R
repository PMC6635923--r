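#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenotypeDataset
#'
#' @param alleles integer array `n x loci x 2` of allele sizes (`NA` =
#'   missing; both alleles of a call must be missing together), or an
#'   `n x (2*loci)` matrix with the two alleles of each locus in adjacent
#'   columns.
#' @param pop character or factor of length `n`: population of each
#'   individual.
#' @param speciesMap named character mapping population -> species. If
#'   omitted, every population is assigned to a single species "sp1".
#' @param coords optional data.frame with columns `pop`, `lat`, `lon`.
#' @param lociNames optional character vector of locus names.
#' @return a [GenotypeDataset-class].
#' @examples
#' a <- array(c(100L, 100L, 100L, 102L), dim = c(2, 1, 2))
#' ds <- GenotypeDataset(a, pop = c("p1", "p1"))
#' nInd(ds)
#' @export
GenotypeDataset <- function(alleles, pop, speciesMap = NULL, coords = NULL,
                            lociNames = NULL) {
  if (is.matrix(alleles)) {
    if (ncol(alleles) %% 2L != 0L)
      stop("matrix input must have an even number of columns (2 per locus)")
    L <- ncol(alleles) / 2L
    a <- array(NA_integer_, dim = c(nrow(alleles), L, 2L))
    a[, , 1] <- alleles[, 2L * seq_len(L) - 1L]
    a[, , 2] <- alleles[, 2L * seq_len(L)]
    alleles <- a
  }
  storage.mode(alleles) <- "integer"
  pop <- as.factor(pop)
  if (is.null(speciesMap)) {
    speciesMap <- setNames(rep("sp1", nlevels(pop)), levels(pop))
  }
  if (is.null(coords)) {
    coords <- data.frame(pop = character(), lat = numeric(),
                         lon = numeric())
  }
  if (!is.null(lociNames)) {
    dimnames(alleles) <- list(NULL, lociNames, NULL)
  } else if (is.null(dimnames(alleles)[[2]])) {
    dimnames(alleles) <- list(NULL, paste0("L", seq_len(dim(alleles)[2])),
                              NULL)
  }
  new("GenotypeDataset", alleles = alleles, popLabels = pop,
      speciesMap = speciesMap, coords = coords)
}

#' @rdname accessors
#' @export
setMethod("alleles", "GenotypeDataset", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("popLabels", "GenotypeDataset", function(x) x@popLabels)
#' @rdname accessors
#' @export
setMethod("speciesMap", "GenotypeDataset", function(x) x@speciesMap)
#' @rdname accessors
#' @export
setMethod("speciesLabels", "GenotypeDataset", function(x) {
  factor(unname(x@speciesMap[as.character(x@popLabels)]))
})
#' @rdname accessors
#' @export
setMethod("popCoords", "GenotypeDataset", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("nInd", "GenotypeDataset", function(x) dim(x@alleles)[1])
#' @rdname accessors
#' @export
setMethod("nLoci", "GenotypeDataset", function(x) dim(x@alleles)[2])
#' @rdname accessors
#' @export
setMethod("lociNames", "GenotypeDataset",
          function(x) dimnames(x@alleles)[[2]])

setMethod("show", "GenotypeDataset", function(object) {
  sp <- speciesLabels(object)
  cat("GenotypeDataset:", nInd(object), "individuals,",
      nLoci(object), "loci\n")
  cat("  populations:", nlevels(object@popLabels),
      " species:", nlevels(sp), "\n")
  nmiss <- sum(is.na(object@alleles[, , 1]))
  cat("  missing calls:", nmiss, "of", nInd(object) * nLoci(object), "\n")
  invisible(object)
})

#' Subset a GenotypeDataset by individuals
#'
#' @param x a [GenotypeDataset-class].
#' @param i integer or logical index over individuals.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GenotypeDataset", function(x, i, j, ..., drop = FALSE) {
  a <- x@alleles[i, , , drop = FALSE]
  pop <- droplevels(x@popLabels[i])
  coords <- x@coords[x@coords$pop %in% levels(pop), , drop = FALSE]
  new("GenotypeDataset", alleles = a, popLabels = pop,
      speciesMap = x@speciesMap[names(x@speciesMap) %in% levels(pop)],
      coords = coords)
})

#' Keep only the named populations
#'
#' @param x a [GenotypeDataset-class].
#' @param pops character vector of population labels to keep.
#' @export
subsetPopulations <- function(x, pops) {
  stopifnot(is(x, "GenotypeDataset"))
  x[as.character(x@popLabels) %in% pops]
}

## Internal: list of n x loci x 2 arrays, one per group (population or
## species), in level order.
.splitByGroup <- function(ds, level = c("population", "species")) {
  level <- match.arg(level)
  g <- if (level == "population") ds@popLabels else speciesLabels(ds)
  idx <- split(seq_len(nInd(ds)), g)
  lapply(idx, function(i) ds@alleles[i, , , drop = FALSE])
}
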