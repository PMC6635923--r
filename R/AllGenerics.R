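#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' `alleles()` returns the `n x loci x 2` allele-size array;
#' `popLabels()` / `speciesLabels()` the per-individual population and
#' species factors; `speciesMap()` the population -> species map;
#' `popCoords()` the per-population coordinate table; `nInd()`, `nLoci()`
#' and `lociNames()` the obvious dimensions.
#'
#' @param x a [GenotypeDataset-class] (or, where documented, a
#'   [HaplotypeTable-class]).
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))
#' @rdname accessors
#' @export
setGeneric("speciesMap", function(x) standardGeneric("speciesMap"))
#' @rdname accessors
#' @export
setGeneric("popCoords", function(x) standardGeneric("popCoords"))
#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname accessors
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))
#' @rdname accessors
#' @export
setGeneric("hapDiffs", function(x) standardGeneric("hapDiffs"))
#' @rdname accessors
#' @export
setGeneric("hapSequences", function(x) standardGeneric("hapSequences"))

#' Haplotype diversity (Nei's unbiased)
#'
#' @param x haplotype counts (numeric vector) or a
#'   [HaplotypeTable-class].
#' @param ... passed to methods.
#' @export
setGeneric("haplotypeDiversity",
           function(x, ...) standardGeneric("haplotypeDiversity"))

#' Hierarchical analysis of molecular variance
#'
#' @param x a [GenotypeDataset-class] or [HaplotypeTable-class].
#' @param ... passed to methods; see [amova,GenotypeDataset-method].
#' @export
setGeneric("amova", function(x, ...) standardGeneric("amova"))
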