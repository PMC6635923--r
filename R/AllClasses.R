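#' @import methods
NULL

#' GenotypeDataset: diploid microsatellite genotypes with population and
#' species structure
#'
#' Container for co-dominant allele-size calls at unlinked microsatellite
#' loci. Alleles are stored as an integer array `individuals x loci x 2`
#' (allele sizes, `NA` = missing; a call is either fully typed or fully
#' missing). Every individual belongs to exactly one population and every
#' population to exactly one species.
#'
#' @slot alleles integer array `[n_ind, n_loci, 2]` of allele sizes.
#' @slot popLabels factor of length `n_ind`; population of each individual.
#' @slot speciesMap named character; maps population label -> species label.
#' @slot coords data.frame with columns `pop`, `lat`, `lon` (decimal
#'   degrees), possibly 0 rows when coordinates are unknown.
#'
#' @seealso [GenotypeDataset()] for the user constructor.
#' @export
setClass("GenotypeDataset",
  representation(
    alleles    = "array",
    popLabels  = "factor",
    speciesMap = "character",
    coords     = "data.frame"
  )
)

setValidity("GenotypeDataset", function(object) {
  a <- object@alleles
  msg <- character()
  if (length(dim(a)) != 3L || dim(a)[3] != 2L)
    msg <- c(msg, "'alleles' must be an n x loci x 2 array")
  if (dim(a)[1] != length(object@popLabels))
    msg <- c(msg, "length(popLabels) must equal number of individuals")
  pops <- levels(object@popLabels)
  if (!all(pops %in% names(object@speciesMap)))
    msg <- c(msg, "every population must appear in speciesMap")
  ## both alleles of a call present or both missing
  m1 <- is.na(a[, , 1, drop = FALSE]); m2 <- is.na(a[, , 2, drop = FALSE])
  if (any(m1 != m2))
    msg <- c(msg, "half-missing genotype calls are not allowed")
  if (nrow(object@coords) > 0 &&
      !all(c("pop", "lat", "lon") %in% colnames(object@coords)))
    msg <- c(msg, "coords needs columns pop, lat, lon")
  if (length(msg)) msg else TRUE
})

#' HaplotypeTable: distinct cpDNA haplotypes with counts per population
#'
#' Holds the distinct (indel-recoded) haplotype sequences, the symmetric
#' matrix of pairwise character differences between haplotypes, and the
#' number of sampled individuals carrying each haplotype in each
#' population. Sequences and differences may be absent (length 0 / 0 x 0)
#' when only counts are known, e.g. when a table is rebuilt from a
#' published survey; distance-based statistics then require `diffs`.
#'
#' @slot haplotypes named character; haplotype id -> recoded sequence.
#' @slot diffs numeric matrix of pairwise differing columns (indel run
#'   counted once); zero diagonal, symmetric.
#' @slot counts integer matrix population x haplotype.
#' @slot speciesMap named character; population -> species.
#' @slot seqLength integer; number of alignment columns after indel
#'   recoding (used to express nucleotide diversity per site).
#' @export
setClass("HaplotypeTable",
  representation(
    haplotypes = "character",
    diffs      = "matrix",
    counts     = "matrix",
    speciesMap = "character",
    seqLength  = "integer"
  )
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  cn <- colnames(object@counts)
  if (is.null(cn) || is.null(rownames(object@counts)))
    msg <- c(msg, "counts must have population rownames and haplotype colnames")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@diffs)) {
    d <- object@diffs
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
      msg <- c(msg, "diffs must be symmetric")
    else if (any(diag(d) != 0))
      msg <- c(msg, "diffs must have zero diagonal")
    if (!all(cn %in% rownames(d)))
      msg <- c(msg, "all haplotypes in counts must appear in diffs")
  }
  if (length(object@haplotypes) &&
      !all(cn %in% names(object@haplotypes)))
    msg <- c(msg, "all haplotypes in counts must appear in haplotypes")
  if (!all(rownames(object@counts) %in% names(object@speciesMap)))
    msg <- c(msg, "every population must appear in speciesMap")
  if (length(msg)) msg else TRUE
})

#' NicheDataset: occurrences and background points in climate space
#'
#' @slot occurrences data.frame with columns `species`, `lat`, `lon` and
#'   one column per climate variable.
#' @slot background data.frame with column `species` and the same climate
#'   variables; background points describe the environment available to
#'   each species.
#' @slot varNames character; names of the climate variable columns.
#' @export
setClass("NicheDataset",
  representation(
    occurrences = "data.frame",
    background  = "data.frame",
    varNames    = "character"
  )
)

setValidity("NicheDataset", function(object) {
  msg <- character()
  need <- c("species", "lat", "lon", object@varNames)
  if (!all(need %in% colnames(object@occurrences)))
    msg <- c(msg, "occurrences must have species, lat, lon and all climate variables")
  if (!all(c("species", object@varNames) %in% colnames(object@background)))
    msg <- c(msg, "background must have species and all climate variables")
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: a three-population divergence scenario
#'
#' Describes one demographic scenario for the species trio: which lineage
#' merges into which at the recent split (t1) and at the older split (t2),
#' and which lineage carries each ancestral size between events. Lineages
#' are indexed 1 = P. jishanensis (J), 2 = P. qiui (Q), 3 = P. rockii (R).
#'
#' The catalogue of step-1 topologies is reconstructed from the study
#' design (all six ordered derived/ancestor choices for the first split);
#' see `scenarioCatalogue()`.
#'
#' @slot id integer scenario id.
#' @slot step integer, 1 or 2 (model-selection round).
#' @slot merge1 integer length 2, c(src, dst) at t1 (src merges into dst).
#' @slot merge2 integer length 2, c(src, dst) at t2.
#' @slot a1Carrier integer; lineage whose size is A1 already between t1
#'   and t2 (0 = none; only step-2 scenario 2 uses this).
#' @slot description character.
#' @export
setClass("ScenarioSpec",
  representation(
    id          = "integer",
    step        = "integer",
    merge1      = "integer",
    merge2      = "integer",
    a1Carrier   = "integer",
    description = "character"
  )
)

#' ScenarioParams: one concrete parameter draw for a scenario
#'
#' Current effective (diploid) sizes NJ, NQ, NR; ancestral sizes A1 (older
#' than t2) and A2 (ancestral lineage between t1 and t2); event times t1 <
#' t2 in generations; mean per-locus per-generation mutation rate mu.
#' Generation time is 10 years throughout the package.
#'
#' @export
setClass("ScenarioParams",
  representation(
    NJ = "numeric", NQ = "numeric", NR = "numeric",
    A1 = "numeric", A2 = "numeric",
    t1 = "numeric", t2 = "numeric",
    mu = "numeric"
  )
)

setValidity("ScenarioParams", function(object) {
  v <- c(object@NJ, object@NQ, object@NR, object@A1, object@A2,
         object@t1, object@t2, object@mu)
  if (length(v) != 8L || any(!is.finite(v)))
    return("all eight parameters must be single finite numbers")
  if (any(v <= 0)) return("all parameters must be positive")
  if (object@t1 >= object@t2) return("t1 must be smaller than t2")
  TRUE
})

#' PriorConfig: per-parameter uniform prior bounds
#'
#' @slot bounds numeric matrix 8 x 2 (columns `lower`, `upper`), rows
#'   NJ, NQ, NR, A1, A2, t1, t2, mu.
#' @export
setClass("PriorConfig", representation(bounds = "matrix"))

setValidity("PriorConfig", function(object) {
  b <- object@bounds
  if (!identical(rownames(b),
                 c("NJ", "NQ", "NR", "A1", "A2", "t1", "t2", "mu")))
    return("bounds rows must be NJ, NQ, NR, A1, A2, t1, t2, mu")
  if (ncol(b) != 2L || any(!is.finite(b)) || any(b[, 1] >= b[, 2]))
    return("bounds must be finite with lower < upper")
  TRUE
})

#' ReferenceTable: simulated parameter draws and summary statistics
#'
#' The substrate of all ABC operations: one row per simulated dataset,
#' pairing the generating scenario id and parameter draw with the
#' summary-statistic vector of the simulated data.
#'
#' @slot scenario integer vector of scenario ids, one per row.
#' @slot params numeric matrix n x 8 (NJ..mu).
#' @slot stats numeric matrix n x 12 of summary statistics.
#' @slot step integer; scenario-selection round the table belongs to.
#' @slot seed integer; master seed used to build the table.
#' @slot priorBounds matrix; copy of the prior bounds (provenance).
#' @export
setClass("ReferenceTable",
  representation(
    scenario    = "integer",
    params      = "matrix",
    stats       = "matrix",
    step        = "integer",
    seed        = "integer",
    priorBounds = "matrix"
  )
)

setValidity("ReferenceTable", function(object) {
  n <- length(object@scenario)
  if (nrow(object@params) != n || nrow(object@stats) != n)
    return("scenario, params and stats must have matching row counts")
  if (ncol(object@params) != 8L) return("params must have 8 columns")
  TRUE
})

#' TruthRecord: ground truth of a synthetic dataset
#'
#' @slot scenarioId integer.
#' @slot step integer.
#' @slot params ScenarioParams used to generate the data.
#' @slot seed integer.
#' @slot sampleSizes named integer; population label -> diploid count.
#' @export
setClass("TruthRecord",
  representation(
    scenarioId  = "integer",
    step        = "integer",
    params      = "ScenarioParams",
    seed        = "integer",
    sampleSizes = "integer"
  )
)

setValidity("TruthRecord", function(object) {
  if (any(object@sampleSizes < 2L))
    return("sample sizes must be at least 2 diploids per population")
  TRUE
})

#' DistancePair: a symmetric population-by-population distance matrix
#'
#' @slot matrix symmetric numeric matrix with zero diagonal (entries may
#'   be NA where undefined).
#' @slot kind one of "fst", "linearized_fst", "geographic_km",
#'   "shared_allele".
#' @export
setClass("DistancePair",
  representation(matrix = "matrix", kind = "character"))

setValidity("DistancePair", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (!object@kind %in% c("fst", "linearized_fst", "geographic_km",
                          "shared_allele"))
    return("unknown kind")
  if (any(abs(diag(m)) > 1e-12, na.rm = TRUE))
    return("matrix must have zero diagonal")
  if (object@kind == "geographic_km" && any(m < 0, na.rm = TRUE))
    return("geographic distances must be non-negative")
  TRUE
})
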