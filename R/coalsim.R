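## Divergence scenarios for the species trio and the coalescent
## microsatellite simulator built on them.

.LINEAGES <- c(J = 1L, Q = 2L, R = 3L)

#' Scenario catalogue
#'
#' Step 1 compares six topologies: every ordered (derived <- ancestor)
#' choice for the first split at t1, with the remaining taxon joining
#' the ancestral lineage at t2 (this catalogue is a reconstruction of
#' the study design, documented as such). Step 2 refines the winning
#' "Q from J" topology with two variants that differ in which taxon is
#' the deep ancestor: in scenario 1 J is ancestral (R keeps its size NR
#' back to t2), in scenario 2 R is ancestral (its lineage already has
#' the ancestral size A1 between t1 and t2). The two are
#' distinguishable exactly when A1 differs from NR.
#'
#' @param step 1 or 2.
#' @return data.frame describing the scenarios.
#' @export
scenarioCatalogue <- function(step = 2) {
  if (step == 1) {
    data.frame(
      id = 1:6,
      derived1  = c("Q", "J", "R", "J", "R", "Q"),
      ancestor1 = c("J", "Q", "J", "R", "Q", "R"),
      stringsAsFactors = FALSE)
  } else if (step == 2) {
    data.frame(
      id = 1:2,
      derived1 = c("Q", "Q"), ancestor1 = c("J", "J"),
      deepAncestor = c("J", "R"),
      stringsAsFactors = FALSE)
  } else stop("step must be 1 or 2")
}

#' Construct a ScenarioSpec
#'
#' @param id scenario id (1..6 in step 1, 1..2 in step 2).
#' @param step model-selection round, 1 or 2.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(id, step = 2) {
  cat <- scenarioCatalogue(step)
  if (!id %in% cat$id)
    stop("invalid scenario id ", id, " for step ", step,
         "; valid ids: ", paste(cat$id, collapse = ", "))
  row <- cat[cat$id == id, ]
  src1 <- .LINEAGES[[row$derived1]]
  dst1 <- .LINEAGES[[row$ancestor1]]
  third <- setdiff(1:3, c(src1, dst1))
  if (step == 1 || row$deepAncestor == row$ancestor1) {
    merge2 <- c(third, dst1)
    a1c <- 0L
    desc <- sprintf("%s from %s at t1; %s joins at t2",
                    row$derived1, row$ancestor1,
                    names(.LINEAGES)[third])
  } else {
    merge2 <- c(dst1, third)
    a1c <- as.integer(third)
    desc <- sprintf(
      "%s from %s at t1; %s is the deep ancestor (carries A1 from t1)",
      row$derived1, row$ancestor1, names(.LINEAGES)[third])
  }
  new("ScenarioSpec", id = as.integer(id), step = as.integer(step),
      merge1 = c(as.integer(src1), as.integer(dst1)),
      merge2 = as.integer(merge2), a1Carrier = a1c,
      description = desc)
}

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec ", object@id, " (step ", object@step, "): ",
      object@description, "\n", sep = "")
  invisible(object)
})

#' Construct a ScenarioParams object
#'
#' @param NJ,NQ,NR current effective diploid sizes.
#' @param A1 ancestral size older than t2 (and, in step-2 scenario 2,
#'   already on the deep-ancestor lineage between t1 and t2).
#' @param A2 size of the merged ancestral lineage between t1 and t2.
#' @param t1,t2 event times in generations, t1 < t2.
#' @param mu mean per-locus per-generation mutation rate.
#' @export
scenarioParams <- function(NJ, NQ, NR, A1, A2, t1, t2, mu) {
  new("ScenarioParams", NJ = NJ, NQ = NQ, NR = NR, A1 = A1, A2 = A2,
      t1 = t1, t2 = t2, mu = mu)
}

setMethod("show", "ScenarioParams", function(object) {
  cat(sprintf(
    "ScenarioParams: NJ=%g NQ=%g NR=%g A1=%g A2=%g t1=%g t2=%g mu=%g\n",
    object@NJ, object@NQ, object@NR, object@A1, object@A2,
    object@t1, object@t2, object@mu))
  invisible(object)
})

.paramsToVector <- function(p) {
  c(NJ = p@NJ, NQ = p@NQ, NR = p@NR, A1 = p@A1, A2 = p@A2,
    t1 = p@t1, t2 = p@t2, mu = p@mu)
}

.vectorToParams <- function(v) {
  scenarioParams(v[["NJ"]], v[["NQ"]], v[["NR"]], v[["A1"]], v[["A2"]],
                 v[["t1"]], v[["t2"]], v[["mu"]])
}

#' Default uniform priors
#'
#' Sizes and times uniform on (10, 1e5) (t1 < t2 enforced by
#' rejection), mutation rate uniform on (1e-4, 1e-3).
#'
#' @return a [PriorConfig-class].
#' @export
defaultPriors <- function() {
  b <- rbind(NJ = c(10, 1e5), NQ = c(10, 1e5), NR = c(10, 1e5),
             A1 = c(10, 1e5), A2 = c(10, 1e5),
             t1 = c(10, 1e5), t2 = c(10, 1e5),
             mu = c(1e-4, 1e-3))
  colnames(b) <- c("lower", "upper")
  new("PriorConfig", bounds = b)
}

#' Draw parameter sets from the prior
#'
#' Independent uniform draws honouring t1 < t2 by rejection; the
#' realized acceptance rate is recorded as an attribute.
#'
#' @param prior a [PriorConfig-class].
#' @param n number of accepted draws.
#' @param seed RNG seed.
#' @return data.frame n x 8 with attributes `seed`, `acceptanceRate`.
#' @export
drawParams <- function(prior, n, seed = NULL) {
  stopifnot(is(prior, "PriorConfig"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- prior@bounds
  acc <- matrix(NA_real_, 0, 8)
  tried <- 0L
  while (nrow(acc) < n) {
    m <- max(n - nrow(acc), 16L)
    m <- ceiling(m * 2.2)
    draw <- sapply(seq_len(8), function(k)
      runif(m, b[k, 1], b[k, 2]))
    tried <- tried + m
    keep <- draw[, 6] < draw[, 7]
    acc <- rbind(acc, draw[keep, , drop = FALSE])
    if (tried > 1000 && nrow(acc) / tried < 1e-3)
      stop("prior acceptance rate below 1e-3; revise the t1/t2 prior")
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  colnames(acc) <- rownames(b)
  out <- as.data.frame(acc)
  attr(out, "seed") <- seed
  attr(out, "acceptanceRate") <- n / tried
  out
}

#' Simulate a microsatellite dataset under a divergence scenario
#'
#' Per locus an independent coalescent genealogy is drawn on the
#' three-population history (backwards merges at t1 and t2, epoch sizes
#' per the scenario), mutations fall on branches as a Poisson process at
#' rate `mu` and move the allele by +/-1 repeat (strict stepwise model;
#' `model = "gsm"` draws geometric step sizes with parameter
#' `gsmP = 0.22`), reflected at +/-40 repeats around the ancestral
#' state. Sampled gene copies are paired at random within populations
#' into diploids (copies are exchangeable, so consecutive pairing is
#' used).
#'
#' @param spec a [ScenarioSpec-class].
#' @param params a [ScenarioParams-class].
#' @param sampleConfig named integer: diploid sample size per
#'   population label.
#' @param nLoci number of loci.
#' @param seed integer seed (required for reproducibility).
#' @param speciesOf named character mapping population labels to
#'   lineages `"J"`, `"Q"`, `"R"`; defaults to the labels themselves
#'   when they already are lineage names.
#' @param model `"smm"` or `"gsm"`.
#' @param gsmP geometric parameter of the generalized stepwise model.
#' @return a [GenotypeDataset-class] (species labels `J`, `Q`, `R`).
#' @export
simulateScenario <- function(spec, params, sampleConfig, nLoci,
                             seed, speciesOf = NULL,
                             model = c("smm", "gsm"), gsmP = 0.22) {
  stopifnot(is(spec, "ScenarioSpec"), is(params, "ScenarioParams"))
  model <- match.arg(model)
  validObject(params)
  if (is.null(names(sampleConfig)))
    stop("sampleConfig must be a named vector of diploid counts")
  if (is.null(speciesOf)) {
    if (!all(names(sampleConfig) %in% names(.LINEAGES)))
      stop("population labels are not J/Q/R; supply speciesOf")
    speciesOf <- setNames(names(sampleConfig), names(sampleConfig))
  }
  if (!all(speciesOf %in% names(.LINEAGES)))
    stop("speciesOf values must be J, Q or R")
  ## epoch size matrix (3 pops x 3 epochs)
  sizes <- matrix(0, 3, 3)
  sizes[, 1] <- c(params@NJ, params@NQ, params@NR)
  sizes[, 2] <- sizes[, 1]
  sizes[spec@merge1[2], 2] <- params@A2
  sizes[spec@merge1[1], 2] <- 0
  if (spec@a1Carrier > 0) sizes[spec@a1Carrier, 2] <- params@A1
  survivor <- spec@merge2[2]
  after1 <- setdiff(1:3, spec@merge1[1])
  if (!setequal(c(spec@merge2), after1))
    stop("impossible merge schedule: t2 merge ", spec@merge2[1], "->",
         spec@merge2[2], " involves the lineage removed at t1")
  sizes[, 3] <- 0
  sizes[survivor, 3] <- params@A1
  ## copies per lineage
  lin <- .LINEAGES[speciesOf[names(sampleConfig)]]
  nCopies <- integer(3)
  for (k in seq_along(sampleConfig))
    nCopies[lin[k]] <- nCopies[lin[k]] + 2L * sampleConfig[[k]]
  mat <- .sim_msat_cpp(params@t1, params@t2, sizes, spec@merge1,
                       spec@merge2, nCopies, params@mu, nLoci,
                       as.double(seed), 40L,
                       if (model == "gsm") gsmP else 0)
  ## copies are emitted lineage-by-lineage; hand them out to the
  ## populations of each lineage in sampleConfig order
  offs <- c(0L, cumsum(nCopies))
  used <- integer(3)
  popOf <- character(); rows <- integer()
  for (k in seq_along(sampleConfig)) {
    l <- lin[k]
    take <- offs[l] + used[l] + seq_len(2L * sampleConfig[[k]])
    used[l] <- used[l] + 2L * sampleConfig[[k]]
    rows <- c(rows, take)
    popOf <- c(popOf, rep(names(sampleConfig)[k], sampleConfig[[k]]))
  }
  mat <- mat[rows, , drop = FALSE]
  n <- length(popOf)
  a <- array(NA_integer_, dim = c(n, nLoci, 2))
  a[, , 1] <- 100L + mat[2 * seq_len(n) - 1L, , drop = FALSE]
  a[, , 2] <- 100L + mat[2 * seq_len(n), , drop = FALSE]
  GenotypeDataset(a, pop = popOf,
                  speciesMap = setNames(unname(speciesOf), names(speciesOf)))
}

#' Stepwise-mutation equilibrium heterozygosity
#'
#' Expected heterozygosity of a constant-size population at
#' mutation-drift equilibrium under the strict stepwise model:
#' `1 - 1/sqrt(1 + 8 N mu)`.
#'
#' @param N diploid effective size.
#' @param mu per-locus mutation rate.
#' @export
smmEquilibriumHe <- function(N, mu) 1 - 1 / sqrt(1 + 8 * N * mu)
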