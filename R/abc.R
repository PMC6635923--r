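## DIYABC-style inference on microsatellite summary statistics:
## reference-table construction, rejection + polychotomous logistic
## scenario choice, local-linear parameter estimation, scenario-choice
## error rates, and posterior model checking.

.STAT_NAMES <- c("NA_J", "NA_Q", "NA_R", "He_J", "He_Q", "He_R",
                 "FST_JQ", "FST_JR", "FST_QR",
                 "dmu2_JQ", "dmu2_JR", "dmu2_QR")

## Fast 12-statistic computation for a 3-group dataset. a1, a2: n x L
## allele matrices; spIdx: integer 1..3 per individual (1=J, 2=Q, 3=R).
.summaryStats3 <- function(a1, a2, spIdx) {
  L <- ncol(a1)
  nAll <- He <- matrix(0, 3, L)
  msz <- matrix(NA_real_, 3, L)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  A <- B <- C <- numeric(3)
  dmu <- matrix(NA_real_, 3, L)
  for (l in seq_len(L)) {
    ok <- !is.na(a1[, l])
    x1 <- a1[ok, l]; x2 <- a2[ok, l]; sp <- spIdx[ok]
    als <- sort(unique(c(x1, x2)))
    K <- length(als)
    c1 <- match(x1, als); c2 <- match(x2, als)
    cnt <- matrix(tabulate(c(c1, c2) + (rep(sp, 2) - 1L) * K,
                           nbins = 3L * K), K, 3)
    het <- c1 != c2
    hcnt <- matrix(tabulate(c(c1[het], c2[het]) +
                              (rep(sp[het], 2) - 1L) * K,
                            nbins = 3L * K), K, 3)
    nS <- tabulate(sp, 3)
    for (s in 1:3) {
      if (nS[s] == 0) next
      nAll[s, l] <- sum(cnt[, s] > 0)
      He[s, l] <- .neiUnbiased(cnt[, s])
      msz[s, l] <- sum(als * cnt[, s]) / (2 * nS[s])
    }
    for (pr in 1:3) {
      s <- pairs[pr, 1]; t <- pairs[pr, 2]
      ni <- nS[c(s, t)]
      if (any(ni < 2)) next
      dmu[pr, l] <- (msz[s, l] - msz[t, l])^2
      p <- cbind(cnt[, s] / (2 * ni[1]), cnt[, t] / (2 * ni[2]))
      h <- cbind(hcnt[, s] / ni[1], hcnt[, t] / ni[2])
      nbar <- mean(ni)
      nc <- 2 * nbar - sum(ni^2) / (2 * nbar)
      pbar <- (ni[1] * p[, 1] + ni[2] * p[, 2]) / (2 * nbar)
      s2 <- (ni[1] * (p[, 1] - pbar)^2 +
               ni[2] * (p[, 2] - pbar)^2) / nbar
      hbar <- (ni[1] * h[, 1] + ni[2] * h[, 2]) / (2 * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 / 2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A[pr] <- A[pr] + sum(a)
      B[pr] <- B[pr] + sum(b)
      C[pr] <- C[pr] + sum(cc)
    }
  }
  fst <- ifelse(A + B + C != 0, A / (A + B + C), NA_real_)
  out <- c(rowMeans(nAll), rowMeans(He), fst, rowMeans(dmu, na.rm = TRUE))
  names(out) <- .STAT_NAMES
  out
}

#' Summary statistics of a three-species microsatellite dataset
#'
#' Per species: mean number of alleles per locus and mean expected
#' heterozygosity (Nei unbiased); per species pair: multi-locus
#' Weir--Cockerham FST and Goldstein's `(delta mu)^2` distance (squared
#' difference of mean allele size, averaged over loci). The ordering of
#' the 12 entries is fixed (J, Q, R; then pairs JQ, JR, QR).
#'
#' @param ds a [GenotypeDataset-class] with exactly 3 species, each with
#'   >= 2 individuals.
#' @return named numeric vector of length 12.
#' @export
summarizeDataset <- function(ds) {
  sp <- speciesLabels(ds)
  if (nlevels(sp) != 3)
    stop("summary statistics are defined for exactly 3 species groups")
  if (any(table(sp) < 2))
    stop("every species group needs at least 2 individuals")
  n <- dim(ds@alleles)[1]
  .summaryStats3(matrix(ds@alleles[, , 1], nrow = n),
                 matrix(ds@alleles[, , 2], nrow = n),
                 as.integer(sp))
}

#' Build an ABC reference table
#'
#' Draws parameters from the prior for each scenario, simulates a
#' dataset per draw and records its summary statistics. Rows whose
#' statistics contain non-finite values are dropped (with a message).
#'
#' @param scenarios list of [ScenarioSpec-class] (or integer ids).
#' @param prior a [PriorConfig-class].
#' @param nPerScenario simulations per scenario.
#' @param sampleConfig named diploid sample sizes (see
#'   [simulateScenario()]).
#' @param nLoci number of loci.
#' @param seed master seed; per-row child seeds derive from it.
#' @param step scenario-selection round (used when `scenarios` are ids).
#' @param speciesOf optional population -> lineage map.
#' @return a [ReferenceTable-class].
#' @export
buildReference <- function(scenarios, prior, nPerScenario, sampleConfig,
                           nLoci, seed, step = 2, speciesOf = NULL) {
  if (is.numeric(scenarios))
    scenarios <- lapply(scenarios, scenarioSpec, step = step)
  set.seed(seed)
  allPar <- list(); allStat <- list(); allScen <- list()
  for (sc in scenarios) {
    par <- drawParams(prior, nPerScenario)
    seeds <- .childSeeds(nPerScenario)
    st <- matrix(NA_real_, nPerScenario, 12)
    for (i in seq_len(nPerScenario)) {
      ds <- simulateScenario(sc, .vectorToParams(unlist(par[i, ])),
                             sampleConfig, nLoci, seeds[i],
                             speciesOf = speciesOf)
      st[i, ] <- summarizeDataset(ds)
    }
    allPar[[length(allPar) + 1L]] <- as.matrix(par)
    allStat[[length(allStat) + 1L]] <- st
    allScen[[length(allScen) + 1L]] <- rep(sc@id, nPerScenario)
  }
  par <- do.call(rbind, allPar)
  st <- do.call(rbind, allStat)
  colnames(st) <- .STAT_NAMES
  scen <- unlist(allScen)
  bad <- !is.finite(rowSums(st))
  if (any(bad)) {
    message(sum(bad), " reference rows with non-finite statistics dropped")
    par <- par[!bad, , drop = FALSE]
    st <- st[!bad, , drop = FALSE]
    scen <- scen[!bad]
  }
  new("ReferenceTable", scenario = as.integer(scen), params = par,
      stats = st, step = as.integer(if (length(scenarios))
        scenarios[[1]]@step else step),
      seed = as.integer(seed), priorBounds = prior@bounds)
}

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", length(object@scenario), "rows,",
      length(unique(object@scenario)), "scenarios (step",
      object@step, ")\n")
  print(table(scenario = object@scenario))
  invisible(object)
})

## Variance-stabilizing transforms applied to the summary statistics
## before standardization: log for counts and distances, logit for the
## bounded diversity/differentiation statistics. This linearizes the
## statistic-parameter relationships (e.g. He saturates in N*mu), so
## both the nearest-neighbour metric and the local-linear regression
## behave over the wide uniform priors.
.transformStats <- function(S) {
  S <- rbind(S)
  out <- S
  out[, 1:3] <- log(pmax(S[, 1:3], 1))
  he <- pmin(pmax(S[, 4:6], 1e-4), 1 - 1e-4)
  out[, 4:6] <- log(he / (1 - he))
  fs <- pmin(pmax(S[, 7:9], 1e-4), 1 - 1e-4)
  out[, 7:9] <- log(fs / (1 - fs))
  out[, 10:12] <- log(pmax(S[, 10:12], 0) + 1e-2)
  out
}

## standardize (transformed) table stats and compute distances to obs
.abcDistances <- function(obs, stats) {
  ts <- .transformStats(stats)
  to <- as.numeric(.transformStats(matrix(obs, nrow = 1)))
  sds <- apply(ts, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  z <- sweep(ts, 2, sds, "/")
  zo <- to / sds
  d <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  list(d = d, z = z, zo = zo, sds = sds)
}

#' Scenario choice by rejection + polychotomous logistic regression
#'
#' Statistics are standardized by their reference-table standard
#' deviations, the `tolerance` fraction of rows closest to the observed
#' vector (Euclidean distance) is retained, and a multinomial logistic
#' regression of the scenario indicator on the statistics is evaluated
#' at the observed vector. 95% CIs come from the regression's
#' asymptotic covariance (delta method). If the retained set misses a
#' scenario entirely the method falls back to direct rejection
#' (retained-set proportions) with a warning.
#'
#' @param obs observed summary vector (as from [summarizeDataset()]).
#' @param table a [ReferenceTable-class] with >= 2 scenarios.
#' @param tolerance fraction of rows to retain (default 0.01).
#' @param ci compute confidence intervals (default TRUE).
#' @return data.frame with scenario, posterior probability, and CI
#'   bounds; attribute `method` is `"mnlogistic"` or `"rejection"`.
#' @export
chooseScenario <- function(obs, table, tolerance = 0.01, ci = TRUE) {
  stopifnot(is(table, "ReferenceTable"))
  ids <- sort(unique(table@scenario))
  if (length(ids) < 2) stop("scenario choice needs >= 2 scenarios")
  ab <- .abcDistances(obs, table@stats)
  ## floor on the retained count: the regression needs enough rows per
  ## scenario to be estimable with 12 covariates
  nKeep <- min(length(ab$d),
               max(length(ids) + 1L, 100L,
                   ceiling(tolerance * length(ab$d))))
  keep <- order(ab$d)[seq_len(nKeep)]
  scen <- factor(table@scenario[keep], levels = ids)
  fallback <- function(msg) {
    warning(msg)
    pp <- as.numeric(prop.table(base::table(scen)))
    data.frame(scenario = ids, posterior = pp,
               lower = NA_real_, upper = NA_real_)
  }
  if (any(tabulate(scen, length(ids)) == 0))
    return(structure(fallback(
      "retained set lacks some scenario; direct rejection used"),
      method = "rejection"))
  Z <- ab$z[keep, , drop = FALSE]
  ## drop statistics that are constant in the retained set
  keepCol <- apply(Z, 2, function(v) sd(v) > 1e-10)
  Z <- Z[, keepCol, drop = FALSE]
  df <- data.frame(scen = scen, Z)
  fit <- tryCatch(
    nnet::multinom(scen ~ ., data = df, trace = FALSE, maxit = 500,
                   decay = 0.05),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(fallback("logistic regression failed; direct rejection used"),
                     method = "rejection"))
  newd <- as.data.frame(as.list(setNames(ab$zo[keepCol], colnames(Z))))
  pp <- predict(fit, newdata = newd, type = "probs")
  if (length(ids) == 2) pp <- c(1 - pp, pp)
  pp <- as.numeric(pp)
  lo <- hi <- rep(NA_real_, length(ids))
  if (ci) {
    V <- tryCatch(vcov(fit), error = function(e) NULL)
    if (!is.null(V)) {
      x <- c(1, unname(ab$zo[keepCol]))
      K <- length(ids); P <- length(x)
      grad <- matrix(0, K, (K - 1) * P)
      for (k in seq_len(K)) for (j in 2:K) {
        gk <- pp[k] * ((k == j) - pp[j])
        grad[k, ((j - 2) * P + 1):((j - 1) * P)] <- gk * x
      }
      se <- sqrt(pmax(0, diag(grad %*% V %*% t(grad))))
      lo <- pmax(0, pp - 1.96 * se)
      hi <- pmin(1, pp + 1.96 * se)
    }
  }
  structure(data.frame(scenario = ids, posterior = pp,
                       lower = lo, upper = hi),
            method = "mnlogistic")
}

## logit transform to prior bounds and back
.toLogit <- function(x, lo, hi) {
  z <- (x - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
  log(z / (1 - z))
}
.fromLogit <- function(u, lo, hi) lo + (hi - lo) / (1 + exp(-u))

#' Local-linear (regression-adjusted) parameter estimation
#'
#' Beaumont-style ABC posterior for the parameters of one scenario:
#' the `tolerance` fraction of that scenario's reference rows closest
#' to the observed statistics is retained with Epanechnikov weights,
#' parameters are logit-transformed to their prior bounds, adjusted by
#' a weighted local-linear regression on the statistics, and
#' back-transformed. Reported quantiles are the weighted 2.5%, 50% and
#' 97.5%.
#'
#' @param obs observed summary vector.
#' @param table a [ReferenceTable-class].
#' @param scenario scenario id whose rows to use.
#' @param tolerance fraction retained (default 0.01). At `tolerance =
#'   1` every row is retained with uniform weight, so the unadjusted
#'   sample reduces to the prior.
#' @param adjust apply the local-linear regression adjustment (default
#'   TRUE).
#' @return object of class `peony_abcpost`: `summary` (data.frame
#'   median / q025 / q975 per parameter, with event times also in
#'   years at 10 years/generation), `sample` (adjusted draws),
#'   `weights`, `method`.
#' @export
estimateParams <- function(obs, table, scenario, tolerance = 0.01,
                           adjust = TRUE) {
  stopifnot(is(table, "ReferenceTable"))
  rows <- table@scenario == scenario
  if (!any(rows)) stop("no rows for scenario ", scenario)
  if (sum(rows) < 1000)
    warning("fewer than 1000 reference rows for scenario ", scenario,
            "; posterior may be unstable")
  stats <- table@stats[rows, , drop = FALSE]
  par <- table@params[rows, , drop = FALSE]
  ab <- .abcDistances(obs, stats)
  nKeep <- min(sum(rows), max(100L, ceiling(tolerance * sum(rows))))
  keep <- order(ab$d)[seq_len(nKeep)]
  d <- ab$d[keep]
  delta <- max(d)
  w <- if (delta > 0 && tolerance < 1) 1 - (d / delta)^2
       else rep(1, length(d))
  if (any(w > 0)) w[w <= 0] <- min(w[w > 0]) else w[] <- 1
  Z <- ab$z[keep, , drop = FALSE]
  keepCol <- apply(Z, 2, function(v) sd(v) > 1e-10)
  X <- sweep(Z[, keepCol, drop = FALSE], 2, ab$zo[keepCol], "-")
  b <- table@priorBounds
  adj <- matrix(NA_real_, length(keep), ncol(par),
                dimnames = list(NULL, colnames(par)))
  method <- if (adjust) "loclinear" else "rejection"
  ## mildly ridge-stabilized weighted design shared by all parameters
  Xw <- cbind(1, X) * sqrt(w)
  XtX <- crossprod(Xw)
  XtX <- XtX + (1e-3 * sum(diag(XtX)) / ncol(XtX)) * diag(ncol(XtX))
  for (j in seq_len(ncol(par))) {
    phi <- .toLogit(par[keep, j], b[j, 1], b[j, 2])
    if (!adjust) {
      adj[, j] <- .fromLogit(phi, b[j, 1], b[j, 2])
      next
    }
    beta <- tryCatch(solve(XtX, crossprod(Xw, phi * sqrt(w))),
                     error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) {
      adj[, j] <- .fromLogit(phi, b[j, 1], b[j, 2])
      method <- "rejection"
      next
    }
    phiStar <- phi - as.numeric(X %*% beta[-1])
    ## keep adjusted draws off the exact prior bounds: an adjustment
    ## beyond +-20 logit units is pure extrapolation
    phiStar <- pmin(pmax(phiStar, -20), 20)
    adj[, j] <- .fromLogit(phiStar, b[j, 1], b[j, 2])
  }
  if (adjust && method == "rejection")
    warning("singular local-linear design; unadjusted rejection sample used")
  qs <- t(apply(adj, 2, .weightedQuantile, w = w,
                probs = c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "q025", "q975")
  summary <- data.frame(parameter = rownames(qs), qs,
                        row.names = NULL)
  for (tp in c("t1", "t2")) {
    r <- summary[summary$parameter == tp, -1] * 10
    summary <- rbind(summary,
                     data.frame(parameter = paste0(tp, "_years"), r))
  }
  structure(list(summary = summary, sample = adj, weights = w,
                 scenario = scenario, method = method),
            class = "peony_abcpost")
}

#' @export
print.peony_abcpost <- function(x, ...) {
  cat("ABC posterior for scenario", x$scenario, "(", x$method, ",",
      nrow(x$sample), "retained draws )\n")
  s <- x$summary
  s[, -1] <- signif(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Type I and type II error of scenario choice
#'
#' Simulates pseudo-observed datasets (pods) under every scenario with
#' prior-drawn parameters and classifies each against the reference
#' table. Type I error: fraction of pods generated under
#' `chosenScenario` that do not get the highest posterior probability
#' for it. Type II error: fraction of pods generated under the other
#' scenarios that do.
#'
#' @param table a [ReferenceTable-class].
#' @param chosenScenario scenario id under evaluation.
#' @param prior a [PriorConfig-class].
#' @param sampleConfig,nLoci,speciesOf as in [simulateScenario()].
#' @param nPods pods per scenario (>= 20).
#' @param tolerance rejection tolerance for classification.
#' @param seed RNG seed.
#' @return list with `typeI`, `typeII`, `nPods`, and the per-pod
#'   assignment table.
#' @export
confidenceErrors <- function(table, chosenScenario, prior, sampleConfig,
                             nLoci, nPods = 100, tolerance = 0.01,
                             seed = NULL, speciesOf = NULL) {
  stopifnot(is(table, "ReferenceTable"), nPods >= 20)
  ids <- sort(unique(table@scenario))
  if (!chosenScenario %in% ids) stop("chosen scenario not in table")
  if (!is.null(seed)) set.seed(seed)
  assign <- list()
  for (id in ids) {
    sc <- scenarioSpec(id, table@step)
    par <- drawParams(prior, nPods)
    seeds <- .childSeeds(nPods)
    top <- integer(nPods)
    for (i in seq_len(nPods)) {
      ds <- simulateScenario(sc, .vectorToParams(unlist(par[i, ])),
                             sampleConfig, nLoci, seeds[i],
                             speciesOf = speciesOf)
      pp <- suppressWarnings(
        chooseScenario(summarizeDataset(ds), table, tolerance,
                       ci = FALSE))
      top[i] <- pp$scenario[which.max(pp$posterior)]
    }
    assign[[as.character(id)]] <- top
  }
  typeI <- mean(assign[[as.character(chosenScenario)]] != chosenScenario)
  others <- unlist(assign[setdiff(as.character(ids),
                                  as.character(chosenScenario))])
  typeII <- mean(others == chosenScenario)
  list(typeI = typeI, typeII = typeII, nPods = nPods,
       assignments = assign)
}

#' Posterior model checking
#'
#' Simulates replicate datasets at parameter values drawn from the ABC
#' posterior sample and locates each observed statistic in its
#' posterior-predictive distribution. Two-sided tail probabilities are
#' `min(p, 1-p) * 2` with `p` the fraction of replicates at or below
#' the observed value.
#'
#' @param obs observed summary vector.
#' @param posterior a `peony_abcpost` from [estimateParams()].
#' @param spec the [ScenarioSpec-class] of the checked scenario.
#' @param sampleConfig,nLoci,speciesOf as in [simulateScenario()].
#' @param nRep posterior-predictive replicates.
#' @param seed RNG seed.
#' @return data.frame with statistic, observed value, predictive mean
#'   and two-sided tail probability.
#' @export
modelCheck <- function(obs, posterior, spec, sampleConfig, nLoci,
                       nRep = 100, seed = NULL, speciesOf = NULL) {
  stopifnot(inherits(posterior, "peony_abcpost"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(posterior$sample)
  idx <- sample.int(n, nRep, replace = TRUE,
                    prob = posterior$weights)
  seeds <- .childSeeds(nRep)
  sims <- matrix(NA_real_, nRep, length(obs))
  for (i in seq_len(nRep)) {
    pv <- posterior$sample[idx[i], ]
    ## guard t1 < t2 after independent marginal adjustment
    if (pv[["t1"]] >= pv[["t2"]])
      pv[c("t1", "t2")] <- sort(pv[c("t1", "t2")]) *
        c(1, 1 + 1e-6)
    ds <- simulateScenario(spec, .vectorToParams(pv), sampleConfig,
                           nLoci, seeds[i], speciesOf = speciesOf)
    sims[i, ] <- summarizeDataset(ds)
  }
  p <- vapply(seq_along(obs), function(k) {
    pk <- mean(sims[, k] <= obs[k])
    min(pk, 1 - pk) * 2
  }, 0)
  data.frame(statistic = names(obs), observed = as.numeric(obs),
             predictiveMean = colMeans(sims), pTail = p)
}
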