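## One-config orchestration of the full analysis: synthetic data (or
## files on disk) -> microsatellite and cpDNA statistics -> demography
## -> ABC -> niche test, with a manifest recording every seed.

.defaultConfig <- function() {
  list(
    seed = 1L,
    outDir = "peonypop-run",
    synthetic = list(
      enabled = TRUE,
      scenario = 1L, step = 2L,
      params = list(NJ = 1690, NQ = 4910, NR = 5090, A1 = 4500,
                    A2 = 9520, t1 = 2430, t2 = 5030, mu = 1.74e-4),
      sampleConfig = list(J = 25, Q = 20, R = 25),
      nLoci = 22,
      cpdna = list(pops = list(P1 = list(H1 = 8, H2 = 2),
                               P2 = list(H2 = 6, H3 = 4),
                               P3 = list(H4 = 10)),
                   nSites = 500, nMutations = 12)),
    inputs = list(genotypes = NULL, popInfo = NULL, fasta = NULL,
                  assignments = NULL, occurrences = NULL,
                  background = NULL),
    msat = list(enabled = TRUE, nPerm = 200),
    cpdna = list(enabled = TRUE, nPerm = 200),
    demography = list(enabled = TRUE, nSim = 200, nBoot = 100),
    abc = list(enabled = FALSE, nPerScenario = 500, tolerance = 0.01,
               nPods = 20),
    niche = list(enabled = TRUE, nOccurrences = 30, nBackground = 200,
                 shift = 2, nVars = 8, nResample = 500))
}

.mergeConfig <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown config field '", paste0(path, k), "'")
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])) &&
        k %in% c("synthetic", "inputs", "msat", "cpdna", "demography",
                 "abc", "niche"))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]],
                                paste0(path, k, "$"))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read (and validate) a pipeline run configuration
#'
#' YAML file with the fields of the default configuration; unknown
#' fields are rejected with a field-precise message, omitted fields
#' fall back to defaults.
#'
#' @param path YAML file, or NULL for the defaults.
#' @return config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .mergeConfig(cfg, user)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages (synthetic data or file inputs,
#' microsatellite statistics, cpDNA statistics, demography, ABC, niche
#' test), writing one CSV report per stage plus a JSON manifest with
#' the config, the package version and every derived seed. Failure of
#' one stage is caught and recorded without corrupting the others'
#' outputs.
#'
#' @param config a config list (see [readRunConfig()]) or a YAML path.
#' @return (invisibly) list of stage results and output paths.
#' @export
runPipeline <- function(config = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config)) config <- .defaultConfig()
  cfg <- .mergeConfig(.defaultConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  seeds <- setNames(.childSeeds(8),
                    c("msatData", "cpdnaData", "msat", "cpdna",
                      "demography", "abc", "niche", "nicheData"))
  results <- list(); status <- list()
  runStage <- function(name, fun) {
    r <- tryCatch(fun(), error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)),
                class = "peony_stage_error")
    })
    status[[name]] <<- if (inherits(r, "peony_stage_error"))
      paste("error:", r$message) else "ok"
    results[[name]] <<- r
    r
  }
  ## ---- data ----------------------------------------------------------
  ds <- NULL; hap <- NULL; niche <- NULL
  if (isTRUE(cfg$synthetic$enabled)) {
    runStage("data", function() {
      p <- cfg$synthetic$params
      par <- scenarioParams(p$NJ, p$NQ, p$NR, p$A1, p$A2, p$t1, p$t2,
                            p$mu)
      mk <- makeMicrosatTruth(cfg$synthetic$scenario, par,
                              unlist(cfg$synthetic$sampleConfig),
                              cfg$synthetic$nLoci,
                              seed = seeds[["msatData"]],
                              step = cfg$synthetic$step)
      ds <<- mk$dataset
      cp <- cfg$synthetic$cpdna
      cpd <- makeCpdnaTruth(lapply(cp$pops, unlist),
                            nSites = cp$nSites,
                            nMutations = cp$nMutations,
                            seed = seeds[["cpdnaData"]])
      hap <<- collapseHaplotypes(cpd$alignment, cpd$assignments)
      niche <<- makeNicheTruth(3, cfg$niche$shift,
                               cfg$niche$nOccurrences,
                               cfg$niche$nBackground,
                               nVars = cfg$niche$nVars,
                               seed = seeds[["nicheData"]])
      writeGenepop(ds, file.path(cfg$outDir, "genotypes.gen"))
      "synthetic"
    })
  } else {
    runStage("data", function() {
      inp <- cfg$inputs
      if (!is.null(inp$genotypes)) {
        pi <- if (!is.null(inp$popInfo)) readPopInfo(inp$popInfo)
        ds <<- readGenepop(inp$genotypes, pi)
      }
      if (!is.null(inp$fasta)) {
        aln <- readAlignmentFasta(inp$fasta)
        asg <- read.csv(inp$assignments, stringsAsFactors = FALSE)
        hap <<- collapseHaplotypes(aln, asg)
      }
      "files"
    })
  }
  ## ---- microsatellite statistics ------------------------------------
  if (isTRUE(cfg$msat$enabled) && !is.null(ds)) {
    runStage("msat", function() {
      div <- diversityReport(ds)
      write.csv(div, file.path(cfg$outDir, "msat_diversity.csv"),
                row.names = FALSE)
      fst <- pairwiseFst(ds)
      write.csv(distMatrix(fst),
                file.path(cfg$outDir, "msat_pairwise_fst.csv"))
      hier <- if (nlevels(popLabels(ds)) >
                    nlevels(speciesLabels(ds)) &&
                  nlevels(speciesLabels(ds)) >= 2)
        "species/population" else "population"
      am <- amova(ds, hierarchy = hier, nPerm = cfg$msat$nPerm,
                  seed = seeds[["msat"]])
      write.csv(am$table, file.path(cfg$outDir, "msat_amova.csv"),
                row.names = FALSE)
      ibd <- if (nrow(popCoords(ds)) >= 4)
        mantelIBD(fst, popCoords(ds), nPerm = 999,
                  seed = seeds[["msat"]])
      pca <- genotypePCA(ds)
      mig <- relativeMigration(ds)
      if (nInd(ds) >= 4)
        sharedAlleleNJ(ds, file.path(cfg$outDir, "msat_nj.nwk"))
      list(diversity = div, fst = fst, amova = am, ibd = ibd,
           pca = pca, migration = mig)
    })
  }
  ## ---- cpDNA statistics ---------------------------------------------
  if (isTRUE(cfg$cpdna$enabled) && !is.null(hap)) {
    runStage("cpdna", function() {
      hd <- haplotypeDiversity(hap)
      pi <- nucleotideDiversity(hap)
      rep <- data.frame(pop = names(hd), Hd = unname(hd),
                        pi = unname(pi))
      write.csv(rep, file.path(cfg$outDir, "cpdna_diversity.csv"),
                row.names = FALSE)
      gn <- gstNst(hap, nPerm = cfg$cpdna$nPerm,
                   seed = seeds[["cpdna"]])
      am <- amova(hap, hierarchy = "population",
                  nPerm = cfg$cpdna$nPerm, seed = seeds[["cpdna"]])
      net <- haplotypeNetwork(hap)
      write.csv(net$edges, file.path(cfg$outDir, "cpdna_network.csv"),
                row.names = FALSE)
      writeNetworkDot(net, file.path(cfg$outDir, "cpdna_network.dot"))
      list(diversity = rep, gstNst = gn, amova = am, network = net)
    })
  }
  ## ---- demography ----------------------------------------------------
  if (isTRUE(cfg$demography$enabled) && !is.null(hap)) {
    runStage("demography", function() {
      rep <- demographyReport(hap, nSim = cfg$demography$nSim,
                              nBoot = cfg$demography$nBoot,
                              seed = seeds[["demography"]])
      write.csv(rep, file.path(cfg$outDir, "demography.csv"),
                row.names = FALSE)
      rep
    })
  }
  ## ---- ABC -----------------------------------------------------------
  if (isTRUE(cfg$abc$enabled) && !is.null(ds)) {
    runStage("abc", function() {
      prior <- defaultPriors()
      obs <- summarizeDataset(ds)
      sc <- cfg$synthetic$sampleConfig
      tab <- buildReference(scenarioCatalogue(cfg$synthetic$step)$id,
                            prior, cfg$abc$nPerScenario,
                            unlist(sc), cfg$synthetic$nLoci,
                            seed = seeds[["abc"]],
                            step = cfg$synthetic$step)
      ch <- chooseScenario(obs, tab, cfg$abc$tolerance)
      best <- ch$scenario[which.max(ch$posterior)]
      est <- estimateParams(obs, tab, best, cfg$abc$tolerance)
      write.csv(ch, file.path(cfg$outDir, "abc_scenarios.csv"),
                row.names = FALSE)
      write.csv(est$summary, file.path(cfg$outDir, "abc_params.csv"),
                row.names = FALSE)
      list(choice = ch, estimate = est)
    })
  }
  ## ---- niche ---------------------------------------------------------
  if (isTRUE(cfg$niche$enabled) && !is.null(niche)) {
    runStage("niche", function() {
      sp <- unique(niche@occurrences$species)
      prs <- utils::combn(sp, 2, simplify = FALSE)
      out <- lapply(prs, function(pr)
        divergenceTest(niche, pr, nResample = cfg$niche$nResample,
                       seed = seeds[["niche"]]))
      tab <- do.call(rbind, lapply(out, function(o)
        cbind(pair = paste(o$pair, collapse = "-"), o$table)))
      write.csv(tab, file.path(cfg$outDir, "niche_divergence.csv"),
                row.names = FALSE)
      out
    })
  }
  manifest <- list(package = "peonypop",
                   version = as.character(utils::packageVersion("peonypop")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = cfg$seed, stageSeeds = as.list(seeds),
                   status = status, config = cfg)
  jsonlite::write_json(manifest,
                       file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(results = results, status = status,
                 outDir = cfg$outDir))
}
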