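## Reading and writing the package's on-disk formats: GenePop-dialect
## genotype text, population info CSV, FASTA alignments (via Biostrings)
## and assignment CSVs.

#' Write a GenotypeDataset as GenePop-dialect text
#'
#' One locus name per line, populations separated by `Pop` lines,
#' individuals as `label , aaabbb aaabbb ...` with three digits per
#' allele and `000000` for missing calls. Individual labels are
#' `<population>_<i>` so the population name survives a round trip.
#'
#' @param ds a [GenotypeDataset-class].
#' @param file output path.
#' @export
writeGenepop <- function(ds, file) {
  stopifnot(is(ds, "GenotypeDataset"))
  a <- ds@alleles
  if (any(a >= 1000, na.rm = TRUE))
    stop("allele sizes >= 1000 cannot be written with 3-digit codes")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("peonypop genotype export", con)
  writeLines(lociNames(ds), con)
  for (p in levels(ds@popLabels)) {
    writeLines("Pop", con)
    idx <- which(ds@popLabels == p)
    for (k in seq_along(idx)) {
      i <- idx[k]
      g1 <- a[i, , 1]; g2 <- a[i, , 2]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      geno <- paste0(formatC(g1, width = 3, flag = "0"),
                     formatC(g2, width = 3, flag = "0"))
      writeLines(paste0(p, "_", k, " , ", paste(geno, collapse = " ")),
                 con)
    }
  }
  invisible(file)
}

#' Read a GenePop-dialect genotype file
#'
#' Accepts 3-digit-per-allele diploid codes (`000` = missing). Population
#' labels are taken from the individual labels (text before the last
#' underscore); when absent, populations are named `pop1`, `pop2`, ...
#' in file order. An optional population-info table attaches species and
#' coordinates.
#'
#' @param file path to the genotype file.
#' @param popInfo optional data.frame with columns `pop`, `species` and
#'   optionally `lat`, `lon` (see [readPopInfo()]).
#' @return a [GenotypeDataset-class].
#' @export
readGenepop <- function(file, popInfo = NULL) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  popIdx <- grep("^pop$", lines, ignore.case = TRUE)
  if (length(popIdx) == 0) stop("no 'Pop' separator found: not GenePop?")
  loci <- lines[2:(popIdx[1] - 1)]
  ## comma-separated locus list on one line is also legal
  if (length(loci) == 1 && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  L <- length(loci)
  popOf <- character(); labs <- character(); rows <- list()
  popNo <- 0L
  for (i in seq(popIdx[1], length(lines))) {
    if (grepl("^pop$", lines[i], ignore.case = TRUE)) {
      popNo <- popNo + 1L
      next
    }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("malformed individual line: ", lines[i])
    lab <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                      "[[:space:]]+")[[1]]
    if (length(genos) != L)
      stop("individual ", lab, " has ", length(genos),
           " genotypes, expected ", L)
    g1 <- as.integer(substr(genos, 1, 3))
    g2 <- as.integer(substr(genos, 4, 6))
    g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
    miss <- is.na(g1) | is.na(g2)
    g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
    rows[[length(rows) + 1L]] <- c(g1, g2)
    labs <- c(labs, lab)
    popOf <- c(popOf, if (grepl("_", lab)) sub("_[^_]*$", "", lab)
               else paste0("pop", popNo))
  }
  n <- length(rows)
  a <- array(NA_integer_, dim = c(n, L, 2),
             dimnames = list(labs, loci, NULL))
  for (i in seq_len(n)) {
    a[i, , 1] <- rows[[i]][seq_len(L)]
    a[i, , 2] <- rows[[i]][L + seq_len(L)]
  }
  speciesMap <- NULL; coords <- NULL
  if (!is.null(popInfo)) {
    speciesMap <- setNames(as.character(popInfo$species),
                           as.character(popInfo$pop))
    if (all(c("lat", "lon") %in% colnames(popInfo)))
      coords <- data.frame(pop = as.character(popInfo$pop),
                           lat = popInfo$lat, lon = popInfo$lon)
  }
  GenotypeDataset(a, pop = popOf, speciesMap = speciesMap,
                  coords = coords, lociNames = loci)
}

#' Read a population-info CSV
#'
#' Expected columns: `pop`, `species`, optionally `lat`, `lon`.
#'
#' @param file CSV path.
#' @export
readPopInfo <- function(file) {
  pi <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("pop", "species")
  if (!all(need %in% colnames(pi)))
    stop("population info needs columns: ", paste(need, collapse = ", "))
  pi
}

#' Read an aligned FASTA file as a character matrix
#'
#' @param file FASTA path (equal-length aligned sequences).
#' @return character matrix, one row per sequence, rownames = sequence
#'   ids.
#' @export
readAlignmentFasta <- function(file) {
  seqs <- Biostrings::readBStringSet(file)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1)
    stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Write aligned sequences to FASTA
#'
#' @param seqs named character vector of (possibly gapped) sequences.
#' @param file output path.
#' @export
writeAlignmentFasta <- function(seqs, file) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = file)
  invisible(file)
}

#' Bundled example data: population metadata for the three tree peonies
#'
#' A table of the 40 wild populations of *P. jishanensis* (10), *P. qiui*
#' (6) and *P. rockii* (24) surveyed in the Qinling--Daba Mountains:
#' species, population code, sample sizes genotyped for nuclear
#' microsatellites (`n_nuc`) and sequenced for cpDNA (`n_cp`), and
#' population coordinates.
#'
#' @return data.frame with columns `species`, `pop`, `n_nuc`, `n_cp`,
#'   `lat`, `lon`.
#' @export
peonyPopulations <- function() {
  read.csv(system.file("extdata", "peony_populations.csv",
                       package = "peonypop"),
           stringsAsFactors = FALSE)
}

#' Bundled example data: cpDNA haplotype counts per population
#'
#' Per-population counts of the 18 chloroplast haplotypes observed across
#' the 40 tree peony populations (sequence-level information is not
#' bundled; the table supports frequency-based statistics such as
#' haplotype diversity).
#'
#' @param asTable logical; if `TRUE` (default) return a
#'   [HaplotypeTable-class] (counts only, no sequences/distances),
#'   otherwise the long-format data.frame.
#' @export
peonyHaplotypeCounts <- function(asTable = TRUE) {
  df <- read.csv(system.file("extdata", "peony_cpdna_haplotypes.csv",
                             package = "peonypop"),
                 stringsAsFactors = FALSE)
  if (!asTable) return(df)
  pops <- unique(df$pop)
  haps <- unique(df$haplotype)
  cnt <- matrix(0L, length(pops), length(haps),
                dimnames = list(pops, haps))
  cnt[cbind(match(df$pop, pops), match(df$haplotype, haps))] <-
    as.integer(df$count)
  spMap <- setNames(df$species[!duplicated(df$pop)], pops)
  new("HaplotypeTable", haplotypes = character(),
      diffs = matrix(numeric(), 0, 0), counts = cnt,
      speciesMap = spMap, seqLength = 2075L)
}
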