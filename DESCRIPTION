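Package: peonypop
Title: Population Genetics and Coalescent-ABC Demographic Inference for
    Tree Peonies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the joint nuclear-microsatellite, chloroplast-DNA
    and climatic-niche analysis of the three tree peony species of the
    Qinling-Daba Mountains (Paeonia jishanensis, P. qiui, P. rockii).
    Provides S4 containers for diploid microsatellite genotypes,
    chloroplast haplotype tables and climate/occurrence data; diversity
    and differentiation statistics (Nei heterozygosities, rarefied
    allelic richness, private alleles, Weir-Cockerham FST, hierarchical
    AMOVA, GST/NST permutation tests); isolation-by-distance Mantel
    tests, shared-allele neighbour-joining, genotype PCA and directional
    relative migration; neutrality tests (Tajima's D, Fu's Fs) and
    sudden-expansion mismatch-distribution fitting; a coalescent
    simulator of microsatellites under stepwise mutation on
    three-population divergence scenarios; DIYABC-style approximate
    Bayesian computation for scenario choice and parameter estimation;
    and a background-versus-observed climatic niche divergence test.
    A synthetic-data generator with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    vegan,
    geosphere,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'abc.R'
    'amova.R'
    'coalsim.R'
    'cpdna.R'
    'demography.R'
    'fst.R'
    'genotype-dataset.R'
    'io.R'
    'msat-diversity.R'
    'msat-structure.R'
    'niche.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
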