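Package: meiomix
Title: Simulation and Inference of Modified Meiosis and Paternal Genome Loss
    in Interspecies Nematode Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study automixis and gynogenesis (sperm-dependent
    parthenogenesis) in Caenorhabditis hybrid crosses. Forward-simulates
    oocyte meiosis with one arm-biased crossover per bivalent, competing
    maternal chromatid-retention modes (canonical meiosis, central fusion,
    sister fusion, apomixis, endoreplication), and paternal genome fates
    (full retention, complete loss, diploid-triploid mosaicism). Converts
    simulated zygotes into single-worm sequencing observables (per-SNP
    allele depths with whole-genome-amplification overdispersion, windowed
    coverage on two reference genomes), genotypes chromosomes by 50-kb
    windowed allele frequencies with circular binary segmentation, classifies
    chromatid-combination genotypes and per-chromosome copy number, and
    tests observed genotype-class counts against inheritance models with an
    exact multinomial goodness-of-fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
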