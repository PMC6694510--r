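Package: mosaicimpute
Title: Founder-Line Mosaic Genotype Reconstruction from Low-Coverage
    Sequencing in Outbred Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs founder-line mosaic genotypes (HH/HL/LL) across the
    genomes of F2 intercross offspring bred from outbred, heterozygous founders
    of two divergent lines. High-coverage founder genotypes are used to select,
    within each nuclear full-sib family, markers fixed for alternative alleles
    between the line pairs; very low coverage (< 0.5x) offspring read counts at
    those markers are then decoded with a chromosome-specific three-state
    hidden Markov model into line-origin segments with recombination breakpoint
    intervals. Includes quality-control filters (marker density, close double
    crossovers, call rate, crossover-count outliers), 1-Mb genotype binning and
    R/qtl export, a pedigree/meiosis/read simulator with crossover interference
    and full ground truth, and accuracy evaluation against truth or independent
    validation genotypes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
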