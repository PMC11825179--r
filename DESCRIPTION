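Package: purgekit
Title: Runs of Homozygosity, Mutational Load and Genetic Purging Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for conservation-genomic analysis of multi-sample SNP data:
    site-level quality and missingness filtering, PLINK-style windowed
    detection of runs of homozygosity (ROH) and F_ROH inbreeding estimation,
    windowed nucleotide diversity and individual heterozygosity, functional
    classification of variants with Grantham-distance scoring and
    outgroup-based derived-allele polarization, and statistics for detecting
    genetic purging: deleterious-to-synonymous ratios inside versus outside
    ROH, the Rxy relative-load statistic with block-jackknife standard
    errors, conservation-score-weighted relative mutational load, and
    derived site-frequency spectra. Includes a seeded synthetic-population
    generator with planted autozygous tracts and a configurable purging
    effect, so every stage can be exercised and calibrated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
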