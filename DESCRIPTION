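Package: palmSSR
Title: Microsatellite Fingerprinting of Clonally Propagated Date Palm Cultivars
Version: 0.1.0
Authors@R:
    person("Al Jufrah", "Genetics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for codominant SSR (microsatellite) genotyping of clonally
    propagated crops, built around date palm cultivar collections. Provides
    readers and writers for tidy and GenAlEx-style genotype tables, per-locus
    and per-cultivar diversity statistics (observed, expected and unbiased
    expected heterozygosity, fixation index, effective allele number, fixed
    alleles), Smouse-Peakall codominant genotypic distances with principal
    coordinates analysis, an AMOVA-based PhiPT permutation test and a
    linkage-disequilibrium screen, construction of minimal multilocus cultivar
    identification keys, and simulation-calibrated maximum-likelihood
    assignment of unknown (male) trees to candidate cultivars with LOD scores
    and delta confidence. A seeded synthetic-data generator emulates clonal
    cultivars descended from single heterotic founders so that every stage of
    the pipeline can be tested without access to field genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
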