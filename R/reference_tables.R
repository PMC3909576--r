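# Published per-locus and per-cultivar summary statistics from the Al
# Jufrah (Libya) date-palm SSR survey, shipped as plain CSV under
# inst/extdata. The raw genotypes behind them were never deposited; these
# printed summaries serve as arithmetic anchors for consistency checks
# (column totals and means, the unbiased-heterozygosity and fixation-index
# relations) and as realistic targets for the synthetic generator.

ref_path <- function(file)
  system.file("extdata", file, package = "palmSSR", mustWork = TRUE)

#' Published Al Jufrah per-locus SSR summary
#'
#' One row per locus: allelic range (bp), total allele and distinct-genotype
#' counts over all female trees, observed and expected heterozygosity, and
#' the alleles fixed within at least one cultivar (`|`-separated, with the
#' cultivar abbreviations carrying each).
#'
#' @return data.frame of 16 loci
#' @export
aljufrah_locus_summary <- function() {
  utils::read.csv(ref_path("aljufrah_locus_summary.csv"),
                  stringsAsFactors = FALSE)
}

#' Published Al Jufrah per-cultivar diversity indices
#'
#' One row per cultivar: mean sample size over loci (`N`), mean allele and
#' effective-allele numbers, mean observed/expected/unbiased-expected
#' heterozygosity, fixation index and percentage of polymorphic loci.
#'
#' @return data.frame of 18 cultivars
#' @export
aljufrah_cultivar_diversity <- function() {
  utils::read.csv(ref_path("aljufrah_cultivar_diversity.csv"),
                  stringsAsFactors = FALSE)
}

#' Published identification-key locus set
#'
#' The three-locus key reported for the Al Jufrah cultivars with the number
#' of labelled alleles per locus.
#'
#' @return data.frame of 3 loci
#' @export
aljufrah_key_loci <- function() {
  utils::read.csv(ref_path("aljufrah_key_loci.csv"), stringsAsFactors = FALSE)
}

#' Published positive-LOD male assignments
#'
#' The 24 male trees reported with positive pair LOD scores, their
#' collection sites and assigned cultivars.
#'
#' @return data.frame of 24 assignments
#' @export
aljufrah_male_assignments <- function() {
  utils::read.csv(ref_path("aljufrah_male_assignments.csv"),
                  stringsAsFactors = FALSE)
}
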