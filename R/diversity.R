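# Per-locus and per-group diversity indices for codominant SSR data:
# observed heterozygosity, Hardy-Weinberg expected heterozygosity and its
# small-sample unbiased form, the fixation index and the effective allele
# number, plus cultivar-level summaries (polymorphic-locus percentage,
# fixed alleles).

#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' `Hexp = 1 - sum(p_i^2)` over the allele frequencies `p_i` of a locus.
#'
#' @param p numeric vector of allele frequencies summing to 1
#' @return a number in `[0, 1)`
#' @export
hexp <- function(p) {
  if (length(p) == 0L) stop("empty frequency vector")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 - sum(p^2)
}

#' Unbiased expected heterozygosity
#'
#' Corrects `Hexp` for diploid sample size `n`: `UHexp = 2n/(2n - 1) * Hexp`.
#'
#' @param h expected heterozygosity
#' @param n diploid sample count (>= 1)
#' @return corrected heterozygosity
#' @export
uhexp <- function(h, n) {
  if (n < 1) stop("n must be >= 1")
  (2 * n) / (2 * n - 1) * h
}

#' Fixation index (inbreeding coefficient)
#'
#' `F = (Hexp - Hobs) / Hexp`; `NA` (undefined) when `Hexp = 0`. Negative
#' values indicate heterozygote excess, as expected for clonally propagated
#' cultivars selected for heterosis; positive values indicate inbreeding or
#' null alleles.
#'
#' @param hobs observed heterozygosity in `[0, 1]`
#' @param hexp expected heterozygosity in `[0, 1]`
#' @return a number, or `NA` when `hexp` is 0
#' @export
fixation_index <- function(hobs, hexp) {
  stopifnot(hobs >= 0, hobs <= 1, hexp >= 0, hexp <= 1)
  if (hexp == 0) return(NA_real_)
  (hexp - hobs) / hexp
}

#' Effective number of alleles
#'
#' `Ne = 1 / sum(p_i^2)`: the number of equally frequent alleles giving the
#' same expected homozygosity. Equals `1 / (1 - Hexp)`.
#'
#' @param p numeric vector of allele frequencies summing to 1
#' @return a number >= 1
#' @export
effective_alleles <- function(p) {
  if (length(p) == 0L) stop("empty frequency vector")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 / sum(p^2)
}

#' Per-locus diversity indices by group
#'
#' For each group and locus with at least one non-missing call: `n` (samples
#' typed), `Na` (alleles observed in the group), `Ne`, `Hobs` (heterozygote
#' fraction among typed samples), `Hexp`, `UHexp` and `F`.
#'
#' @param x a [genotype_table()]
#' @param group_by `"cultivar"`, `"locality"` or `"all"`
#' @return data.frame with one row per group x locus
#' @export
locus_table <- function(x, group_by = c("cultivar", "locality", "all")) {
  group_by <- match.arg(group_by)
  labels <- if (group_by == "all") rep("ALL", n_samples(x)) else
    x$samples[[group_by]]
  rows <- list()
  for (g in unique(labels)) {
    idx <- which(labels == g)
    for (loc in names(x$loci)) {
      m <- x$calls[[loc]][idx, , drop = FALSE]
      m <- m[!is.na(m[, 1L]), , drop = FALSE]
      if (nrow(m) == 0L) next
      n <- nrow(m)
      cnt <- table(as.vector(m))
      p <- as.numeric(cnt) / (2L * n)
      he <- hexp(p)
      ho <- mean(m[, 1L] != m[, 2L])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = loc, n = n, Na = length(cnt),
        Ne = effective_alleles(p), Hobs = ho, Hexp = he,
        UHexp = uhexp(he, n), F = fixation_index(ho, he),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group-level summary of diversity indices
#'
#' Arithmetic means over loci of the [locus_table()] indices (monomorphic
#' loci included, contributing 0 to the heterozygosities and 1 to `Na`/`Ne`),
#' the percentage of polymorphic loci, and two fixation-index summaries:
#' `F` as the ratio of mean heterozygosities `(mean_Hexp - mean_Hobs) /
#' mean_Hexp` (the form consistent with per-cultivar report tables for this
#' kind of data) and `F_locus_mean`, the mean of per-locus `F` over
#' polymorphic loci.
#'
#' @param stats output of [locus_table()] covering all loci of `x`
#' @param x the [genotype_table()] the stats were computed from (supplies the
#'   full locus list, so loci unscored in a group still enter the
#'   polymorphism denominator)
#' @return data.frame with one row per group
#' @export
group_summary <- function(stats, x) {
  total_loci <- n_loci(x)
  rows <- lapply(split(stats, stats$group), function(s) {
    mean_hobs <- mean(s$Hobs)
    mean_hexp <- mean(s$Hexp)
    f_ratio <- if (mean_hexp > 0) (mean_hexp - mean_hobs) / mean_hexp else NA_real_
    poly <- s$Na >= 2L
    data.frame(
      group = s$group[1L],
      N = mean(s$n),
      mean_Na = mean(s$Na),
      mean_Ne = mean(s$Ne),
      mean_Hobs = mean_hobs,
      mean_Hexp = mean_hexp,
      mean_UHexp = mean(s$UHexp),
      F = f_ratio,
      F_locus_mean = if (any(poly)) mean(s$F[poly]) else NA_real_,
      P_pct = 100 * sum(poly) / total_loci,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Whole-collection per-locus allele summary
#'
#' One row per locus across all samples: allelic range in bp, total allele
#' count, number of distinct unordered genotypes, `Hobs`, `Hexp`, and the
#' number of alleles fixed in at least one cultivar.
#'
#' @param x a [genotype_table()]
#' @return data.frame with one row per locus
#' @export
locus_summary <- function(x) {
  fixed <- fixed_alleles(x)
  rows <- lapply(names(x$loci), function(loc) {
    m <- x$calls[[loc]]
    m <- m[!is.na(m[, 1L]), , drop = FALSE]
    cnt <- table(as.vector(m))
    p <- as.numeric(cnt) / (2L * nrow(m))
    geno <- unique(paste(m[, 1L], m[, 2L]))
    data.frame(
      locus = loc,
      range_min = min(as.integer(names(cnt))),
      range_max = max(as.integer(names(cnt))),
      n_alleles = length(cnt),
      n_genotypes = length(geno),
      Hobs = mean(m[, 1L] != m[, 2L]),
      Hexp = hexp(p),
      n_fixed = sum(fixed$locus == loc),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Alleles fixed within cultivars
#'
#' An allele is fixed at a locus when some cultivar's non-missing calls are
#' all homozygous for it. Each (locus, allele) pair is reported once, with
#' the cultivars carrying it fixed.
#'
#' @param x a [genotype_table()] with cultivar labels
#' @return data.frame with columns `locus`, `allele`, `cultivars`
#'   (comma-separated, sorted) and `n_cultivars`
#' @export
fixed_alleles <- function(x) {
  rows <- list()
  cvs <- unique(x$samples$cultivar)
  for (loc in names(x$loci)) {
    fixed_in <- list()
    for (cv in cvs) {
      m <- x$calls[[loc]][x$samples$cultivar == cv, , drop = FALSE]
      m <- m[!is.na(m[, 1L]), , drop = FALSE]
      if (nrow(m) == 0L) next
      a <- unique(as.vector(m))
      if (length(a) == 1L)
        fixed_in[[as.character(a)]] <- c(fixed_in[[as.character(a)]], cv)
    }
    for (al in names(fixed_in))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, allele = as.integer(al),
        cultivars = paste(sort(fixed_in[[al]]), collapse = ","),
        n_cultivars = length(fixed_in[[al]]),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(locus = character(), allele = integer(),
                      cultivars = character(), n_cultivars = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$locus, out$allele), , drop = FALSE]
}
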