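# Fixture builders shared across the suite. All tables are built in code;
# nothing binary is read from disk.

# Build a genotype_table from "a/b" genotype strings.
# loci: named list, each a character vector like c("140/150", "140/140", NA)
tab_from_strings <- function(loci, cultivar = NULL, locality = NULL,
                             sex = "female", ids = NULL, registry = NULL) {
  n <- length(loci[[1L]])
  calls <- lapply(loci, function(v) {
    stopifnot(length(v) == n)
    m <- matrix(NA_integer_, n, 2L)
    ok <- !is.na(v)
    parts <- strsplit(v[ok], "/", fixed = TRUE)
    m[ok, ] <- t(vapply(parts, function(p) as.integer(p), integer(2L)))
    m
  })
  samples <- data.frame(
    sample_id = ids %||% sprintf("S%02d", seq_len(n)),
    cultivar = cultivar %||% rep("CV1", n),
    locality = locality %||% rep("Loc1", n),
    sex = rep_len(sex, n),
    stringsAsFactors = FALSE)
  genotype_table(samples, calls, loci = registry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# Named frequency vector helper.
fr <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), names(v))
}

# Exhaustive oracle: all smallest discriminating locus subsets by direct
# enumeration over consensus-profile signatures.
oracle_min_subsets <- function(x) {
  cvs <- sort(unique(x$samples$cultivar))
  profs <- lapply(cvs, function(cv) consensus_profile(x, cv))
  names(profs) <- cvs
  sig <- function(subset)
    vapply(profs, function(p)
      paste(vapply(subset, function(l) paste(p$calls[[l]], collapse = "/"), ""),
            collapse = ";"), "")
  locs <- names(x$loci)
  for (size in seq_along(locs)) {
    subs <- utils::combn(locs, size, simplify = FALSE)
    hits <- Filter(function(s) !anyDuplicated(sig(s)), subs)
    if (length(hits)) return(list(size = size, subsets = hits))
  }
  list(size = Inf, subsets = list())
}

# Independent brute-force Smouse-Peakall single-locus distance: enumerate
# dosage vectors explicitly over the union allele set.
brute_locus_distance <- function(g1, g2) {
  alle <- sort(unique(c(g1, g2)))
  v1 <- sapply(alle, function(a) sum(g1 == a))
  v2 <- sapply(alle, function(a) sum(g2 == a))
  0.5 * sum((v1 - v2)^2)
}
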