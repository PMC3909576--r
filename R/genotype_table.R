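# Core container for codominant diploid SSR genotype tables.
#
# A genotype_table holds, for n samples typed at L loci:
#   * samples: data.frame with sample_id, cultivar, locality, sex
#   * calls:   named list of n x 2 integer matrices (allele sizes in bp),
#              rows canonicalized so allele_a <= allele_b; a missing call
#              has NA in both columns (half-missing calls are rejected)
#   * loci:    named list of strictly increasing integer allele-size vectors,
#              the registered allele set of each locus

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a codominant genotype table
#'
#' @param samples data.frame with columns `sample_id`, `cultivar`, `locality`,
#'   `sex`. Missing metadata may be given as `NA` and is stored as
#'   `"UNKNOWN"` (sex as `"unknown"`).
#' @param calls named list, one element per locus, each an `n x 2` integer
#'   matrix of allele sizes (bp). Both entries `NA` encodes a missing call;
#'   half-missing calls are rejected, not imputed.
#' @param loci optional named list of integer allele-size vectors registering
#'   the allele set per locus; defaults to the alleles observed in `calls`.
#'   Every allele observed in `calls` must be registered.
#'
#' @return An object of class `genotype_table` with components `samples`,
#'   `calls` and `loci`.
#' @export
genotype_table <- function(samples, calls, loci = NULL) {
  stopifnot(is.data.frame(samples), is.list(calls), length(calls) >= 1L)
  locus_names <- names(calls)
  if (is.null(locus_names) || anyDuplicated(locus_names) || any(locus_names == ""))
    stop("calls must be a named list with unique, non-empty locus names")

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("cultivar", "locality", "sex"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  samples$cultivar <- ifelse(is.na(samples$cultivar) | samples$cultivar == "",
                             "UNKNOWN", as.character(samples$cultivar))
  samples$locality <- ifelse(is.na(samples$locality) | samples$locality == "",
                             "UNKNOWN", as.character(samples$locality))
  sex <- tolower(as.character(samples$sex))
  sex[is.na(sex) | !(sex %in% c("female", "male"))] <- "unknown"
  samples$sex <- sex
  samples <- samples[c("sample_id", "cultivar", "locality", "sex")]
  rownames(samples) <- NULL

  n <- nrow(samples)
  calls <- lapply(locus_names, function(loc) {
    m <- calls[[loc]]
    m <- matrix(as.integer(as.matrix(m)), ncol = 2L)
    if (nrow(m) != n)
      stop("locus ", loc, ": ", nrow(m), " calls for ", n, " samples")
    half <- xor(is.na(m[, 1L]), is.na(m[, 2L]))
    if (any(half))
      stop("locus ", loc, ": half-missing call at sample ",
           samples$sample_id[which(half)[1L]])
    bad <- !is.na(m[, 1L]) & (m[, 1L] <= 0L | m[, 2L] <= 0L)
    if (any(bad))
      stop("locus ", loc, ": non-positive allele size at sample ",
           samples$sample_id[which(bad)[1L]])
    swap <- !is.na(m[, 1L]) & m[, 1L] > m[, 2L]
    if (any(swap)) m[swap, ] <- m[swap, 2:1, drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  names(calls) <- locus_names

  observed <- lapply(calls, function(m) sort(unique(as.integer(m[!is.na(m)]))))
  if (is.null(loci)) {
    loci <- observed
  } else {
    if (!setequal(names(loci), locus_names))
      stop("loci registry names do not match call locus names")
    loci <- lapply(loci[locus_names], function(a) sort(unique(as.integer(a))))
    for (loc in locus_names) {
      extra <- setdiff(observed[[loc]], loci[[loc]])
      if (length(extra))
        stop("locus ", loc, ": observed allele(s) ",
             paste(extra, collapse = ", "), " not registered")
    }
    names(loci) <- locus_names
  }

  structure(list(samples = samples, calls = calls, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d loci\n",
              nrow(x$samples), length(x$loci)))
  cat(sprintf("  cultivars: %d, localities: %d, sexes: %s\n",
              length(unique(x$samples$cultivar)),
              length(unique(x$samples$locality)),
              paste(names(table(x$samples$sex)), table(x$samples$sex),
                    sep = "=", collapse = " ")))
  na_per_locus <- vapply(x$loci, length, 1L)
  cat(sprintf("  alleles per locus: %d-%d (total %d)\n",
              min(na_per_locus), max(na_per_locus), sum(na_per_locus)))
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param x a `genotype_table`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_loci <- function(x) length(x$loci)

#' Subset a genotype table by sample
#'
#' @param x a `genotype_table`
#' @param idx integer or logical index into samples
#' @return a `genotype_table` with the selected samples; the locus registry
#'   (allele sets) is kept as-is so subsets stay comparable to the parent.
#' @export
subset_samples <- function(x, idx) {
  genotype_table(x$samples[idx, , drop = FALSE],
                 lapply(x$calls, function(m) m[idx, , drop = FALSE]),
                 loci = x$loci)
}

#' Combine two genotype tables over the same loci
#'
#' @param x,y `genotype_table` objects sharing an identical locus set
#' @return a `genotype_table` with the samples of both and the union of the
#'   registered allele sets.
#' @export
bind_samples <- function(x, y) {
  if (!identical(names(x$loci), names(y$loci)))
    stop("tables do not share the same loci")
  loci <- stats::setNames(
    lapply(names(x$loci), function(l) sort(union(x$loci[[l]], y$loci[[l]]))),
    names(x$loci))
  genotype_table(rbind(x$samples, y$samples),
                 stats::setNames(lapply(names(x$calls), function(l)
                   rbind(x$calls[[l]], y$calls[[l]])), names(x$calls)),
                 loci = loci)
}

#' Validate a genotype table
#'
#' Reporting-only checks: duplicate sample ids (caught at construction, but
#' re-checked for tables assembled by hand), alleles outside a declared
#' allelic range, and per-locus missingness.
#'
#' @param x a `genotype_table`
#' @param allelic_range optional named list `locus -> c(min, max)` of declared
#'   fragment-size ranges in bp; observed alleles outside the range are
#'   flagged as warnings.
#' @return data.frame with columns `severity` ("error"/"warning"/"note"),
#'   `locus`, `sample_id`, `message`; zero rows for a clean table.
#' @export
validate_genotypes <- function(x, allelic_range = NULL) {
  issues <- list()
  add <- function(severity, locus, sample_id, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, locus = locus, sample_id = sample_id,
      message = message, stringsAsFactors = FALSE)

  dup <- unique(x$samples$sample_id[duplicated(x$samples$sample_id)])
  for (d in dup) add("error", NA_character_, d, "duplicate sample_id")

  for (loc in names(x$loci)) {
    m <- x$calls[[loc]]
    miss <- sum(is.na(m[, 1L]))
    if (miss > 0L)
      add("note", loc, NA_character_,
          sprintf("%d/%d calls missing (%.1f%%)", miss, nrow(m),
                  100 * miss / nrow(m)))
    if (!is.null(allelic_range) && !is.null(allelic_range[[loc]])) {
      rng <- allelic_range[[loc]]
      out <- !is.na(m[, 1L]) & (m[, 1L] < rng[1L] | m[, 2L] > rng[2L])
      for (i in which(out))
        add("warning", loc, x$samples$sample_id[i],
            sprintf("allele outside declared range %d-%d: %d/%d",
                    rng[1L], rng[2L], m[i, 1L], m[i, 2L]))
    }
  }
  if (!length(issues))
    return(data.frame(severity = character(), locus = character(),
                      sample_id = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Per-group, per-locus allele frequencies
#'
#' Counts allele copies among non-missing calls and divides by `2n`, where
#' `n` is the number of samples in the group with a non-missing call at the
#' locus.
#'
#' @param x a `genotype_table`
#' @param group_by `"cultivar"`, `"locality"`, or `"all"` (a single pooled
#'   group labelled `"ALL"`)
#' @return list of `freq_table` objects, one per group, each a list with
#'   `group` and `per_locus` (`locus -> list(p = named frequency vector,
#'   n = diploid sample count)`); loci with zero non-missing calls in a group
#'   are omitted from that group's `per_locus`. Groups with no data at any
#'   locus are skipped with a warning.
#' @export
allele_frequencies <- function(x, group_by = c("cultivar", "locality", "all")) {
  group_by <- match.arg(group_by)
  labels <- if (group_by == "all") rep("ALL", n_samples(x)) else
    x$samples[[group_by]]
  out <- list()
  for (g in unique(labels)) {
    idx <- which(labels == g)
    per_locus <- list()
    for (loc in names(x$loci)) {
      m <- x$calls[[loc]][idx, , drop = FALSE]
      m <- m[!is.na(m[, 1L]), , drop = FALSE]
      if (nrow(m) == 0L) next
      cnt <- table(factor(as.vector(m), levels = x$loci[[loc]]))
      p <- as.numeric(cnt) / (2L * nrow(m))
      names(p) <- names(cnt)
      per_locus[[loc]] <- list(p = p[p > 0], n = nrow(m))
    }
    if (!length(per_locus)) {
      warning("group '", g, "' has no non-missing calls at any locus; skipped")
      next
    }
    out[[g]] <- structure(list(group = g, per_locus = per_locus),
                          class = "freq_table")
  }
  out
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table for group '%s' over %d loci\n",
              x$group, length(x$per_locus)))
  invisible(x)
}
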