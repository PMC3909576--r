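# Minimal multilocus cultivar identification keys.
#
# Cultivars -- not individuals -- are keyed: each cultivar is reduced to a
# modal consensus genotype per locus, alleles occurring among consensus
# profiles at the key loci are labelled a1.., b1.., c1.. ascending by
# fragment size, and the smallest locus subset whose consensus profiles are
# all distinct is found by exhaustive search.

#' Consensus (modal) genotype of a cultivar
#'
#' @param x a [genotype_table()]
#' @param cultivar cultivar label
#' @return list with `calls` (named list locus -> length-2 allele vector or
#'   `NA` pair) and `variant_fraction` (named numeric: fraction of typed
#'   samples deviating from the modal genotype per locus). Modal ties break
#'   toward the lexicographically smaller allele pair.
#' @export
consensus_profile <- function(x, cultivar) {
  idx <- which(x$samples$cultivar == cultivar)
  if (!length(idx)) stop("no samples for cultivar '", cultivar, "'")
  calls <- list(); vf <- numeric(0)
  for (loc in names(x$loci)) {
    m <- x$calls[[loc]][idx, , drop = FALSE]
    m <- m[!is.na(m[, 1L]), , drop = FALSE]
    if (nrow(m) == 0L) {
      calls[[loc]] <- c(NA_integer_, NA_integer_)
      vf[loc] <- NA_real_
      next
    }
    keys <- paste(m[, 1L], m[, 2L], sep = "/")
    cnt <- table(keys)
    top <- names(cnt)[cnt == max(cnt)]
    # lexicographic tie-break on the numeric allele pair
    pairs <- do.call(rbind, lapply(strsplit(top, "/", fixed = TRUE), as.integer))
    pick <- order(pairs[, 1L], pairs[, 2L])[1L]
    calls[[loc]] <- pairs[pick, ]
    vf[loc] <- 1 - max(cnt) / nrow(m)
  }
  list(calls = calls, variant_fraction = vf)
}

# Consensus profiles for all cultivars, warning on high within-cultivar
# variation (possible mixed or seed-propagated cultivar).
consensus_table <- function(x, warn_threshold = 0.2) {
  cvs <- sort(unique(x$samples$cultivar))
  profs <- lapply(cvs, function(cv) consensus_profile(x, cv))
  names(profs) <- cvs
  for (cv in cvs) {
    vf <- profs[[cv]]$variant_fraction
    high <- vf[!is.na(vf) & vf > warn_threshold]
    if (length(high))
      warning("cultivar '", cv, "': variant fraction > ", warn_threshold,
              " at ", paste(names(high), collapse = ", "),
              " (consensus may not represent all clones)")
  }
  profs
}

#' Label alleles of a locus subset
#'
#' Alleles observed among cultivar consensus profiles at each locus of the
#' subset are labelled `<prefix><i>` ascending by fragment size, with
#' prefixes a, b, c, ... assigned in subset order.
#'
#' @param x a [genotype_table()]
#' @param loci_subset character vector of locus names (at most 26)
#' @param profiles optional precomputed [consensus_profile()] list
#' @return list of labelings, each with `locus`, `prefix`, `label_map`
#'   (named character: allele size -> label)
#' @export
label_alleles <- function(x, loci_subset, profiles = NULL) {
  if (!length(loci_subset)) stop("empty locus subset")
  if (length(loci_subset) > 26L) stop("more than 26 loci cannot be prefixed a-z")
  if (!all(loci_subset %in% names(x$loci)))
    stop("unknown loci: ",
         paste(setdiff(loci_subset, names(x$loci)), collapse = ", "))
  if (is.null(profiles)) profiles <- suppressWarnings(consensus_table(x))
  out <- list()
  for (i in seq_along(loci_subset)) {
    loc <- loci_subset[i]
    alle <- sort(unique(stats::na.omit(unlist(
      lapply(profiles, function(p) p$calls[[loc]])))))
    labels <- paste0(letters[i], seq_along(alle))
    out[[loc]] <- list(locus = loc, prefix = letters[i],
                       label_map = stats::setNames(labels, alle))
  }
  out
}

# Multilocus profile strings used for uniqueness checks.
profile_strings <- function(profiles, loci_subset) {
  vapply(profiles, function(p)
    paste(vapply(loci_subset, function(loc)
      paste(p$calls[[loc]], collapse = "/"), ""), collapse = ";"), "")
}

#' Find a minimal discriminating locus subset
#'
#' Exhaustive search over subsets of size 1..`max_size` for the smallest
#' locus subset under which all cultivar consensus profiles are distinct.
#' Ties break toward fewer total labelled alleles, then lexicographic locus
#' names. Beyond `exhaustive_limit` loci per subset size the search falls
#' back to greedy forward selection.
#'
#' @param x a [genotype_table()] with >= 2 cultivars
#' @param max_size largest subset size to try (default 4)
#' @param exhaustive_limit subset size up to which search is exhaustive
#' @return object of class `id_key`: list with `loci`, `labelings`,
#'   `profiles` (cultivar -> per-locus label pairs), `unique` certificate,
#'   `total_alleles`, and `collisions` (pairs of cultivars left unseparated
#'   when `unique` is `FALSE`)
#' @export
find_key <- function(x, max_size = 4L, exhaustive_limit = 4L) {
  if (max_size < 1L) stop("max_size must be >= 1")
  cvs <- sort(unique(x$samples$cultivar))
  if (length(cvs) < 2L) stop("need at least 2 cultivars")
  profiles <- suppressWarnings(consensus_table(x))
  locs <- names(x$loci)

  n_distinct <- function(subset)
    length(unique(profile_strings(profiles, subset)))
  n_labels <- function(subset)
    sum(vapply(label_alleles(x, subset, profiles), function(l)
      length(l$label_map), 1L))

  best <- NULL
  for (size in seq_len(min(max_size, length(locs)))) {
    if (size <= exhaustive_limit) {
      cand <- utils::combn(locs, size, simplify = FALSE)
    } else {
      # greedy forward selection from the best smaller subset
      base <- best_partial(profiles, locs, size, n_distinct)
      cand <- list(base)
    }
    hits <- Filter(function(s) n_distinct(s) == length(cvs), cand)
    if (length(hits)) {
      la <- vapply(hits, n_labels, 1L)
      hits <- hits[la == min(la)]
      keys <- vapply(hits, paste, "", collapse = "\r")
      best <- hits[[order(keys)[1L]]]
      break
    }
  }

  if (is.null(best)) {
    # no discriminating subset: report the best-separating one at max size
    size <- min(max_size, length(locs))
    cand <- if (size <= exhaustive_limit)
      utils::combn(locs, size, simplify = FALSE)
    else list(best_partial(profiles, locs, size, n_distinct))
    sep <- vapply(cand, n_distinct, 1L)
    best <- cand[[which.max(sep)]]
  }
  assemble_key(x, profiles, best)
}

# Build the id_key object for a given locus subset.
assemble_key <- function(x, profiles, subset) {
  labelings <- label_alleles(x, subset, profiles)
  prof_lab <- lapply(profiles, function(p) {
    stats::setNames(lapply(subset, function(loc) {
      g <- p$calls[[loc]]
      if (is.na(g[1L])) return(c(NA_character_, NA_character_))
      unname(labelings[[loc]]$label_map[as.character(g)])
    }), subset)
  })
  strs <- profile_strings(profiles, subset)
  uniq <- !anyDuplicated(strs)
  coll <- list()
  if (!uniq) {
    dup <- split(names(profiles), strs)
    coll <- unname(Filter(function(v) length(v) > 1L, dup))
  }
  structure(list(loci = subset, labelings = labelings, profiles = prof_lab,
                 unique = uniq,
                 total_alleles = sum(vapply(labelings, function(l)
                   length(l$label_map), 1L)),
                 collisions = coll),
            class = "id_key")
}

#' Build an identification key on a forced locus subset
#'
#' Like [find_key()] but without the search: labels alleles and profiles on
#' the given loci and certifies (or refutes) uniqueness.
#'
#' @inheritParams label_alleles
#' @return an `id_key`
#' @export
build_key <- function(x, loci_subset) {
  profiles <- suppressWarnings(consensus_table(x))
  assemble_key(x, profiles, loci_subset)
}

# Greedy forward selection helper for subset sizes beyond the exhaustive
# search limit.
best_partial <- function(profiles, locs, size, n_distinct) {
  chosen <- character(0)
  for (s in seq_len(size)) {
    rest <- setdiff(locs, chosen)
    gain <- vapply(rest, function(l) n_distinct(c(chosen, l)), 1L)
    chosen <- c(chosen, rest[which.max(gain)])
  }
  sort(chosen)
}

#' @export
print.id_key <- function(x, ...) {
  cat(sprintf("id_key: %d loci (%s), %d labelled alleles, unique = %s\n",
              length(x$loci), paste(x$loci, collapse = ", "),
              x$total_alleles, x$unique))
  invisible(x)
}

#' Render an identification key as a text table
#'
#' One row per cultivar: the cultivar name followed by its per-locus label
#' pair (e.g. `a3/a7`), homozygotes as repeated labels (`a1/a1`), in a
#' deterministic (alphabetical) cultivar order.
#'
#' @param key an `id_key` from [find_key()]
#' @return character vector of tab-separated lines, header first
#' @export
render_key <- function(key) {
  header <- paste(c("cultivar", key$loci), collapse = "\t")
  rows <- vapply(sort(names(key$profiles)), function(cv) {
    cells <- vapply(key$loci, function(loc)
      paste(key$profiles[[cv]][[loc]], collapse = "/"), "")
    paste(c(cv, cells), collapse = "\t")
  }, "")
  c(header, unname(rows))
}

#' Parse a rendered identification key
#'
#' Inverse of [render_key()]; used to round-trip keys through text.
#'
#' @param lines character vector as produced by [render_key()]
#' @return list with `loci` and `profiles` (cultivar -> per-locus label
#'   pairs)
#' @export
parse_key <- function(lines) {
  cells <- strsplit(lines, "\t", fixed = TRUE)
  loci <- cells[[1L]][-1L]
  profiles <- list()
  for (row in cells[-1L]) {
    profiles[[row[1L]]] <- stats::setNames(
      lapply(row[-1L], function(s) strsplit(s, "/", fixed = TRUE)[[1L]]), loci)
  }
  list(loci = loci, profiles = profiles)
}
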