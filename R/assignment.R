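# Maximum-likelihood assignment of unknown (male) trees to candidate
# cultivars. Each candidate profile is scored as the putative single parent
# of the query: the per-locus likelihood ratio compares the Mendelian
# transition probability (one gamete from the candidate, the other from the
# population allele pool) against the HWE probability of the query genotype
# in an unrelated individual, with a simple per-locus mistyping model. The
# summed natural-log ratio is the LOD score; confidence in the best
# candidate is calibrated by Monte-Carlo simulation of the delta (best
# minus second-best LOD) criterion.

#' Assignment configuration
#'
#' @param error_rate probability `e` that a locus call is mistyped (the
#'   observed genotype then being a random HWE draw)
#' @param n_sim number of simulated offspring used to calibrate the delta
#'   criterion
#' @param strict_conf,relaxed_conf confidence levels for the strict and
#'   relaxed assignment tiers
#' @param seed integer seed for the calibration simulation
#' @return list of class `assign_config`
#' @export
assign_config <- function(error_rate = 0.01, n_sim = 10000L,
                          strict_conf = 0.95, relaxed_conf = 0.80,
                          seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1, n_sim >= 100L,
            relaxed_conf > 0.5, relaxed_conf < strict_conf, strict_conf < 1)
  structure(list(error_rate = error_rate, n_sim = as.integer(n_sim),
                 strict_conf = strict_conf, relaxed_conf = relaxed_conf,
                 seed = as.integer(seed)),
            class = "assign_config")
}

#' Single-parent Mendelian transition probability
#'
#' Probability of observing offspring genotype `offspring` given that one
#' gamete comes from `parent` (each parental allele transmitted with
#' probability 1/2) and the other from a population with allele frequencies
#' `p`. Zero when no parental allele occurs in the offspring.
#'
#' @param parent,offspring length-2 allele vectors (unordered genotypes)
#' @param p named allele-frequency vector for the locus
#' @return probability in `[0, 1]`
#' @export
transition_prob <- function(parent, offspring, p) {
  freq <- function(a) {
    f <- p[as.character(a)]
    if (is.na(f)) 0 else unname(f)
  }
  gametes <- if (parent[1L] == parent[2L]) {
    stats::setNames(1, parent[1L])
  } else {
    stats::setNames(c(0.5, 0.5), parent)
  }
  tot <- 0
  for (g in names(gametes)) {
    gi <- as.integer(g)
    w <- gametes[[g]]
    if (offspring[1L] == offspring[2L]) {
      if (gi == offspring[1L]) tot <- tot + w * freq(offspring[1L])
    } else {
      if (gi == offspring[1L]) tot <- tot + w * freq(offspring[2L])
      if (gi == offspring[2L]) tot <- tot + w * freq(offspring[1L])
    }
  }
  tot
}

# HWE genotype frequency of an unordered call.
hwe_geno_freq <- function(g, p) {
  fa <- p[as.character(g[1L])]; fb <- p[as.character(g[2L])]
  fa <- if (is.na(fa)) 0 else unname(fa)
  fb <- if (is.na(fb)) 0 else unname(fb)
  if (g[1L] == g[2L]) fa^2 else 2 * fa * fb
}

#' LOD score of a candidate parent for a query genotype
#'
#' Per typed locus, `ln(((1 - e) * T + e * P) / P)` where `T` is the
#' single-parent transition probability and `P` the HWE frequency of the
#' query genotype; a Mendelian mismatch therefore contributes `ln(e)` (a
#' finite negative value) when `e > 0` and `-Inf` when `e = 0`.
#'
#' @param query_calls,candidate_calls named lists `locus -> length-2 allele
#'   vector` (NA pairs skipped)
#' @param freqs a `freq_table` supplying the allele frequencies
#' @param e per-locus mistyping rate
#' @return the summed natural-log likelihood ratio; `-Inf` (with a warning)
#'   if `e = 0` and a mismatch occurs
#' @export
lod_score <- function(query_calls, candidate_calls, freqs, e = 0.01) {
  shared <- intersect(names(query_calls), names(candidate_calls))
  lod <- 0
  used <- 0L
  for (loc in shared) {
    qg <- query_calls[[loc]]; cg <- candidate_calls[[loc]]
    if (is.na(qg[1L]) || is.na(cg[1L])) next
    p <- freqs$per_locus[[loc]]$p
    if (is.null(p)) next
    P <- hwe_geno_freq(qg, p)
    if (P <= 0) next  # query carries an allele unseen in the reference pool
    Tr <- transition_prob(cg, qg, p)
    num <- (1 - e) * Tr + e * P
    if (num <= 0) {
      warning("Mendelian mismatch with error_rate = 0 at ", loc,
              "; LOD is -Inf")
      return(-Inf)
    }
    lod <- lod + log(num / P)
    used <- used + 1L
  }
  if (used == 0L) stop("no shared typed locus between query and candidate")
  lod
}

#' Candidate profiles from a reference table
#'
#' The distinct multilocus genotypes observed within each cultivar become
#' candidate parental profiles (a cultivar with variant clones therefore
#' contributes several profiles).
#'
#' @param x a [genotype_table()] of reference (female) trees
#' @return list of candidates, each with `cultivar`, `profile_id` and
#'   `calls` (named list locus -> length-2 allele vector)
#' @export
candidate_profiles <- function(x) {
  out <- list()
  for (cv in sort(unique(x$samples$cultivar))) {
    idx <- which(x$samples$cultivar == cv)
    keys <- vapply(idx, function(i)
      paste(vapply(names(x$calls), function(loc)
        paste(x$calls[[loc]][i, ], collapse = "/"), ""), collapse = ";"), "")
    reps <- idx[!duplicated(keys)]
    for (k in seq_along(reps)) {
      i <- reps[k]
      calls <- stats::setNames(lapply(names(x$calls), function(loc)
        x$calls[[loc]][i, ]), names(x$calls))
      out[[length(out) + 1L]] <- list(
        cultivar = cv, profile_id = sprintf("%s#%d", cv, k), calls = calls)
    }
  }
  out
}

# LOD scores of many queries against many candidates, vectorized over
# queries within each locus x candidate cell.
# queries: list of named call lists. Returns matrix n_query x n_candidate.
lod_matrix <- function(queries, candidates, freqs, e) {
  nq <- length(queries); nc <- length(candidates)
  L <- matrix(0, nq, nc)
  locs <- names(freqs$per_locus)
  for (loc in locs) {
    p <- freqs$per_locus[[loc]]$p
    qg <- t(vapply(queries, function(q)
      q[[loc]] %||% c(NA_integer_, NA_integer_), integer(2L)))
    a <- qg[, 1L]; b <- qg[, 2L]
    lookup <- function(al) {
      f <- unname(p[as.character(al)])
      f[is.na(f)] <- 0
      f
    }
    pa <- lookup(a); pb <- lookup(b)
    hom <- !is.na(a) & a == b
    Pq <- ifelse(hom, pa^2, 2 * pa * pb)
    usable <- !is.na(a) & Pq > 0
    # transition contribution of one parental gamete allele g
    t_of <- function(g)
      ifelse(hom, (a == g) * pa, (g == a) * pb + (g == b) * pa)
    for (j in seq_len(nc)) {
      cg <- candidates[[j]]$calls[[loc]]
      if (is.null(cg) || is.na(cg[1L])) next
      Tr <- if (cg[1L] == cg[2L]) t_of(cg[1L]) else
        0.5 * t_of(cg[1L]) + 0.5 * t_of(cg[2L])
      num <- (1 - e) * Tr + e * Pq
      contrib <- rep(0, nq)
      contrib[usable] <- log(num[usable] / Pq[usable])  # -Inf iff e=0 mismatch
      L[, j] <- L[, j] + contrib
    }
  }
  L
}

# Best/second-best cultivar-level LOD and delta from a LOD matrix row.
# Profiles of the same cultivar never penalize each other: the per-cultivar
# LOD is the max over its profiles, and delta is taken across cultivars.
# An exact LOD tie between two cultivars (e.g. both carry an identical
# profile) is flagged: the query cannot be attributed.
cultivar_delta <- function(lods, cultivars) {
  by_cv <- tapply(lods, cultivars, max)
  ord <- order(by_cv, decreasing = TRUE)
  best <- names(by_cv)[ord[1L]]
  delta <- if (length(by_cv) > 1L) by_cv[ord[1L]] - by_cv[ord[2L]] else Inf
  list(best = best, lod = unname(by_cv[ord[1L]]), delta = unname(delta),
       tie = length(by_cv) > 1L && delta < 1e-12,
       per_cultivar = by_cv)
}

#' Calibrate delta confidence thresholds by simulation
#'
#' Simulates `n_sim` offspring, each from a uniformly drawn candidate (one
#' gamete from the candidate, one from the population pool, then per-locus
#' mistyping at rate `e`), scores them against all candidates and records
#' the cultivar-level delta and whether the best cultivar is the true
#' source. The critical delta at confidence `c` is the smallest simulated
#' delta `d` such that the success proportion among trials with delta >= `d`
#' is at least `c` (`Inf` with a warning if unreachable).
#'
#' @param candidates list from [candidate_profiles()]
#' @param freqs a `freq_table` of population allele frequencies
#' @param config an [assign_config()]
#' @return object of class `critical_deltas`: list with `strict_delta`,
#'   `relaxed_delta`, `assignment_rate` (fraction of simulated queries at or
#'   above each threshold), `success_rate`, `n_sim`
#' @export
simulate_critical_deltas <- function(candidates, freqs, config) {
  if (length(candidates) < 2L) stop("need at least 2 candidates")
  locs <- names(freqs$per_locus)
  cultivars <- vapply(candidates, `[[`, "", "cultivar")
  sim <- with_seed(derive_seed(config$seed, "critdelta"), {
    truth <- resample(seq_along(candidates), config$n_sim, replace = TRUE)
    queries <- lapply(truth, function(ci) {
      calls <- list()
      for (loc in locs) {
        p <- freqs$per_locus[[loc]]$p
        cg <- candidates[[ci]]$calls[[loc]]
        g <- if (is.null(cg) || is.na(cg[1L])) draw_genotype(p) else
          sort(c(resample(cg), resample(as.integer(names(p)), prob = p)))
        if (stats::runif(1) < config$error_rate) g <- draw_genotype(p)
        calls[[loc]] <- g
      }
      calls
    })
    list(truth = truth, queries = queries)
  })
  L <- lod_matrix(sim$queries, candidates, freqs, config$error_rate)
  res <- lapply(seq_len(nrow(L)), function(i) cultivar_delta(L[i, ], cultivars))
  delta <- vapply(res, `[[`, 0, "delta")
  # an exact cross-cultivar tie can never be certified: count it as failure
  success <- vapply(seq_along(res), function(i)
    !res[[i]]$tie && res[[i]]$best == cultivars[sim$truth[i]], TRUE)

  critical <- function(conf) {
    ord <- order(delta, decreasing = TRUE)
    succ_sorted <- success[ord]
    delta_sorted <- delta[ord]
    rate <- cumsum(succ_sorted) / seq_along(succ_sorted)
    if (rate[length(rate)] >= conf) return(0)  # whole set already qualifies
    ok <- which(rate >= conf)
    if (!length(ok)) {
      warning(sprintf("confidence %.2f unreachable (max tail success %.3f)",
                      conf, max(rate)))
      return(Inf)
    }
    # largest tail (smallest delta) still meeting the confidence level
    delta_sorted[max(ok)]
  }
  strict <- critical(config$strict_conf)
  relaxed <- critical(config$relaxed_conf)
  if (is.finite(strict) && is.finite(relaxed) && relaxed > strict)
    relaxed <- strict
  structure(list(
    strict_delta = strict, relaxed_delta = relaxed,
    assignment_rate = c(strict = mean(delta >= strict),
                        relaxed = mean(delta >= relaxed)),
    success_rate = c(strict = mean(success[delta >= strict]),
                     relaxed = mean(success[delta >= relaxed])),
    n_sim = config$n_sim),
    class = "critical_deltas")
}

#' @export
print.critical_deltas <- function(x, ...) {
  cat(sprintf(paste0("critical_deltas (n_sim = %d): strict >= %.3f ",
                     "(%.1f%% assigned), relaxed >= %.3f (%.1f%% assigned)\n"),
              x$n_sim, x$strict_delta, 100 * x$assignment_rate["strict"],
              x$relaxed_delta, 100 * x$assignment_rate["relaxed"]))
  invisible(x)
}

#' Assign query trees to candidate cultivars
#'
#' Scores every query against every candidate profile, takes the best
#' cultivar (maximum profile LOD per cultivar), and grades confidence by
#' comparing the cultivar-level delta with simulation-calibrated critical
#' deltas.
#'
#' @param queries a [genotype_table()] of unknown trees
#' @param candidates list from [candidate_profiles()]
#' @param freqs population `freq_table` (typically from the full female
#'   reference, `group_by = "all"`)
#' @param config an [assign_config()]
#' @param deltas optional precomputed [simulate_critical_deltas()] result
#' @return list with `assignments` (data.frame: `query_id`, `locality`,
#'   `cultivar`, `profile_id`, `lod`, `delta`, `confidence` in
#'   strict/relaxed/none, `n_loci_used`), `critical_deltas`, and
#'   `lod_matrix` (query x candidate)
#' @export
assign_queries <- function(queries, candidates, freqs, config = assign_config(),
                           deltas = NULL) {
  if (is.null(deltas))
    deltas <- simulate_critical_deltas(candidates, freqs, config)
  locs <- names(freqs$per_locus)
  qcalls <- lapply(seq_len(n_samples(queries)), function(i)
    stats::setNames(lapply(names(queries$calls), function(loc)
      queries$calls[[loc]][i, ]), names(queries$calls)))
  n_used <- vapply(qcalls, function(q)
    sum(vapply(locs, function(loc)
      !is.null(q[[loc]]) && !is.na(q[[loc]][1L]), TRUE)), 1L)
  L <- lod_matrix(qcalls, candidates, freqs, config$error_rate)
  cultivars <- vapply(candidates, `[[`, "", "cultivar")
  profile_ids <- vapply(candidates, `[[`, "", "profile_id")
  rows <- lapply(seq_len(nrow(L)), function(i) {
    if (n_used[i] == 0L)
      return(data.frame(query_id = queries$samples$sample_id[i],
                        locality = queries$samples$locality[i],
                        cultivar = NA_character_, profile_id = NA_character_,
                        lod = NA_real_, delta = NA_real_,
                        confidence = "unassigned", n_loci_used = 0L,
                        stringsAsFactors = FALSE))
    cd <- cultivar_delta(L[i, ], cultivars)
    best_j <- which(cultivars == cd$best)[which.max(L[i, cultivars == cd$best])]
    conf <- if (cd$tie) "none"  # indistinguishable cultivars
    else if (cd$delta >= deltas$strict_delta) "strict"
    else if (cd$delta >= deltas$relaxed_delta) "relaxed" else "none"
    data.frame(query_id = queries$samples$sample_id[i],
               locality = queries$samples$locality[i],
               cultivar = cd$best, profile_id = profile_ids[best_j],
               lod = cd$lod, delta = cd$delta, confidence = conf,
               n_loci_used = n_used[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$locality, out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  list(assignments = out, critical_deltas = deltas, lod_matrix = L)
}
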