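# Smouse-Peakall codominant genotypic distances and downstream analyses.
#
# A diploid genotype at a locus is scored as an additive dosage vector over
# the locus allele set (homozygote AiAi -> 2 at i, heterozygote AiAj -> 1 at
# i and j). The squared genotypic distance between two individuals at a
# locus is one-half the squared Euclidean distance between their dosage
# vectors, giving single-locus values in {0, 1, 2, 3, 4}; multilocus
# distance is the sum over loci under independence.

#' Additive genotype scoring vector
#'
#' @param call length-2 integer vector of allele sizes (canonical unordered
#'   form), or both `NA` for a missing call
#' @param alleles the locus's registered allele sizes
#' @return named integer dosage vector over `alleles` (all zero, with
#'   attribute `missing = TRUE`, for a missing call)
#' @export
score_vector <- function(call, alleles) {
  v <- stats::setNames(integer(length(alleles)), alleles)
  if (is.na(call[1L])) {
    attr(v, "missing") <- TRUE
    return(v)
  }
  if (!all(call %in% alleles))
    stop("unregistered allele(s): ", paste(setdiff(call, alleles), collapse = ", "))
  v[as.character(call[1L])] <- v[as.character(call[1L])] + 1L
  v[as.character(call[2L])] <- v[as.character(call[2L])] + 1L
  v
}

# Single-locus squared genotypic distance between two canonical calls.
locus_pair_distance <- function(a, b) {
  # 0.5 * ||dosage(a) - dosage(b)||^2 over the union of the two calls' alleles
  alle <- unique(c(a, b))
  da <- tabulate(match(a, alle), length(alle))
  db <- tabulate(match(b, alle), length(alle))
  0.5 * sum((da - db)^2)
}

#' Pairwise squared genotypic distance between two samples
#'
#' Sums single-locus squared distances over the loci where both samples have
#' a non-missing call.
#'
#' @param x a [genotype_table()]
#' @param i,j sample indices (or sample ids)
#' @param rescale if `TRUE`, rescale the sum by `L / loci_used` to keep
#'   distances comparable under missing data (off by default: complete
#'   profiles are the norm for curated SSR panels)
#' @return a non-negative number; errors if the pair shares no typed locus
#' @export
pair_distance <- function(x, i, j, rescale = FALSE) {
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  used <- 0L
  d <- 0
  for (loc in names(x$calls)) {
    a <- x$calls[[loc]][i, ]
    b <- x$calls[[loc]][j, ]
    if (is.na(a[1L]) || is.na(b[1L])) next
    used <- used + 1L
    d <- d + locus_pair_distance(a, b)
  }
  if (used == 0L) stop("samples share no typed locus; distance undefined")
  if (rescale) d <- d * n_loci(x) / used
  d
}

#' Full squared genotypic distance matrix
#'
#' Computes the Smouse-Peakall squared-distance matrix for all sample pairs,
#' locus by locus through dosage matrices (missing calls drop the locus for
#' the pairs involved).
#'
#' @inheritParams pair_distance
#' @return object of class `ssr_dist`: list with `ids`, symmetric `matrix`
#'   (zero diagonal) and `loci_used` (pairwise count of shared typed loci)
#' @export
genotypic_distance <- function(x, rescale = FALSE) {
  n <- n_samples(x)
  D <- matrix(0, n, n)
  used <- matrix(0L, n, n)
  for (loc in names(x$calls)) {
    m <- x$calls[[loc]]
    ok <- !is.na(m[, 1L])
    alle <- x$loci[[loc]]
    k <- length(alle)
    M <- matrix(0, n, k)
    ia <- match(m[ok, 1L], alle)
    ib <- match(m[ok, 2L], alle)
    rows <- which(ok)
    M[cbind(rows, ia)] <- M[cbind(rows, ia)] + 1
    M[cbind(rows, ib)] <- M[cbind(rows, ib)] + 1
    sq <- rowSums(M^2)
    Dl <- 0.5 * (outer(sq, sq, "+") - 2 * tcrossprod(M))
    both <- outer(ok, ok, "&")
    Dl[!both] <- 0
    D <- D + Dl
    used <- used + both
  }
  D[D < 0] <- 0           # guard tiny negative rounding
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (any(used[upper.tri(used)] == 0L))
    warning("some sample pairs share no typed locus; their distance is undefined (0 reported)")
  if (rescale) {
    scale <- n_loci(x) / pmax(used, 1L)
    D <- D * scale
  }
  structure(list(ids = x$samples$sample_id, matrix = D, loci_used = used),
            class = "ssr_dist")
}

#' @export
print.ssr_dist <- function(x, ...) {
  cat(sprintf("ssr_dist: %d x %d squared genotypic distances (max %.2f)\n",
              nrow(x$matrix), ncol(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Cultivar-level distance summary
#'
#' Off-diagonal entries are the mean individual distances between all cross
#' pairs of two cultivars; the diagonal holds the mean pairwise dissimilarity
#' internal to each cultivar (0 for singletons, flagged).
#'
#' @param dist an `ssr_dist` from [genotypic_distance()]
#' @param labels cultivar label per sample (defaults required)
#' @return object of class `cultivar_dist`: list with `cultivars`, `matrix`
#'   (between means, within means on the diagonal) and `singleton` flags
#' @export
cultivar_matrix <- function(dist, labels) {
  stopifnot(length(labels) == length(dist$ids))
  cvs <- sort(unique(labels))
  k <- length(cvs)
  M <- matrix(0, k, k, dimnames = list(cvs, cvs))
  singleton <- stats::setNames(logical(k), cvs)
  for (a in seq_len(k)) {
    ia <- which(labels == cvs[a])
    if (length(ia) == 1L) singleton[a] <- TRUE
    if (length(ia) >= 2L) {
      sub <- dist$matrix[ia, ia, drop = FALSE]
      M[a, a] <- mean(sub[upper.tri(sub)])
    }
    if (a < k) for (b in (a + 1L):k) {
      ib <- which(labels == cvs[b])
      M[a, b] <- M[b, a] <- mean(dist$matrix[ia, ib, drop = FALSE])
    }
  }
  structure(list(cultivars = cvs, matrix = M, singleton = singleton),
            class = "cultivar_dist")
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Gower double-centering of `-D/2` (the input already being squared
#' distances) followed by eigendecomposition; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. The percentage
#' of variation per axis is computed over positive eigenvalues only;
#' negative eigenvalues (non-Euclidean input) are retained in `eigenvalues`
#' for inspection.
#'
#' @param d an `ssr_dist`, a `cultivar_dist` (its off-diagonal part is
#'   embedded; within-cultivar diagonal values are reported alongside, not
#'   embedded), or a plain symmetric matrix of squared distances
#' @return object of class `ssr_pcoa`: list with `ids`, `eigenvalues`
#'   (descending), `coordinates` (one column per positive axis),
#'   `pct_variation` and `cumulative_pct`
#' @export
ssr_pcoa <- function(d) {
  if (inherits(d, "ssr_dist")) {
    M <- d$matrix; ids <- d$ids
  } else if (inherits(d, "cultivar_dist")) {
    M <- d$matrix; diag(M) <- 0; ids <- d$cultivars
  } else {
    M <- as.matrix(d); ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  }
  if (any(is.na(M))) stop("distance matrix contains NA")
  if (nrow(M) < 3L) stop("PCoA needs at least 3 entities")
  n <- nrow(M)
  A <- -0.5 * M
  # Gower centering: B = (I - 11'/n) A (I - 11'/n)
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  B <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev) * 1e-9 & ev > 0
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), sum(pos))
  rownames(coords) <- ids
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pct <- 100 * ev[pos] / sum(ev[pos])
  structure(list(ids = ids, eigenvalues = ev, coordinates = coords,
                 pct_variation = pct, cumulative_pct = cumsum(pct)),
            class = "ssr_pcoa")
}

#' @export
print.ssr_pcoa <- function(x, ...) {
  k <- min(3L, length(x$pct_variation))
  cat(sprintf("ssr_pcoa: %d entities, %d positive axes; first %d axes explain %.1f%%\n",
              length(x$ids), length(x$pct_variation), k, x$cumulative_pct[k]))
  invisible(x)
}

# AMOVA variance components from a squared-distance matrix and group labels.
# SS_within = sum over groups of (sum of within-group pair d2) / n_g;
# SS_total = (sum of all pair d2) / N. PhiPT = s2_among / (s2_among + s2_within).
amova_phi <- function(D, groups) {
  N <- nrow(D)
  tab <- table(groups)
  G <- length(tab)
  ss_total <- sum(D[upper.tri(D)]) / N
  ss_within <- 0
  for (g in names(tab)) {
    idx <- which(groups == g)
    if (length(idx) >= 2L) {
      sub <- D[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1L
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(tab^2) / N) / df_among
  s2_within <- ms_within
  s2_among <- (ms_among - ms_within) / n0
  phi <- s2_among / (s2_among + s2_within)
  list(phi = phi, s2_among = s2_among, s2_within = s2_within,
       ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within)
}

#' PhiPT permutation test (AMOVA on squared distances)
#'
#' PhiPT is the among-group fraction of molecular variance estimated from
#' the squared genotypic distance matrix; significance is assessed by
#' permuting individual group labels.
#'
#' @param dist an `ssr_dist` (or plain symmetric squared-distance matrix)
#' @param groups group label per sample
#' @param n_perm number of label permutations (999 is customary)
#' @param seed integer seed for the permutation stream
#' @return object of class `phipt_result`: list with `phi_pt`,
#'   `n_permutations`, `p_value` (add-one rule, so never exactly 0) and the
#'   variance components
#' @export
phipt <- function(dist, groups, n_perm = 999L, seed = 1L) {
  D <- if (inherits(dist, "ssr_dist")) dist$matrix else as.matrix(dist)
  stopifnot(length(groups) == nrow(D), n_perm >= 1L)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab == 0L)) stop("empty group")
  obs <- amova_phi(D, groups)
  ge <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(length(groups))
      if (amova_phi(D, groups[perm])$phi >= obs$phi) hits <- hits + 1L
    }
    hits
  })
  structure(list(phi_pt = obs$phi, n_permutations = as.integer(n_perm),
                 p_value = (1 + ge) / (n_perm + 1),
                 components = obs),
            class = "phipt_result")
}

#' @export
print.phipt_result <- function(x, ...) {
  cat(sprintf("PhiPT = %.3f, p = %.3f (%d permutations)\n",
              x$phi_pt, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise linkage-disequilibrium screen
#'
#' For every unordered pair of loci, tests multilocus genotypic association
#' with a permutation test: the statistic is the sum over allele pairs of the
#' squared covariance between allele-dosage vectors, and the null is built
#' by permuting individuals' genotypes at the second locus. Samples missing
#' at either locus are dropped pairwise.
#'
#' @param x a [genotype_table()]
#' @param n_perm permutations per pair
#' @param seed integer seed
#' @return data.frame with one row per locus pair: `locus1`, `locus2`,
#'   `statistic`, `p_value`, `n` (samples used)
#' @export
ld_screen <- function(x, n_perm = 999L, seed = 1L) {
  locs <- names(x$loci)
  if (length(locs) < 2L) stop("need at least 2 loci")
  dosage <- lapply(locs, function(loc) {
    m <- x$calls[[loc]]
    alle <- x$loci[[loc]]
    M <- matrix(0, nrow(m), length(alle))
    ok <- which(!is.na(m[, 1L]))
    M[cbind(ok, match(m[ok, 1L], alle))] <- M[cbind(ok, match(m[ok, 1L], alle))] + 1
    M[cbind(ok, match(m[ok, 2L], alle))] <- M[cbind(ok, match(m[ok, 2L], alle))] + 1
    M[is.na(m[, 1L]), ] <- NA
    M
  })
  names(dosage) <- locs
  cov_stat <- function(A, B) {
    # sum of squared covariances between all dosage columns
    Ac <- scale(A, center = TRUE, scale = FALSE)
    Bc <- scale(B, center = TRUE, scale = FALSE)
    C <- crossprod(Ac, Bc) / (nrow(A) - 1L)
    sum(C^2)
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(locs)[-length(locs)]) for (j in (i + 1L):length(locs)) {
      A <- dosage[[i]]; B <- dosage[[j]]
      ok <- !is.na(A[, 1L]) & !is.na(B[, 1L])
      A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
      n <- nrow(A)
      if (n < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus1 = locs[i], locus2 = locs[j], statistic = NA_real_,
          p_value = NA_real_, n = n, stringsAsFactors = FALSE)
        next
      }
      obs <- cov_stat(A, B)
      ge <- 0L
      for (b in seq_len(n_perm))
        if (cov_stat(A, B[sample.int(n), , drop = FALSE]) >= obs) ge <- ge + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        locus1 = locs[i], locus2 = locs[j], statistic = obs,
        p_value = (1 + ge) / (n_perm + 1), n = n, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
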