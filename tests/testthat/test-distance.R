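# Smouse-Peakall distances, cultivar summary, PCoA, PhiPT and the LD
# screen, each checked against an independent oracle.

test_that("single-locus distances match brute-force dosage enumeration", {
  cases <- list(
    list(g1 = c(140L, 150L), g2 = c(140L, 150L), d = 0),  # identical het
    list(g1 = c(140L, 150L), g2 = c(140L, 160L), d = 1),  # AB vs AC
    list(g1 = c(140L, 140L), g2 = c(140L, 150L), d = 1),  # AA vs AB
    list(g1 = c(140L, 150L), g2 = c(160L, 170L), d = 2),  # AB vs CD
    list(g1 = c(140L, 140L), g2 = c(150L, 160L), d = 3),  # AA vs BC
    list(g1 = c(140L, 140L), g2 = c(150L, 150L), d = 4))  # AA vs BB
  for (cs in cases) {
    x <- tab_from_strings(list(L1 = c(paste(cs$g1, collapse = "/"),
                                      paste(cs$g2, collapse = "/"))))
    expect_equal(pair_distance(x, 1L, 2L), cs$d)
    expect_equal(brute_locus_distance(cs$g1, cs$g2), cs$d)  # oracle agrees
    expect_equal(genotypic_distance(x)$matrix[1L, 2L], cs$d)
  }
})

test_that("score_vector follows the additive dosage convention", {
  expect_identical(unname(score_vector(c(140L, 140L), c(140L, 150L))),
                   c(2L, 0L))
  expect_identical(unname(score_vector(c(140L, 150L), c(140L, 150L, 160L))),
                   c(1L, 1L, 0L))
  miss <- score_vector(c(NA_integer_, NA_integer_), c(140L, 150L))
  expect_true(isTRUE(attr(miss, "missing")))
  expect_true(all(miss == 0L))
  expect_error(score_vector(c(999L, 999L), c(140L, 150L)), "unregistered")
})

test_that("multilocus distance sums per-locus values; missing loci drop pairwise", {
  x <- tab_from_strings(list(L1 = c("140/140", "150/150"),    # 4
                             L2 = c("100/102", "100/104"),    # 1
                             L3 = c("200/202", NA)))          # dropped
  expect_equal(pair_distance(x, 1L, 2L), 5)
  D <- genotypic_distance(x)
  expect_equal(D$matrix[1L, 2L], 5)
  expect_identical(D$loci_used[1L, 2L], 2L)
  # rescaled variant inflates by L / loci_used
  expect_equal(pair_distance(x, 1L, 2L, rescale = TRUE), 5 * 3 / 2)
  # metric sanity on a simulated table
  d <- simulate_dataset(sim_config(n_loci = 6L, n_cultivars = 4L,
                                   clones_per_cultivar = 5L, n_males = 0L,
                                   rng_seed = 23L))
  D <- genotypic_distance(d$females)
  expect_true(isSymmetric(D$matrix))
  expect_true(all(diag(D$matrix) == 0))
  expect_true(all(D$matrix <= 4 * n_loci(d$females)))
  # zero distance iff identical multilocus genotypes
  for (i in c(1L, 5L, 9L)) for (j in c(2L, 7L)) {
    same <- all(vapply(names(d$females$calls), function(loc)
      identical(d$females$calls[[loc]][i, ], d$females$calls[[loc]][j, ]), TRUE))
    expect_identical(D$matrix[i, j] == 0, same)
  }
})

test_that("cultivar_matrix averages cross pairs and within pairs", {
  x <- tab_from_strings(list(L1 = c("140/140", "140/140", "150/150", "140/150")),
                        cultivar = c("A", "A", "B", "B"))
  cm <- cultivar_matrix(genotypic_distance(x), x$samples$cultivar)
  # brute force: cross pairs (1,3)=4 (1,4)=1 (2,3)=4 (2,4)=1 -> mean 2.5
  expect_equal(cm$matrix["A", "B"], 2.5)
  expect_equal(cm$matrix["A", "A"], 0)      # identical clones
  expect_equal(cm$matrix["B", "B"], 1)      # within B: BB vs AB = 1
  expect_false(any(cm$singleton))
  # singleton cultivars flagged, diagonal 0
  y <- tab_from_strings(list(L1 = c("140/140", "150/150")),
                        cultivar = c("A", "B"))
  cmy <- cultivar_matrix(genotypic_distance(y), y$samples$cultivar)
  expect_true(all(cmy$singleton))
  expect_equal(cmy$matrix["A", "B"], 4)
})

test_that("PCoA matches the ape oracle and closed forms", {
  # three mutually equidistant entities: two equal eigenvalues, equilateral
  M <- matrix(4, 3, 3); diag(M) <- 0
  p <- ssr_pcoa(M)
  expect_equal(p$eigenvalues[1L], p$eigenvalues[2L], tolerance = 1e-10)
  expect_equal(p$eigenvalues[1L], 2, tolerance = 1e-10)
  d12 <- sum((p$coordinates[1L, ] - p$coordinates[2L, ])^2)
  d13 <- sum((p$coordinates[1L, ] - p$coordinates[3L, ])^2)
  expect_equal(d12, 4, tolerance = 1e-10)
  expect_equal(d13, 4, tolerance = 1e-10)
  # round trip on a Euclidean point set
  set.seed(77)
  pts <- matrix(rnorm(5 * 3), 5, 3)
  D2 <- as.matrix(stats::dist(pts))^2
  p <- ssr_pcoa(D2)
  rec <- as.matrix(stats::dist(p$coordinates))^2
  expect_equal(rec, D2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(p$pct_variation), 100, tolerance = 1e-9)
  # independent oracle: ape::pcoa on the unsquared distances
  ap <- ape::pcoa(stats::dist(pts))
  k <- length(p$pct_variation)
  expect_equal(p$eigenvalues[seq_len(k)], ap$values$Eigenvalues[seq_len(k)],
               tolerance = 1e-8)
  expect_equal(abs(p$coordinates), abs(ap$vectors[, seq_len(k)]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # two identical entities -> coincident coordinates
  M <- as.matrix(stats::dist(rbind(c(0, 0), c(0, 0), c(3, 4), c(6, 8))))^2
  p <- ssr_pcoa(M)
  expect_equal(p$coordinates[1L, ], p$coordinates[2L, ], tolerance = 1e-10)
})

# Independent AMOVA oracle for scalar data: with d2(i,j) = (x_i - x_j)^2,
# the distance-AMOVA sums of squares equal classical one-way ANOVA sums of
# squares, so variance components follow from textbook mean squares.
anova_phi_oracle <- function(x, g) {
  N <- length(x); tab <- table(g); G <- length(tab)
  grand <- mean(x)
  ss_within <- sum(unlist(lapply(split(x, g), function(v) sum((v - mean(v))^2))))
  ss_among <- sum(tab * (vapply(split(x, g), mean, 0) - grand)^2)
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  n0 <- (N - sum(tab^2) / N) / (G - 1)
  s2a <- (ms_among - ms_within) / n0
  s2a / (s2a + ms_within)
}

test_that("PhiPT equals the scalar ANOVA oracle to 1e-10", {
  x <- c(0, 1, 2, 10, 11, 14)
  g <- c("a", "a", "a", "b", "b", "b")
  D <- outer(x, x, function(a, b) (a - b)^2)
  res <- phipt(D, g, n_perm = 99L, seed = 1L)
  expect_equal(res$phi_pt, anova_phi_oracle(x, g), tolerance = 1e-10)
  # unbalanced groups too
  g2 <- c("a", "a", "b", "b", "b", "b")
  res2 <- phipt(D, g2, n_perm = 9L, seed = 1L)
  expect_equal(res2$phi_pt, anova_phi_oracle(x, g2), tolerance = 1e-10)
})

test_that("PhiPT endpoints: null labels and perfectly separated clones", {
  # homogeneous pool with random labels: Phi ~ 0, p > 0.05
  set.seed(5)
  x <- rnorm(24)
  D <- outer(x, x, function(a, b) (a - b)^2)
  g <- rep(c("p", "q", "r"), each = 8L)[sample.int(24)]
  res <- phipt(D, g, n_perm = 999L, seed = 2L)
  expect_gt(res$p_value, 0.05)
  expect_lt(abs(res$phi_pt), 0.3)
  # two internally identical, mutually different clone groups: Phi = 1
  y <- tab_from_strings(list(L1 = c("140/140", "140/140", "150/150", "150/150")),
                        cultivar = c("A", "A", "B", "B"))
  res <- phipt(genotypic_distance(y), y$samples$cultivar, n_perm = 99L,
               seed = 3L)
  expect_equal(res$phi_pt, 1)
  # invariance under group relabeling and sample permutation
  d <- simulate_dataset(sim_config(n_loci = 5L, n_cultivars = 3L,
                                   clones_per_cultivar = 4L, n_males = 0L,
                                   rng_seed = 71L))
  D <- genotypic_distance(d$females)$matrix
  g <- d$females$samples$cultivar
  phi1 <- palmSSR:::amova_phi(D, g)$phi
  phi2 <- palmSSR:::amova_phi(D, paste0("relabel_", g))$phi
  perm <- sample.int(length(g))
  phi3 <- palmSSR:::amova_phi(D[perm, perm], g[perm])$phi
  expect_equal(phi1, phi2, tolerance = 1e-12)
  expect_equal(phi1, phi3, tolerance = 1e-12)
})

test_that("LD screen enumerates all locus pairs and calibrates under the null", {
  # 16 loci -> choose(16,2) = 120 pairs (pair enumeration only, 1 perm)
  loci <- stats::setNames(
    lapply(1:16, function(i) c("140/150", "140/140", "150/150")),
    sprintf("L%02d", 1:16))
  x <- tab_from_strings(loci)
  ld <- ld_screen(x, n_perm = 1L, seed = 1L)
  expect_identical(nrow(ld), 120L)
  # duplicated locus is maximally associated with itself: p at the floor
  d <- simulate_dataset(sim_config(n_loci = 2L, n_cultivars = 6L,
                                   clones_per_cultivar = 8L, n_males = 0L,
                                   rng_seed = 83L))
  dup <- d$females$calls$L01
  x2 <- genotype_table(d$females$samples,
                       list(A = dup, B = dup),
                       loci = list(A = d$females$loci$L01,
                                   B = d$females$loci$L01))
  ld2 <- ld_screen(x2, n_perm = 199L, seed = 4L)
  expect_equal(ld2$p_value, 1 / 200)
  # independently simulated HWE loci: few p-values below 0.05
  cfg <- sim_config(n_loci = 8L, n_cultivars = 1L, clones_per_cultivar = 40L,
                    seed_propagated = 1L, n_males = 0L, rng_seed = 97L)
  d3 <- simulate_cultivars(cfg, simulate_background(cfg))
  ld3 <- ld_screen(d3$table, n_perm = 199L, seed = 5L)
  expect_identical(nrow(ld3), 28L)
  expect_lte(mean(ld3$p_value < 0.05), 0.15)
})
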