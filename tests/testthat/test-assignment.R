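# LOD assignment: Mendelian transition probabilities, scalar LOD anchors,
# additivity, delta calibration determinism, and end-to-end assignment on
# synthetic males.

test_that("transition_prob covers the Mendelian cases", {
  p <- fr("140" = 0.7, "150" = 0.3)
  # parent AA, offspring AB: single compatible gamete path -> p_B
  expect_equal(transition_prob(c(140L, 140L), c(140L, 150L), p), 0.3)
  # parent AB, offspring AB: 0.5 p_B + 0.5 p_A
  p2 <- fr("140" = 0.5, "150" = 0.5)
  expect_equal(transition_prob(c(140L, 150L), c(140L, 150L), p2), 0.5)
  # parent AA, offspring BC: incompatible
  p3 <- fr("140" = 0.2, "150" = 0.4, "160" = 0.4)
  expect_equal(transition_prob(c(140L, 140L), c(150L, 160L), p3), 0)
  # parent AB, offspring AA: 0.5 p_A
  expect_equal(transition_prob(c(140L, 150L), c(140L, 140L), p3), 0.1)
})

test_that("lod_score matches hand computation and handles mismatches", {
  freqs <- structure(list(group = "ALL", per_locus = list(
    L1 = list(p = fr("140" = 0.5, "150" = 0.5), n = 10L))),
    class = "freq_table")
  q <- list(L1 = c(140L, 150L))
  # candidate AB, query AB, e = 0: T = 0.5, P = 0.5 -> LOD = 0
  expect_equal(lod_score(q, list(L1 = c(140L, 150L)), freqs, e = 0), 0)
  # mismatch at e = 0.01: contribution ln(e) (T = 0 -> (e P)/P = e)
  freqs$per_locus$L2 <- list(p = fr("100" = 0.5, "102" = 0.5), n = 10L)
  q2 <- list(L1 = c(140L, 150L), L2 = c(100L, 100L))
  cand <- list(L1 = c(140L, 150L), L2 = c(102L, 102L))
  expect_equal(lod_score(q2, cand, freqs, e = 0.01), log(0.01))
  # e = 0 with a mismatch -> -Inf, flagged
  expect_warning(l0 <- lod_score(q2, cand, freqs, e = 0), "mismatch")
  expect_identical(l0, -Inf)
  # common-allele sharing can still give negative LOD
  freqs3 <- structure(list(group = "ALL", per_locus = list(
    L1 = list(p = fr("140" = 0.95, "150" = 0.05), n = 10L))),
    class = "freq_table")
  l <- lod_score(list(L1 = c(140L, 140L)), list(L1 = c(140L, 150L)),
                 freqs3, e = 0.01)
  expect_lt(l, 0)  # T = 0.5 * 0.95 < P = 0.9025
})

test_that("lod_score is additive over loci", {
  freqs <- structure(list(group = "ALL", per_locus = list(
    L1 = list(p = fr("140" = 0.6, "150" = 0.4), n = 10L),
    L2 = list(p = fr("100" = 0.3, "102" = 0.7), n = 10L))),
    class = "freq_table")
  q <- list(L1 = c(140L, 150L), L2 = c(100L, 102L))
  cand <- list(L1 = c(140L, 140L), L2 = c(100L, 102L))
  both <- lod_score(q, cand, freqs, e = 0.01)
  only1 <- lod_score(q["L1"], cand["L1"], freqs, e = 0.01)
  only2 <- lod_score(q["L2"], cand["L2"], freqs, e = 0.01)
  expect_equal(both, only1 + only2)
  # vectorized matrix route agrees with the scalar route
  L <- palmSSR:::lod_matrix(list(q), list(list(cultivar = "X",
                                               profile_id = "X#1",
                                               calls = cand)),
                            freqs, 0.01)
  expect_equal(L[1L, 1L], both)
})

test_that("candidate_profiles returns distinct within-cultivar profiles", {
  x <- tab_from_strings(
    list(L1 = c("140/150", "140/150", "140/160", "100/102")),
    cultivar = c("A", "A", "A", "B"))
  cands <- candidate_profiles(x)
  expect_identical(vapply(cands, `[[`, "", "cultivar"), c("A", "A", "B"))
  expect_identical(vapply(cands, `[[`, "", "profile_id"),
                   c("A#1", "A#2", "B#1"))
})

test_that("critical deltas: diagnostic candidates give strict_delta 0, clones are indistinguishable", {
  # candidates fixed for disjoint alleles at 8 loci, e = 0: essentially
  # always correct (an offspring heterozygous at every locus is the only
  # ambiguous configuration, probability 2^-8)
  per_locus <- stats::setNames(lapply(1:8, function(i)
    list(p = fr("140" = 0.5, "150" = 0.5), n = 50L)), sprintf("L%d", 1:8))
  freqs <- structure(list(group = "ALL", per_locus = per_locus),
                     class = "freq_table")
  calls_of <- function(a) stats::setNames(
    lapply(1:8, function(i) c(a, a)), sprintf("L%d", 1:8))
  cands <- list(
    list(cultivar = "A", profile_id = "A#1", calls = calls_of(140L)),
    list(cultivar = "B", profile_id = "B#1", calls = calls_of(150L)))
  cd <- simulate_critical_deltas(cands, freqs,
                                 assign_config(error_rate = 0, n_sim = 500L,
                                               seed = 6L))
  expect_identical(cd$strict_delta, 0)
  expect_gte(unname(cd$success_rate["strict"]), 0.99)
  # identical candidates: success ~ 0.5, strict level unreachable
  freqs1 <- structure(list(group = "ALL", per_locus = per_locus["L1"]),
                      class = "freq_table")
  cands2 <- list(
    list(cultivar = "A", profile_id = "A#1", calls = list(L1 = c(140L, 150L))),
    list(cultivar = "B", profile_id = "B#1", calls = list(L1 = c(140L, 150L))))
  w <- capture_warnings(
    cd2 <- simulate_critical_deltas(cands2, freqs1,
                                    assign_config(error_rate = 0,
                                                  n_sim = 500L, seed = 7L)))
  expect_true(any(grepl("unreachable", w)))
  expect_identical(cd2$strict_delta, Inf)
  # determinism: same seed, same thresholds
  cd3 <- simulate_critical_deltas(cands, freqs,
                                  assign_config(error_rate = 0, n_sim = 500L,
                                                seed = 6L))
  expect_identical(cd$strict_delta, cd3$strict_delta)
  expect_identical(cd$assignment_rate, cd3$assignment_rate)
})

test_that("synthetic males are assigned to their source cultivar", {
  cfg <- sim_config(n_loci = 10L, n_cultivars = 6L, clones_per_cultivar = 4L,
                    seed_propagated = integer(0), variant_clone_rate = 0,
                    mislabel_rate = 0, n_males = 30L, typing_error_rate = 0,
                    rng_seed = 61L)
  d <- simulate_dataset(cfg)
  freqs <- allele_frequencies(d$females, "all")[["ALL"]]
  cands <- candidate_profiles(d$females)
  res <- assign_queries(d$males, cands, freqs,
                        assign_config(error_rate = 0.01, n_sim = 1000L,
                                      seed = 8L))
  truth <- d$truth[d$truth$sample_id %in% res$assignments$query_id, ]
  m <- merge(res$assignments, truth, by.x = "query_id", by.y = "sample_id")
  strict <- m[m$confidence == "strict", ]
  expect_gt(nrow(strict), 0L)
  expect_gte(mean(strict$cultivar == strict$male_source_cultivar), 0.9)
  # deltas are non-negative and confidence respects the thresholds
  expect_true(all(res$assignments$delta >= 0))
  cd <- res$critical_deltas
  expect_true(all(res$assignments$delta[res$assignments$confidence == "strict"]
                  >= cd$strict_delta))
  expect_gte(cd$strict_delta, 0)
  expect_gte(cd$strict_delta, cd$relaxed_delta)
})

test_that("profiles of the same cultivar never penalize each other", {
  freqs <- structure(list(group = "ALL", per_locus = list(
    L1 = list(p = fr("140" = 0.25, "150" = 0.25, "160" = 0.5), n = 50L))),
    class = "freq_table")
  # two profiles of cultivar A (variant clones), one distinct B
  cands <- list(
    list(cultivar = "A", profile_id = "A#1", calls = list(L1 = c(140L, 140L))),
    list(cultivar = "A", profile_id = "A#2", calls = list(L1 = c(140L, 150L))),
    list(cultivar = "B", profile_id = "B#1", calls = list(L1 = c(160L, 160L))))
  q <- tab_from_strings(list(L1 = "140/140"), cultivar = "UNKNOWN",
                        sex = "male", ids = "Q1",
                        registry = list(L1 = c(140L, 150L, 160L)))
  res <- assign_queries(q, cands, freqs,
                        assign_config(error_rate = 0.01, n_sim = 200L,
                                      seed = 9L))
  a <- res$assignments
  expect_identical(a$cultivar, "A")
  # delta is computed against B (the best other cultivar), not against A#2
  lods <- res$lod_matrix[1L, ]
  expect_equal(a$delta, max(lods[1:2]) - lods[3L])
})
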