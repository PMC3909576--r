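# Generator contracts: determinism, allele-count ranges, clonal structure,
# HWE behaviour of the seed-propagated path, and Mendelian male construction.

test_that("generation is a pure function of the config (determinism)", {
  cfg <- sim_config(n_loci = 6L, n_cultivars = 4L, clones_per_cultivar = 5L,
                    n_males = 6L, rng_seed = 123L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table$calls, b$table$calls)
  expect_identical(a$truth, b$truth)
})

test_that("background respects allele-count range and concentration limit", {
  cfg <- sim_config(n_loci = 16L, alleles_per_locus = c(4L, 11L),
                    rng_seed = 2L)
  bg <- simulate_background(cfg)
  k <- vapply(bg$per_locus, function(l) length(l$p), 1L)
  expect_length(k, 16L)
  expect_true(all(k >= 4L & k <= 11L))
  # near-infinite concentration -> equifrequent alleles
  cfg2 <- sim_config(n_loci = 3L, alleles_per_locus = c(2L, 2L),
                     freq_concentration = 1e6, rng_seed = 3L)
  bg2 <- simulate_background(cfg2)
  for (l in bg2$per_locus)
    expect_true(all(abs(l$p - 0.5) < 0.01))
})

test_that("pure-clone cultivars are identical and fully heterozygous", {
  cfg <- sim_config(n_loci = 8L, n_cultivars = 5L, clones_per_cultivar = 6L,
                    founder_het_prob = 1, variant_clone_rate = 0,
                    mislabel_rate = 0, seed_propagated = integer(0),
                    n_males = 0L, rng_seed = 17L)
  d <- simulate_cultivars(cfg, simulate_background(cfg))
  expect_true(all(d$truth$propagation == "clone"))
  for (cv in unique(d$table$samples$cultivar)) {
    idx <- d$table$samples$cultivar == cv
    for (loc in names(d$table$calls)) {
      m <- d$table$calls[[loc]][idx, , drop = FALSE]
      expect_true(all(m[, 1L] == m[1L, 1L] & m[, 2L] == m[1L, 2L]))
      expect_true(m[1L, 1L] != m[1L, 2L])  # forced heterozygous
    }
  }
})

test_that("clones_per_cultivar = 1 yields founders only", {
  cfg <- sim_config(n_loci = 4L, n_cultivars = 6L, clones_per_cultivar = 1L,
                    seed_propagated = integer(0), n_males = 0L, rng_seed = 4L)
  d <- simulate_cultivars(cfg, simulate_background(cfg))
  expect_identical(n_samples(d$table), 6L)
  expect_true(all(table(d$table$samples$cultivar) == 1L))
})

test_that("variant clones differ by one ladder step at one locus", {
  cfg <- sim_config(n_loci = 6L, n_cultivars = 3L, clones_per_cultivar = 30L,
                    founder_het_prob = 1, variant_clone_rate = 0.5,
                    mislabel_rate = 0, seed_propagated = integer(0),
                    n_males = 0L, rng_seed = 21L)
  d <- simulate_cultivars(cfg, simulate_background(cfg))
  variants <- d$truth$sample_id[d$truth$propagation == "variant_clone"]
  expect_gt(length(variants), 0L)
  for (v in variants) {
    cv <- d$truth$true_cultivar[d$truth$sample_id == v]
    founder <- d$founders[[cv]]
    i <- match(v, d$table$samples$sample_id)
    diffs <- 0L
    for (loc in names(d$table$calls)) {
      g <- d$table$calls[[loc]][i, ]
      f <- sort(founder[[loc]])
      if (!identical(as.integer(g), as.integer(f))) diffs <- diffs + 1L
    }
    expect_lte(diffs, 1L)  # exactly one locus touched (may mutate onto itself)
  }
})

test_that("seed-propagated cultivar has F near 0 at n = 200", {
  cfg <- sim_config(n_loci = 16L, n_cultivars = 2L,
                    clones_per_cultivar = 200L, seed_propagated = 1L,
                    variant_clone_rate = 0, mislabel_rate = 0,
                    n_males = 0L, rng_seed = 31L)
  d <- simulate_cultivars(cfg, simulate_background(cfg))
  gs <- group_summary(locus_table(d$table, "cultivar"), d$table)
  f_seed <- gs$F[gs$group == "CV01"]
  expect_lt(abs(f_seed), 0.1)
  # the clonal sibling cultivar stays at F = -1 where heterozygous
  expect_lt(gs$F[gs$group == "CV02"], -0.9)
})

test_that("males are Mendelian offspring of their source founder", {
  cfg <- sim_config(n_loci = 8L, n_cultivars = 4L, clones_per_cultivar = 3L,
                    seed_propagated = integer(0), n_males = 25L,
                    typing_error_rate = 0, rng_seed = 41L)
  bg <- simulate_background(cfg)
  cv <- simulate_cultivars(cfg, bg)
  ml <- simulate_males(cfg, cv, bg)
  expect_identical(n_samples(ml$table), 25L)
  for (i in seq_len(25L)) {
    src <- ml$truth$male_source_cultivar[i]
    founder <- cv$founders[[src]]
    for (loc in names(ml$table$calls)) {
      g <- ml$table$calls[[loc]][i, ]
      expect_true(any(g %in% founder[[loc]]))  # shares >= 1 allele per locus
    }
  }
  # n_males = 0 -> empty result
  cfg0 <- sim_config(n_loci = 4L, n_cultivars = 2L, n_males = 0L,
                     seed_propagated = integer(0), rng_seed = 1L)
  bg0 <- simulate_background(cfg0)
  ml0 <- simulate_males(cfg0, simulate_cultivars(cfg0, bg0), bg0)
  expect_null(ml0$table)
  expect_identical(nrow(ml0$truth), 0L)
})

test_that("typing_error_rate = 1 destroys parent-offspring signal", {
  cfg <- sim_config(n_loci = 8L, n_cultivars = 6L, clones_per_cultivar = 3L,
                    seed_propagated = integer(0), n_males = 60L,
                    typing_error_rate = 1, rng_seed = 51L)
  bg <- simulate_background(cfg)
  cv <- simulate_cultivars(cfg, bg)
  ml <- simulate_males(cfg, cv, bg)
  # with every call replaced by a random HWE draw, sharing an allele with
  # the source founder at every locus becomes vanishingly rare
  all_share <- vapply(seq_len(60L), function(i) {
    src <- ml$truth$male_source_cultivar[i]
    all(vapply(names(ml$table$calls), function(loc)
      any(ml$table$calls[[loc]][i, ] %in% cv$founders[[src]][[loc]]), TRUE))
  }, TRUE)
  expect_lt(mean(all_share), 0.5)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(variant_clone_rate = 1.5), "probabilities")
  expect_error(sim_config(alleles_per_locus = c(1L, 5L)), "alleles_per_locus")
  expect_error(sim_config(seed_propagated = 99L), "out of range")
})
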