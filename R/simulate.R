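# Seeded generator of synthetic SSR genotype tables that emulate clonally
# propagated cultivar collections: each cultivar descends from a single
# (usually highly heterozygous) seed founder and is multiplied by offshoots,
# with occasional variant clones (one-step SSR ladder mutations), occasional
# mislabelled clones, one or more traditionally seed-propagated cultivars,
# and male trees that are open-pollinated seed offspring of a cultivar
# founder with the paternal gamete drawn from the oasis-wide allele pool.

#' Configuration for the synthetic cultivar generator
#'
#' Defaults reflect a mid-sized oasis collection: 16 loci carrying 4-11
#' alleles each, 18 cultivars sampled 7-39 trees deep (~21 on average),
#' one seed-propagated cultivar (index 1), founders forced heterozygous at
#' 50% of loci (which, adding the chance heterozygosity of free draws,
#' leaves founders heterozygous at roughly 80-85% of loci -- the
#' polymorphic-locus percentage typical of clonal date-palm cultivar
#' panels), rare variant clones and mislabellings, 63 male trees, and a 1%
#' per-locus typing error applied to males.
#'
#' @param n_loci number of SSR loci
#' @param alleles_per_locus length-2 integer range of allele counts per locus
#' @param freq_concentration Dirichlet concentration for background allele
#'   frequencies (1 = uniform simplex)
#' @param n_cultivars number of cultivars
#' @param clones_per_cultivar single count or length-2 range of trees sampled
#'   per cultivar (the founder genotype is always member 1)
#' @param founder_het_prob probability a founder locus is forced heterozygous
#' @param seed_propagated integer vector of cultivar indices propagated by
#'   seed rather than clonally (each member an independent HWE draw from a
#'   50/50 founder/background allele pool)
#' @param variant_clone_rate probability a clonal member carries one
#'   one-step ladder mutation
#' @param mislabel_rate probability a clonal member is in fact a clone of a
#'   different cultivar's founder
#' @param n_males number of male trees (seed offspring of a uniformly chosen
#'   cultivar founder x background pollen)
#' @param typing_error_rate probability a male's locus call is replaced by a
#'   random HWE genotype from the background
#' @param rng_seed integer seed; all generation is a pure function of the
#'   config
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_loci = 16L,
                       alleles_per_locus = c(4L, 11L),
                       freq_concentration = 1,
                       n_cultivars = 18L,
                       clones_per_cultivar = c(7L, 39L),
                       founder_het_prob = 0.5,
                       seed_propagated = 1L,
                       variant_clone_rate = 0.02,
                       mislabel_rate = 0.01,
                       n_males = 63L,
                       typing_error_rate = 0.01,
                       rng_seed = 1L) {
  if (length(alleles_per_locus) == 1L)
    alleles_per_locus <- rep(alleles_per_locus, 2L)
  if (length(clones_per_cultivar) == 1L)
    clones_per_cultivar <- rep(clones_per_cultivar, 2L)
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              freq_concentration = freq_concentration,
              n_cultivars = as.integer(n_cultivars),
              clones_per_cultivar = as.integer(clones_per_cultivar),
              founder_het_prob = founder_het_prob,
              seed_propagated = as.integer(seed_propagated),
              variant_clone_rate = variant_clone_rate,
              mislabel_rate = mislabel_rate,
              n_males = as.integer(n_males),
              typing_error_rate = typing_error_rate,
              rng_seed = as.integer(rng_seed))
  probs <- c(founder_het_prob = founder_het_prob,
             variant_clone_rate = variant_clone_rate,
             mislabel_rate = mislabel_rate,
             typing_error_rate = typing_error_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_loci < 1L || cfg$n_cultivars < 1L || cfg$n_males < 0L)
    stop("counts must be positive (n_males may be 0)")
  if (cfg$alleles_per_locus[1L] < 2L || cfg$alleles_per_locus[2L] > 40L ||
      diff(cfg$alleles_per_locus) < 0L)
    stop("alleles_per_locus must be an increasing range within [2, 40]")
  if (any(cfg$seed_propagated < 1L | cfg$seed_propagated > cfg$n_cultivars))
    stop("seed_propagated indices out of range")
  structure(cfg, class = "sim_config")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Simulate the oasis-wide background allele pool
#'
#' Draws, for each locus, a distinct-integer allele ladder (2-bp dinucleotide
#' steps from a random 100-300 bp start) and Dirichlet-distributed
#' frequencies.
#'
#' @param config a [sim_config()]
#' @return a `freq_table` (group `"BACKGROUND"`), reproducible from
#'   `config$rng_seed`
#' @export
simulate_background <- function(config) {
  with_seed(derive_seed(config$rng_seed, "background"), {
    per_locus <- list()
    for (l in seq_len(config$n_loci)) {
      k <- resample(seq(config$alleles_per_locus[1L],
                        config$alleles_per_locus[2L]))
      start <- resample(100:300)
      sizes <- start + 2L * (seq_len(k) - 1L)
      p <- rdirichlet1(k, config$freq_concentration)
      per_locus[[sprintf("L%02d", l)]] <-
        list(p = stats::setNames(p, sizes), n = NA_integer_)
    }
    structure(list(group = "BACKGROUND", per_locus = per_locus),
              class = "freq_table")
  })
}

# sample() safe against the length-1 "sample from 1:x" pitfall
resample <- function(x, size = 1L, replace = FALSE, prob = NULL)
  x[sample.int(length(x), size, replace = replace, prob = prob)]

draw_genotype <- function(p_named) {
  sort(resample(as.integer(names(p_named)), 2L, replace = TRUE,
                prob = p_named))
}

#' Simulate clonal cultivars from single founders
#'
#' Each cultivar gets one founder genotype (two background draws per locus,
#' redrawn until heterozygous with probability `founder_het_prob`). Clonal
#' members copy the founder exactly, except: with probability
#' `mislabel_rate` a member is a clone of another cultivar's founder, and
#' otherwise with probability `variant_clone_rate` it carries a single
#' one-step ladder mutation at one random locus. Members of seed-propagated
#' cultivars are independent HWE draws from a 50/50 mixture of the founder's
#' alleles and the background pool. Member 1 of every cultivar is always the
#' founder itself.
#'
#' @param config a [sim_config()]
#' @param background a `freq_table` from [simulate_background()]
#' @return list with `table` (a [genotype_table()] of female trees) and
#'   `truth` (data.frame: `sample_id`, `true_cultivar`, `propagation` in
#'   clone/variant_clone/mislabeled/seed, `male_source_cultivar` = NA)
#' @export
simulate_cultivars <- function(config, background) {
  locs <- names(background$per_locus)
  with_seed(derive_seed(config$rng_seed, "cultivars"), {
    # founders: distinct multilocus genotypes (retry on collision)
    founders <- list()
    key_of <- function(g) paste(unlist(g), collapse = "|")
    seen <- character(0)
    for (cv in seq_len(config$n_cultivars)) {
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        g <- lapply(locs, function(loc) {
          p <- background$per_locus[[loc]]$p
          force_het <- stats::runif(1) < config$founder_het_prob &&
            length(p) >= 2L
          geno <- draw_genotype(p)
          if (force_het) {
            tries <- 0L
            while (geno[1L] == geno[2L] && tries < 1000L) {
              geno <- draw_genotype(p)
              tries <- tries + 1L
            }
            if (geno[1L] == geno[2L]) {
              # near-fixed locus: force the two most frequent alleles
              top <- as.integer(names(sort(p, decreasing = TRUE))[1:2])
              geno <- sort(top)
            }
          }
          geno
        })
        names(g) <- locs
        if (!(key_of(g) %in% seen)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw ", config$n_cultivars,
                    " distinct founders after 100 attempts")
      seen <- c(seen, key_of(g))
      founders[[cv]] <- g
    }

    cultivar_names <- sprintf("CV%02d", seq_len(config$n_cultivars))
    sizes <- resample(seq(config$clones_per_cultivar[1L],
                          config$clones_per_cultivar[2L]),
                      config$n_cultivars, replace = TRUE)

    samples <- list(); truth <- list()
    calls <- stats::setNames(
      lapply(locs, function(loc) matrix(NA_integer_, 0L, 2L)), locs)
    add_sample <- function(id, cultivar, genotype, propagation) {
      samples[[length(samples) + 1L]] <<- data.frame(
        sample_id = id, cultivar = cultivar,
        locality = sprintf("Site%d", 1L + (length(samples) %% 5L)),
        sex = "female", stringsAsFactors = FALSE)
      for (loc in locs)
        calls[[loc]] <<- rbind(calls[[loc]], genotype[[loc]])
      truth[[length(truth) + 1L]] <<- data.frame(
        sample_id = id, true_cultivar = cultivar, propagation = propagation,
        male_source_cultivar = NA_character_, stringsAsFactors = FALSE)
    }

    for (cv in seq_len(config$n_cultivars)) {
      cname <- cultivar_names[cv]
      founder <- founders[[cv]]
      is_seed <- cv %in% config$seed_propagated
      if (is_seed) {
        # 50/50 founder-allele / background pool per locus
        pool <- lapply(locs, function(loc) {
          p_bg <- background$per_locus[[loc]]$p
          f <- founder[[loc]]
          p_f <- table(f) / 2
          alle <- union(as.integer(names(p_bg)), f)
          p <- stats::setNames(numeric(length(alle)), alle)
          p[names(p_bg)] <- p[names(p_bg)] + 0.5 * p_bg
          p[names(p_f)] <- p[names(p_f)] + 0.5 * as.numeric(p_f)
          p
        })
        names(pool) <- locs
      }
      for (m in seq_len(sizes[cv])) {
        id <- sprintf("%s-F%03d", cname, m)
        if (is_seed) {
          g <- lapply(pool, draw_genotype)
          names(g) <- locs
          add_sample(id, cname, g, "seed")
        } else if (m == 1L) {
          add_sample(id, cname, founder, "clone")
        } else if (config$n_cultivars > 1L &&
                   stats::runif(1) < config$mislabel_rate) {
          src <- resample(setdiff(seq_len(config$n_cultivars), cv))
          add_sample(id, cname, founders[[src]], "mislabeled")
        } else if (stats::runif(1) < config$variant_clone_rate) {
          g <- founder
          loc <- resample(locs)
          ladder <- sort(unique(c(as.integer(names(background$per_locus[[loc]]$p)),
                                  g[[loc]])))
          which_allele <- sample(1:2, 1L)
          pos <- match(g[[loc]][which_allele], ladder)
          step <- if (pos == 1L) 1L else if (pos == length(ladder)) -1L else
            sample(c(-1L, 1L), 1L)
          g[[loc]][which_allele] <- ladder[pos + step]
          g[[loc]] <- sort(g[[loc]])
          add_sample(id, cname, g, "variant_clone")
        } else {
          add_sample(id, cname, founder, "clone")
        }
      }
    }

    samples <- do.call(rbind, samples)
    truth <- do.call(rbind, truth)
    # register the full background ladder plus any mutation-extended alleles
    loci <- stats::setNames(lapply(locs, function(loc)
      sort(unique(c(as.integer(names(background$per_locus[[loc]]$p)),
                    as.integer(calls[[loc]]))))), locs)
    list(table = genotype_table(samples, calls, loci = loci), truth = truth,
         founders = stats::setNames(founders, cultivar_names))
  })
}

#' Simulate male trees as seed offspring of cultivar founders
#'
#' Each male receives one gamete from a uniformly chosen cultivar founder
#' and one from the background pool (open pollination), then a per-locus
#' typing error at `typing_error_rate` replaces the call with a random HWE
#' background genotype.
#'
#' @param config a [sim_config()]
#' @param cultivars result of [simulate_cultivars()]
#' @param background the matching background `freq_table`
#' @return list with `table` (a [genotype_table()] of males) and `truth`
#'   (`male_source_cultivar` filled in)
#' @export
simulate_males <- function(config, cultivars, background) {
  locs <- names(background$per_locus)
  founders <- cultivars$founders
  with_seed(derive_seed(config$rng_seed, "males"), {
    samples <- list(); truth <- list()
    calls <- stats::setNames(
      lapply(locs, function(loc)
        matrix(NA_integer_, config$n_males, 2L)), locs)
    if (config$n_males > 0L) for (i in seq_len(config$n_males)) {
      src <- resample(seq_along(founders))
      for (loc in locs) {
        maternal <- resample(founders[[src]][[loc]])
        p <- background$per_locus[[loc]]$p
        paternal <- resample(as.integer(names(p)), prob = p)
        g <- sort(c(maternal, paternal))
        if (stats::runif(1) < config$typing_error_rate)
          g <- draw_genotype(p)
        calls[[loc]][i, ] <- g
      }
      samples[[i]] <- data.frame(
        sample_id = sprintf("M%03d", i), cultivar = "UNKNOWN",
        locality = sprintf("Site%d", 1L + (i %% 5L)), sex = "male",
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        sample_id = sprintf("M%03d", i), true_cultivar = NA_character_,
        propagation = "seed",
        male_source_cultivar = names(founders)[src],
        stringsAsFactors = FALSE)
    }
    if (config$n_males == 0L)
      return(list(table = NULL,
                  truth = data.frame(sample_id = character(),
                                     true_cultivar = character(),
                                     propagation = character(),
                                     male_source_cultivar = character(),
                                     stringsAsFactors = FALSE)))
    samples <- do.call(rbind, samples)
    loci <- stats::setNames(lapply(locs, function(loc)
      sort(unique(c(cultivars$table$loci[[loc]],
                    as.integer(calls[[loc]]))))), locs)
    list(table = genotype_table(samples, calls, loci = loci),
         truth = do.call(rbind, truth))
  })
}

#' One-call synthetic dataset
#'
#' Runs [simulate_background()], [simulate_cultivars()] and
#' [simulate_males()] and combines females and males into one table over a
#' shared locus registry.
#'
#' @param config a [sim_config()]
#' @return list with `table` (females + males), `females`, `males`,
#'   `background`, `truth`, `founders`
#' @export
simulate_dataset <- function(config) {
  bg <- simulate_background(config)
  cv <- simulate_cultivars(config, bg)
  ml <- simulate_males(config, cv, bg)
  tab <- if (is.null(ml$table)) cv$table else {
    # align registries before binding
    loci <- stats::setNames(lapply(names(cv$table$loci), function(l)
      sort(union(cv$table$loci[[l]], ml$table$loci[[l]]))),
      names(cv$table$loci))
    bind_samples(
      genotype_table(cv$table$samples, cv$table$calls, loci = loci),
      genotype_table(ml$table$samples, ml$table$calls, loci = loci))
  }
  list(table = tab, females = cv$table, males = ml$table,
       background = bg, truth = rbind(cv$truth, ml$truth),
       founders = cv$founders)
}
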