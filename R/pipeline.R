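# One-command end-to-end run: validate -> diversity -> distance/PCoA/PhiPT
# -> LD screen -> identification key -> male assignment, with a deterministic
# report bundle and a run manifest. Also the entry point behind the
# command-line wrapper in exec/.

#' Pipeline run configuration
#'
#' @param input path to a genotype CSV, or `NULL` to simulate input
#' @param dialect input dialect, `"tidy"` or `"genalex"`
#' @param simulate a [sim_config()] used when `input` is `NULL`
#' @param out_dir output directory (created; must be empty unless `force`)
#' @param seed master seed propagated (via stable derivation) to every
#'   stochastic stage
#' @param stages character vector of stages to run, a subset of
#'   `c("validate", "diversity", "distance", "pcoa", "phipt", "ld", "key",
#'   "assign")`
#' @param group_by grouping for diversity/PhiPT (`"cultivar"` or
#'   `"locality"`)
#' @param n_perm permutations for PhiPT and the LD screen
#' @param key_max_size largest key size searched
#' @param key_loci optional forced key locus subset
#' @param assignment an [assign_config()]; its seed is overridden by `seed`
#' @param force overwrite a non-empty `out_dir`
#' @return list of class `run_config`
#' @export
run_config <- function(input = NULL, dialect = "tidy", simulate = sim_config(),
                       out_dir, seed = 1L,
                       stages = c("validate", "diversity", "distance", "pcoa",
                                  "phipt", "ld", "key", "assign"),
                       group_by = "cultivar", n_perm = 999L,
                       key_max_size = 4L, key_loci = NULL,
                       assignment = assign_config(), force = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("validate", "diversity", "distance", "pcoa",
                                  "phipt", "ld", "key", "assign"))
  structure(list(input = input, dialect = dialect, simulate = simulate,
                 out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 group_by = group_by, n_perm = as.integer(n_perm),
                 key_max_size = as.integer(key_max_size), key_loci = key_loci,
                 assignment = assignment, force = force),
            class = "run_config")
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a genotype table, then runs the requested stages and
#' writes one artifact per stage plus `manifest.json` (package version,
#' seed, input checksum, stage timings). A stage failure aborts the run,
#' removes the partial outputs, and rethrows with the stage name.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the in-memory stage results and the paths
#'   written
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0L && !config$force)
    stop("output directory not empty (use force = TRUE): ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  results <- list()
  timings <- list()
  emit <- function(path) written <<- c(written, path)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  # --- input ---------------------------------------------------------------
  males <- NULL
  truth <- NULL
  if (!is.null(config$input)) {
    tab <- stage("read", read_genotypes(config$input, config$dialect))
    females <- subset_samples(tab, tab$samples$sex != "male")
    if (any(tab$samples$sex == "male"))
      males <- subset_samples(tab, tab$samples$sex == "male")
    checksum <- unname(tools::md5sum(config$input))
  } else {
    sim <- stage("simulate", {
      sc <- config$simulate
      sc$rng_seed <- derive_seed(config$seed, "simulate")
      simulate_dataset(sc)
    })
    tab <- sim$table
    females <- sim$females
    males <- sim$males
    truth <- sim$truth
    p <- file.path(out, "simulated_genotypes.csv")
    write_genotypes(tab, p, "tidy"); emit(p)
    p <- file.path(out, "simulated_truth.csv")
    utils::write.csv(truth, p, row.names = FALSE); emit(p)
    checksum <- "simulated"
  }
  results$table <- tab

  run_stage <- function(s) s %in% config$stages

  if (run_stage("validate")) {
    v <- stage("validate", validate_genotypes(females))
    if (any(v$severity == "error"))
      stage("validate", stop(sum(v$severity == "error"), " validation errors"))
    p <- file.path(out, "validation.tsv"); write_tsv(v, p); emit(p)
    results$validation <- v
  }

  if (run_stage("diversity")) {
    d <- stage("diversity", {
      lt <- locus_table(females, config$group_by)
      list(locus = lt, groups = group_summary(lt, females),
           summary = locus_summary(females), fixed = fixed_alleles(females))
    })
    for (nm in c("locus", "groups", "summary", "fixed")) {
      p <- file.path(out, paste0("diversity_", nm, ".tsv"))
      write_tsv(d[[nm]], p); emit(p)
    }
    results$diversity <- d
  }

  dist <- NULL
  if (any(vapply(c("distance", "pcoa", "phipt"), run_stage, TRUE))) {
    dist <- stage("distance", genotypic_distance(females))
  }
  if (run_stage("distance")) {
    cvd <- stage("distance", cultivar_matrix(dist, females$samples$cultivar))
    p <- file.path(out, "distance_individual.csv")
    m <- dist$matrix; dimnames(m) <- list(dist$ids, dist$ids)
    utils::write.csv(m, p); emit(p)
    p <- file.path(out, "distance_cultivar.csv")
    utils::write.csv(cvd$matrix, p); emit(p)
    results$distance <- dist; results$cultivar_distance <- cvd
  }

  if (run_stage("pcoa")) {
    pc <- stage("pcoa", {
      cvd <- results$cultivar_distance %||%
        cultivar_matrix(dist, females$samples$cultivar)
      ssr_pcoa(cvd)
    })
    co <- data.frame(entity = pc$ids, pc$coordinates, check.names = FALSE)
    p <- file.path(out, "pcoa_coordinates.csv")
    utils::write.csv(co, p, row.names = FALSE); emit(p)
    p <- file.path(out, "pcoa_eigen.csv")
    utils::write.csv(data.frame(axis = seq_along(pc$pct_variation),
                                pct_variation = pc$pct_variation,
                                cumulative_pct = pc$cumulative_pct),
                     p, row.names = FALSE); emit(p)
    results$pcoa <- pc
  }

  if (run_stage("phipt")) {
    ph <- stage("phipt", phipt(dist, females$samples$cultivar,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "phipt")))
    p <- file.path(out, "phipt.json")
    jsonlite::write_json(list(phi_pt = ph$phi_pt, p_value = ph$p_value,
                              n_permutations = ph$n_permutations),
                         p, auto_unbox = TRUE, digits = NA); emit(p)
    results$phipt <- ph
  }

  if (run_stage("ld")) {
    ld <- stage("ld", ld_screen(females, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, "ld")))
    p <- file.path(out, "ld_pairs.tsv"); write_tsv(ld, p); emit(p)
    results$ld <- ld
  }

  if (run_stage("key")) {
    key <- stage("key", {
      if (!is.null(config$key_loci)) build_key(females, config$key_loci)
      else find_key(females, max_size = config$key_max_size)
    })
    p <- file.path(out, "identification_key.tsv")
    writeLines(render_key(key), p); emit(p)
    p <- file.path(out, "key_certificate.json")
    jsonlite::write_json(list(loci = key$loci, unique = key$unique,
                              total_alleles = key$total_alleles),
                         p, auto_unbox = TRUE); emit(p)
    results$key <- key
  }

  if (run_stage("assign") && !is.null(males) && n_samples(males) > 0L) {
    asg <- stage("assign", {
      freqs <- allele_frequencies(females, "all")[["ALL"]]
      cands <- candidate_profiles(females)
      ac <- config$assignment
      ac$seed <- derive_seed(config$seed, "assign")
      assign_queries(males, cands, freqs, ac)
    })
    p <- file.path(out, "assignments.tsv")
    write_tsv(asg$assignments, p); emit(p)
    p <- file.path(out, "critical_deltas.json")
    jsonlite::write_json(list(strict_delta = asg$critical_deltas$strict_delta,
                              relaxed_delta = asg$critical_deltas$relaxed_delta,
                              n_sim = asg$critical_deltas$n_sim),
                         p, auto_unbox = TRUE, digits = NA); emit(p)
    results$assignment <- asg
  }

  manifest <- list(
    package = "palmSSR",
    version = as.character(utils::packageVersion("palmSSR")),
    seed = config$seed,
    input = config$input %||% "simulated",
    input_md5 = checksum,
    stages = config$stages,
    n_samples = n_samples(tab), n_loci = n_loci(tab),
    timings_sec = timings,
    timestamp = format(Sys.time(), tz = "UTC"))
  p <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE); emit(p)

  invisible(list(results = results, paths = written))
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/palmssr` script. Subcommands: `simulate`,
#' `validate`, `diversity`, `distance`, `pcoa`, `phipt`, `ld`, `key`,
#' `assign`, `run`. Options are `--key value` pairs; common ones are
#' `--input`, `--dialect`, `--out`, `--seed`, `--n-perm`, `--force`.
#'
#' @param args character vector of command-line arguments
#' @return integer exit code: 0 ok, 1 usage error, 2 data error, 3 internal
#' @export
palmssr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: palmssr <simulate|validate|diversity|distance|pcoa|phipt|ld|key|assign|run>",
    "  --out DIR [--input FILE] [--dialect tidy|genalex] [--seed N]",
    "  [--n-perm N] [--key-max-size N] [--error-rate X] [--n-sim N] [--force]",
    sep = "\n")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    message(usage); return(1L)
  }
  cmd <- args[1L]
  all_stages <- c("validate", "diversity", "distance", "pcoa", "phipt", "ld",
                  "key", "assign")
  if (!cmd %in% c(all_stages, "simulate", "run")) {
    message("unknown subcommand: ", cmd, "\n", usage); return(1L)
  }
  opts <- list(); i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) { message("unexpected argument: ", a); return(1L) }
    key <- gsub("-", "_", substring(a, 3L))
    if (key == "force") { opts$force <- TRUE; i <- i + 1L; next }
    if (i == length(args)) { message("missing value for ", a); return(1L) }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$out)) { message("--out is required\n", usage); return(1L) }

  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  seed <- as.integer(num(opts$seed, 1))
  stages <- if (cmd == "run") all_stages
  else if (cmd == "simulate") character(0)
  else cmd
  cfg <- tryCatch(
    run_config(
      input = opts$input, dialect = opts$dialect %||% "tidy",
      simulate = sim_config(rng_seed = seed),
      out_dir = opts$out, seed = seed,
      stages = if (length(stages)) stages else "validate",
      n_perm = as.integer(num(opts$n_perm, 999)),
      key_max_size = as.integer(num(opts$key_max_size, 4)),
      assignment = assign_config(error_rate = num(opts$error_rate, 0.01),
                                 n_sim = as.integer(num(opts$n_sim, 10000)),
                                 seed = seed),
      force = isTRUE(opts$force)),
    error = function(e) { message("usage error: ", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(1L)
  if (cmd == "simulate") cfg$stages <- character(0)

  res <- tryCatch(run_pipeline(cfg), error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    message("error: ", msg)
    return(if (grepl("stage '(read|validate)'", msg)) 2L else 3L)
  }
  message("wrote ", length(res$paths), " artifact(s) to ", cfg$out_dir)
  0L
}
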