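# Readers and writers for the two supported table dialects.
#
# tidy:    sample_id,cultivar,locality,sex,<locus>_1,<locus>_2,...
#          missing call = empty pair of cells
# genalex: codominant GenAlEx CSV layout --
#          row 1: n_loci, n_samples, n_pops, <pop sizes...>
#          row 2: title, , , <pop names...>
#          row 3: sample_id, pop, <locus name + blank per locus>
#          data:  sample, pop, allele_a, allele_b, ...   (missing = 0)
#          Only sample id, population (stored as cultivar) and calls survive
#          a genalex round trip; locality and sex are not part of the layout.

#' Read a codominant genotype table
#'
#' @param path file path of a CSV in the declared dialect
#' @param dialect `"tidy"` or `"genalex"`
#' @return a [genotype_table()]
#' @export
read_genotypes <- function(path, dialect = c("tidy", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tidy") read_genotypes_tidy(path) else read_genotypes_genalex(path)
}

read_genotypes_tidy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  meta_cols <- c("sample_id", "cultivar", "locality", "sex")
  if (!all(meta_cols %in% names(df)))
    stop("malformed tidy header: need columns ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  allele_cols <- setdiff(names(df), meta_cols)
  if (length(allele_cols) == 0L || length(allele_cols) %% 2L != 0L)
    stop("malformed tidy header: expected <locus>_1,<locus>_2 column pairs, got ",
         length(allele_cols), " allele columns")
  stems <- sub("_[12]$", "", allele_cols)
  loci <- unique(stems)
  for (loc in loci) {
    want <- paste0(loc, c("_1", "_2"))
    if (!all(want %in% allele_cols))
      stop("malformed tidy header: locus ", loc, " lacks a _1/_2 column pair")
  }
  calls <- lapply(loci, function(loc) {
    a <- df[[paste0(loc, "_1")]]
    b <- df[[paste0(loc, "_2")]]
    parse_allele <- function(v, col) {
      v <- trimws(v)
      v[v == ""] <- NA
      bad <- !is.na(v) & is.na(suppressWarnings(as.integer(v)))
      if (any(bad))
        stop("non-integer allele size in column ", col, ", row ",
             which(bad)[1L], ": '", v[which(bad)[1L]], "'")
      as.integer(v)
    }
    cbind(parse_allele(a, paste0(loc, "_1")), parse_allele(b, paste0(loc, "_2")))
  })
  names(calls) <- loci
  genotype_table(df[meta_cols], calls)
}

read_genotypes_genalex <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4L) stop("malformed genalex file: fewer than 4 rows")
  split_csv <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]
  h1 <- split_csv(lines[1L])
  nl <- suppressWarnings(as.integer(h1[1L]))
  ns <- suppressWarnings(as.integer(h1[2L]))
  np <- suppressWarnings(as.integer(h1[3L]))
  if (any(is.na(c(nl, ns, np))))
    stop("malformed genalex header row 1: expected n_loci, n_samples, n_pops")
  pop_sizes <- suppressWarnings(as.integer(h1[4L:(3L + np)]))
  if (anyNA(pop_sizes) || sum(pop_sizes) != ns)
    stop("genalex pop sizes ", paste(pop_sizes, collapse = "+"),
         " do not sum to declared sample count ", ns)
  h2 <- split_csv(lines[2L])
  pop_names <- h2[4L:(3L + np)]
  h3 <- split_csv(lines[3L])
  locus_names <- h3[seq(3L, by = 2L, length.out = nl)]
  if (any(is.na(locus_names)) || any(locus_names == ""))
    stop("malformed genalex header row 3: missing locus names")
  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  if (length(data_lines) != ns)
    stop("genalex declared sample count ", ns, " but file has ",
         length(data_lines), " data rows")
  cells <- lapply(data_lines, split_csv)
  want_cols <- 2L + 2L * nl
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) < want_cols)
      stop("genalex data row ", i, ": expected ", want_cols, " columns, got ",
           length(cells[[i]]))
  }
  mat <- t(vapply(cells, function(v) v[seq_len(want_cols)],
                  character(want_cols)))
  sample_id <- mat[, 1L]
  pop <- mat[, 2L]
  calls <- lapply(seq_len(nl), function(j) {
    a <- mat[, 1L + 2L * j]
    b <- mat[, 2L + 2L * j]
    parse0 <- function(v, col) {
      x <- suppressWarnings(as.integer(trimws(v)))
      bad <- is.na(x)
      if (any(bad))
        stop("non-integer allele size at genalex data row ", which(bad)[1L],
             ", locus ", locus_names[j])
      x[x == 0L] <- NA_integer_  # 0 encodes missing
      x
    }
    cbind(parse0(a), parse0(b))
  })
  names(calls) <- locus_names
  genotype_table(
    data.frame(sample_id = sample_id, cultivar = pop,
               locality = NA_character_, sex = NA_character_,
               stringsAsFactors = FALSE),
    calls)
}

#' Write a codominant genotype table
#'
#' Writers emit UTF-8, comma-separated files with deterministic column order;
#' `write_genotypes()` followed by [read_genotypes()] in the same dialect
#' round-trips the table (for `genalex`, locality and sex are not stored).
#'
#' @param x a [genotype_table()]
#' @param path output file path
#' @param dialect `"tidy"` or `"genalex"`
#' @param title dataset title placed in the genalex second header row
#' @return `path`, invisibly
#' @export
write_genotypes <- function(x, path, dialect = c("tidy", "genalex"),
                            title = "palmSSR export") {
  dialect <- match.arg(dialect)
  if (dialect == "tidy") {
    df <- x$samples
    for (loc in names(x$calls)) {
      df[[paste0(loc, "_1")]] <- x$calls[[loc]][, 1L]
      df[[paste0(loc, "_2")]] <- x$calls[[loc]][, 2L]
    }
    utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    # genalex groups rows by population (cultivar), in first-appearance order
    pops <- unique(x$samples$cultivar)
    ord <- order(match(x$samples$cultivar, pops))
    pop_sizes <- as.integer(table(factor(x$samples$cultivar, levels = pops)))
    nl <- n_loci(x)
    ns <- n_samples(x)
    h1 <- c(nl, ns, length(pops), pop_sizes)
    h2 <- c(title, "", "", pops)
    h3 <- c("sample_id", "pop",
            as.vector(rbind(names(x$loci), rep("", nl))))
    body <- vapply(ord, function(i) {
      alleles <- unlist(lapply(x$calls, function(m) {
        v <- m[i, ]
        v[is.na(v)] <- 0L
        v
      }), use.names = FALSE)
      paste(c(x$samples$sample_id[i], x$samples$cultivar[i], alleles),
            collapse = ",")
    }, character(1L))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(paste(h1, collapse = ","), paste(h2, collapse = ","),
                 paste(h3, collapse = ","), body), con = con)
  }
  invisible(path)
}
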