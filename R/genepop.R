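#' Read a Genepop file
#'
#' Parses the community-standard Genepop format for diploid co-dominant
#' genotypes, in both the 2-digit and 3-digit allele dialects. A call of
#' `"0000"`/`"000000"` (or with either allele 0) is missing. Population
#' boundaries are taken from `Pop` lines; each population is named after its
#' last individual label (the Genepop convention) unless labels are absent.
#'
#' @param path path to a Genepop file, or a character vector of lines via
#'   `text =`.
#' @param text optional character scalar/vector with file content.
#' @return named list of [genotype_matrix()] objects, one per population.
#' @export
read_genepop <- function(path = NULL, text = NULL) {
  if (is.null(text)) lines <- readLines(path, warn = FALSE)
  else lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a Genepop file: too few lines")
  lines <- lines[-1L]  # title line
  # locus names: one per line, or a single comma-separated line
  is_pop <- function(x) grepl("^\\s*pop\\s*$", x, ignore.case = TRUE)
  first_pop <- which(vapply(lines, is_pop, TRUE))[1L]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' line")
  locus_lines <- trimws(lines[seq_len(first_pop - 1L)])
  locus_lines <- locus_lines[locus_lines != ""]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  L <- length(loci)
  body <- lines[first_pop:length(lines)]
  pops <- list(); cur <- NULL; cur_ids <- character(0)
  width <- NA_integer_
  flush <- function(pops, cur, cur_ids) {
    if (is.null(cur)) return(pops)
    name <- if (length(cur_ids)) cur_ids[length(cur_ids)] else paste0("pop", length(pops) + 1L)
    calls <- array(NA_integer_, dim = c(length(cur), L, 2L))
    for (i in seq_along(cur)) calls[i, , ] <- cur[[i]]
    pops[[name]] <- genotype_matrix(calls, individuals = make.unique(cur_ids),
                                    loci = loci, pop = name)
    pops
  }
  lineno <- first_pop + 1L  # original numbering offset (title removed)
  for (raw in body) {
    ln <- trimws(raw)
    if (is_pop(ln)) {
      pops <- flush(pops, cur, cur_ids)
      cur <- list(); cur_ids <- character(0)
      lineno <- lineno + 1L
      next
    }
    if (ln == "") { lineno <- lineno + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) { id <- ""; geno_str <- parts[1L] }
    else { id <- trimws(parts[1L]); geno_str <- paste(parts[-1L], collapse = " ") }
    toks <- strsplit(trimws(geno_str), "\\s+")[[1L]]
    toks <- toks[toks != ""]
    if (length(toks) != L)
      stop(sprintf("Genepop parse error at line %d: %d genotype fields, expected %d loci",
                   lineno + 1L, length(toks), L))
    w <- unique(nchar(toks)) / 2L
    if (length(w) != 1L || !w %in% c(2L, 3L))
      stop(sprintf("Genepop parse error at line %d: inconsistent allele field width", lineno + 1L))
    if (is.na(width)) width <- as.integer(w)
    else if (width != w)
      stop(sprintf("mixed %d- and %d-digit allele encodings within one file", 2L * width, 2L * w))
    a1 <- as.integer(substr(toks, 1L, width))
    a2 <- as.integer(substr(toks, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    cur[[length(cur) + 1L]] <- cbind(a1, a2)
    cur_ids <- c(cur_ids, if (id == "") paste0("ind", length(cur)) else id)
    lineno <- lineno + 1L
  }
  pops <- flush(pops, cur, cur_ids)
  pops
}

#' Write Genepop format
#'
#' @param pops a named list of [genotype_matrix()] objects (or a single one).
#' @param path output path; omit (or `NULL`) to return the lines invisibly.
#' @param digits allele field width per allele: 2 or 3.
#' @param title title line content.
#' @return invisibly, the character vector of lines written.
#' @export
write_genepop <- function(pops, path = NULL, digits = 3L, title = "mixmating export") {
  if (inherits(pops, "genotype_matrix")) pops <- stats::setNames(list(pops), pops$pop)
  stopifnot(digits %in% c(2L, 3L))
  loci <- pops[[1L]]$loci
  maxa <- max(unlist(lapply(pops, function(g) g$calls)), 0L, na.rm = TRUE)
  if (maxa >= 10^digits) stop("allele labels too large for ", digits, "-digit encoding")
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  out <- c(title, loci)
  for (nm in names(pops)) {
    g <- pops[[nm]]
    if (!identical(g$loci, loci)) stop("all populations must share the locus list")
    out <- c(out, "Pop")
    for (i in seq_len(n_ind(g))) {
      fields <- paste0(fmt(g$calls[i, , 1L]), fmt(g$calls[i, , 2L]))
      out <- c(out, paste0(g$individuals[i], ", ", paste(fields, collapse = " ")))
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read/write the tabular genotype CSV dialect
#'
#' Columns: `individual, population, ecotype, year`, then one column per
#' locus holding `"a/b"` calls with `"."` for missing.
#'
#' @param path file path.
#' @return named list of [genotype_matrix()] objects keyed by population.
#' @export
read_genotype_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual", "population", "ecotype", "year")
  if (!all(need %in% names(d))) stop("genotype CSV must have columns ", paste(need, collapse = ", "))
  loci <- setdiff(names(d), c(need, "lat", "lon", "platform"))
  out <- list()
  multi_year <- any(vapply(split(d$year, d$population),
                           function(y) length(unique(y)) > 1L, TRUE))
  d$.key <- if (multi_year) paste0(d$population, "_y", d$year) else d$population
  for (p in unique(d$.key)) {
    dp <- d[d$.key == p, , drop = FALSE]
    calls <- array(NA_integer_, dim = c(nrow(dp), length(loci), 2L))
    for (l in seq_along(loci)) {
      v <- as.character(dp[[loci[l]]])
      ok <- !is.na(v) & v != "." & v != ""
      ab <- matrix(NA_integer_, nrow(dp), 2L)
      if (any(ok)) {
        sp <- strsplit(v[ok], "/", fixed = TRUE)
        ab[ok, 1L] <- as.integer(vapply(sp, `[`, "", 1L))
        ab[ok, 2L] <- as.integer(vapply(sp, `[`, "", 2L))
      }
      calls[, l, ] <- ab
    }
    eco <- unique(dp$ecotype)
    if (length(eco) > 1L) stop("ecotype label must be identical within population ", p)
    out[[as.character(p)]] <- genotype_matrix(
      calls, individuals = make.unique(as.character(dp$individual)), loci = loci,
      pop = as.character(dp$population[1L]), ecotype = as.character(eco),
      year = unique(dp$year),
      lat = if ("lat" %in% names(dp)) dp$lat[1L] else NA_real_,
      lon = if ("lon" %in% names(dp)) dp$lon[1L] else NA_real_,
      platform = if ("platform" %in% names(dp)) as.character(dp$platform[1L]) else NA_character_)
  }
  out
}

#' @rdname read_genotype_csv
#' @param pops named list of `genotype_matrix` objects (or one).
#' @export
write_genotype_csv <- function(pops, path) {
  if (inherits(pops, "genotype_matrix")) pops <- list(pops)
  rows <- lapply(pops, function(g) {
    gm <- matrix(".", n_ind(g), n_loci(g))
    ok <- !is.na(g$calls[, , 1L, drop = FALSE])[, , 1L]
    dim(ok) <- dim(gm)
    gm[ok] <- paste0(g$calls[, , 1L][ok], "/", g$calls[, , 2L][ok])
    colnames(gm) <- g$loci
    cbind(data.frame(individual = g$individuals, population = g$pop,
                     ecotype = g$ecotype, year = g$year[1L],
                     stringsAsFactors = FALSE),
          as.data.frame(gm, stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the progeny-table CSV dialect
#'
#' Same as the genotype CSV plus `family` and `role` (`mother`/`progeny`)
#' columns. One optional mother row per family.
#'
#' @param path file path.
#' @return a [progeny_array_set()].
#' @export
read_progeny_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual", "population", "ecotype", "year", "family", "role")
  if (!all(need %in% names(d))) stop("progeny CSV must have columns ", paste(need, collapse = ", "))
  loci <- setdiff(names(d), c(need, "lat", "lon", "platform"))
  parse_calls <- function(dp) {
    calls <- array(NA_integer_, dim = c(nrow(dp), length(loci), 2L))
    for (l in seq_along(loci)) {
      v <- as.character(dp[[loci[l]]])
      ok <- !is.na(v) & v != "." & v != ""
      if (any(ok)) {
        sp <- strsplit(v[ok], "/", fixed = TRUE)
        calls[ok, l, 1L] <- as.integer(vapply(sp, `[`, "", 1L))
        calls[ok, l, 2L] <- as.integer(vapply(sp, `[`, "", 2L))
      }
    }
    calls
  }
  fams <- list()
  for (f in unique(d$family)) {
    df <- d[d$family == f, , drop = FALSE]
    pr <- df[df$role == "progeny", , drop = FALSE]
    mo <- df[df$role == "mother", , drop = FALSE]
    prog <- genotype_matrix(parse_calls(pr),
                            individuals = make.unique(as.character(pr$individual)),
                            loci = loci, pop = as.character(d$population[1L]),
                            ecotype = as.character(d$ecotype[1L]), year = d$year[1L])
    mother <- NULL
    if (nrow(mo) == 1L) {
      mc <- parse_calls(mo)
      mother <- rbind(mc[1L, , 1L], mc[1L, , 2L])
    }
    fams[[as.character(f)]] <- list(mother = mother, progeny = prog)
  }
  progeny_array_set(fams, loci = loci, pop = as.character(d$population[1L]),
                    ecotype = as.character(d$ecotype[1L]), year = d$year[1L])
}

#' @rdname read_progeny_csv
#' @param arr a `progeny_array_set`.
#' @export
write_progeny_csv <- function(arr, path) {
  rows <- list()
  fmt_calls <- function(calls) {
    gm <- matrix(".", dim(calls)[1L], dim(calls)[2L])
    ok <- !is.na(calls[, , 1L, drop = FALSE])[, , 1L]
    dim(ok) <- dim(gm)
    gm[ok] <- paste0(calls[, , 1L][ok], "/", calls[, , 2L][ok])
    gm
  }
  for (fn in names(arr$families)) {
    fam <- arr$families[[fn]]
    if (!is.null(fam$mother)) {
      mg <- array(fam$mother, dim = c(2L, length(arr$loci), 1L))
      mg <- aperm(mg, c(3L, 2L, 1L))
      gm <- fmt_calls(mg); colnames(gm) <- arr$loci
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(individual = paste0(fn, "_mother"), population = arr$pop,
                   ecotype = arr$ecotype, year = arr$year, family = fn,
                   role = "mother", stringsAsFactors = FALSE),
        as.data.frame(gm, stringsAsFactors = FALSE))
    }
    g <- fam$progeny
    gm <- fmt_calls(g$calls); colnames(gm) <- arr$loci
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(individual = g$individuals, population = arr$pop,
                 ecotype = arr$ecotype, year = arr$year, family = fn,
                 role = "progeny", stringsAsFactors = FALSE),
      as.data.frame(gm, stringsAsFactors = FALSE))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population metadata CSV
#'
#' Columns: `population, lat, lon, ecotype` (decimal degrees).
#' @param path file path.
#' @return a data.frame.
#' @export
read_metadata_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "lat", "lon", "ecotype")
  if (!all(need %in% names(d))) stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  d
}
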