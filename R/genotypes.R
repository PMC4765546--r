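#' Diploid multilocus genotype matrix
#'
#' Container for co-dominant diploid genotypes (microsatellite-style data):
#' one unordered allele pair per individual and locus, with a missing-data
#' mask and population-level metadata. Allele labels are opaque positive
#' integers; repeat sizes are never interpreted. A half-missing call (one
#' allele scored, the other not) is treated as fully missing, because the
#' Genepop exchange format cannot represent half-calls.
#'
#' @param calls integer array `n_ind x n_loci x 2` of allele labels
#'   (`NA` for missing; a call with any `NA` is set fully missing), or an
#'   `n_ind x (2*n_loci)` matrix with allele pairs in adjacent columns.
#' @param individuals character vector of individual IDs (default `ind_1..n`).
#' @param loci character vector of locus names (default `L1..L`).
#' @param pop population identifier.
#' @param ecotype ecotype/group label (free-form; identical within a population).
#' @param year sampling season/year tag.
#' @param lat,lon decimal-degree coordinates of the population (optional).
#' @param platform genotyping-platform tag; frequency-based analyses refuse to
#'   pool across platforms unless forced (see [pool_genotypes()]).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals = NULL, loci = NULL,
                            pop = "pop1", ecotype = NA_character_,
                            year = NA, lat = NA_real_, lon = NA_real_,
                            platform = NA_character_) {
  if (is.matrix(calls)) {
    if (ncol(calls) %% 2L != 0L) stop("matrix 'calls' must have 2 columns per locus")
    L <- ncol(calls) / 2L
    a <- array(NA_integer_, dim = c(nrow(calls), L, 2L))
    a[, , 1L] <- as.integer(calls[, 2L * seq_len(L) - 1L, drop = FALSE])
    a[, , 2L] <- as.integer(calls[, 2L * seq_len(L), drop = FALSE])
    calls <- a
  }
  stopifnot(is.array(calls), length(dim(calls)) == 3L, dim(calls)[3L] == 2L)
  storage.mode(calls) <- "integer"
  n <- dim(calls)[1L]; L <- dim(calls)[2L]
  if (is.null(individuals)) individuals <- paste0("ind_", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  stopifnot(length(individuals) == n, length(loci) == L)
  # half-missing -> fully missing
  half <- matrix(xor(is.na(calls[, , 1L]), is.na(calls[, , 2L])), n, L)
  if (any(half)) {
    idx1 <- cbind(which(half, arr.ind = TRUE), 1L)
    idx2 <- cbind(which(half, arr.ind = TRUE), 2L)
    calls[idx1] <- NA_integer_; calls[idx2] <- NA_integer_
  }
  if (any(calls <= 0L, na.rm = TRUE)) stop("allele labels must be positive integers")
  dimnames(calls) <- list(individuals, loci, NULL)
  structure(list(calls = calls, individuals = individuals, loci = loci,
                 pop = pop, ecotype = ecotype, year = year,
                 lat = lat, lon = lon, platform = platform),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (pop %s%s%s)\n",
              n_ind(x), n_loci(x), x$pop,
              if (!is.na(x$ecotype)) paste0(", ecotype ", x$ecotype) else "",
              if (!is.na(x$year[1L])) paste0(", year ", x$year[1L]) else ""))
  miss <- mean(is.na(x$calls[, , 1L]))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_ind <- function(g) dim(g$calls)[1L]

#' @rdname genotype_matrix
#' @export
n_loci <- function(g) dim(g$calls)[2L]

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i individual index (integer/logical/character).
#' @param j locus index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  calls <- x$calls[i, j, , drop = FALSE]
  genotype_matrix(calls,
                  individuals = x$individuals[seq_len(n_ind(x))[if (is.character(i)) match(i, x$individuals) else i]],
                  loci = x$loci[seq_len(n_loci(x))[if (is.character(j)) match(j, x$loci) else j]],
                  pop = x$pop, ecotype = x$ecotype, year = x$year,
                  lat = x$lat, lon = x$lon, platform = x$platform)
}

#' Per-locus allele frequencies and gene-copy counts
#'
#' Frequencies are computed over non-missing gene copies only; a genotype
#' missing at a locus removes both copies there. Loci with no data at all are
#' flagged and returned with `NULL` frequencies so downstream code can drop
#' them.
#'
#' @param g a `genotype_matrix`.
#' @return A list with `freqs` (per-locus named numeric vectors, names are
#'   allele labels), `counts` (per-locus gene-copy counts), and `empty`
#'   (character vector of all-missing loci).
#' @export
allele_freqs <- function(g) {
  L <- n_loci(g)
  freqs <- vector("list", L); counts <- integer(L)
  names(freqs) <- g$loci; names(counts) <- g$loci
  empty <- character(0)
  for (l in seq_len(L)) {
    a <- c(g$calls[, l, 1L], g$calls[, l, 2L])
    a <- a[!is.na(a)]
    counts[l] <- length(a)
    if (length(a) == 0L) {
      empty <- c(empty, g$loci[l]); freqs[l] <- list(NULL); next
    }
    tab <- table(a)
    f <- as.numeric(tab) / length(a)
    names(f) <- names(tab)
    freqs[[l]] <- f
  }
  if (length(empty)) warning("all-missing loci excluded: ", paste(empty, collapse = ", "))
  list(freqs = freqs, counts = counts, empty = empty)
}

#' Per-individual heterozygosity patterns
#'
#' Returns the only information the multilocus selfing-rate estimator
#' consumes: a 0/1 matrix indicating heterozygosity per individual and locus,
#' with missing calls propagated as `NA` (masked, never coerced to 0).
#'
#' @param g a `genotype_matrix`.
#' @return integer matrix `n_ind x n_loci` with entries 1 (heterozygous),
#'   0 (homozygous), or `NA` (missing).
#' @export
het_patterns <- function(g) {
  h <- (g$calls[, , 1L] != g$calls[, , 2L]) * 1L
  dim(h) <- dim(g$calls)[1:2]
  dimnames(h) <- list(g$individuals, g$loci)
  h
}

#' Pool genotype samples of one population
#'
#' Plain row concatenation of genotype matrices (e.g. two seasonal samples
#' pooled to estimate selfing with more precision). Samples genotyped on
#' different platforms must not be merged for frequency-based analyses
#' (allele bins differ between analyzers); pooling across distinct
#' `platform` tags is refused unless `force = TRUE`.
#'
#' @param ... `genotype_matrix` objects, or a single list of them.
#' @param force pool across differing platform tags anyway.
#' @return a `genotype_matrix` with metadata taken from the first sample.
#' @export
pool_genotypes <- function(..., force = FALSE) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1L]], "genotype_matrix")) gs <- gs[[1L]]
  stopifnot(length(gs) >= 1L, all(vapply(gs, inherits, TRUE, "genotype_matrix")))
  loci <- gs[[1L]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("locus lists differ; cannot pool")
  plats <- unique(vapply(gs, function(g) as.character(g$platform), ""))
  plats <- plats[!is.na(plats) & plats != "NA"]
  if (length(plats) > 1L && !force)
    stop("refusing to pool samples genotyped on different platforms (",
         paste(plats, collapse = " vs "), "); use force = TRUE to override")
  calls <- do.call(abind3, lapply(gs, function(g) g$calls))
  years <- unique(unlist(lapply(gs, function(g) g$year)))
  genotype_matrix(calls,
                  individuals = make.unique(unlist(lapply(gs, function(g) g$individuals))),
                  loci = loci, pop = gs[[1L]]$pop, ecotype = gs[[1L]]$ecotype,
                  year = if (length(years) == 1L) years else years,
                  lat = gs[[1L]]$lat, lon = gs[[1L]]$lon,
                  platform = gs[[1L]]$platform)
}

# bind 3-d arrays along first margin
abind3 <- function(...) {
  as <- list(...)
  n <- sum(vapply(as, function(a) dim(a)[1L], 1L))
  d <- dim(as[[1L]])
  out <- array(NA_integer_, dim = c(n, d[2L], d[3L]))
  at <- 0L
  for (a in as) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Progeny-array set
#'
#' Family-structured progeny genotypes with optional maternal genotypes, the
#' input to the correlated mixed-mating model. All families share one locus
#' list; each family holds at least one progeny.
#'
#' @param families list of families; each family is a list with elements
#'   `progeny` (a `genotype_matrix`) and optionally `mother` (a length-`2*L`
#'   integer vector of allele pairs in locus order, or a `2 x L` matrix, or
#'   `NULL` when the maternal genotype was not collected).
#' @param loci character vector of locus names.
#' @param pop,ecotype,year population metadata.
#' @return An object of class `progeny_array_set`.
#' @export
progeny_array_set <- function(families, loci = NULL, pop = "pop1",
                              ecotype = NA_character_, year = NA) {
  stopifnot(length(families) >= 1L)
  if (is.null(loci)) loci <- families[[1L]]$progeny$loci
  families <- lapply(families, function(fam) {
    stopifnot(inherits(fam$progeny, "genotype_matrix"))
    if (!identical(fam$progeny$loci, loci)) stop("all families must share the same locus list")
    if (n_ind(fam$progeny) < 1L) stop("each family needs at least one progeny")
    if (!is.null(fam$mother)) {
      m <- fam$mother
      if (is.matrix(m)) m <- as.vector(m)  # 2 x L columnwise -> a1,a2 per locus
      if (length(m) != 2L * length(loci)) stop("maternal genotype must cover the same loci")
      fam$mother <- matrix(as.integer(m), nrow = 2L)
    }
    fam
  })
  if (is.null(names(families))) names(families) <- paste0("fam_", seq_along(families))
  structure(list(families = families, loci = loci, pop = pop,
                 ecotype = ecotype, year = year),
            class = "progeny_array_set")
}

#' @export
print.progeny_array_set <- function(x, ...) {
  k <- vapply(x$families, function(f) n_ind(f$progeny), 1L)
  cat(sprintf("progeny_array_set: %d families, %d-%d progeny, %d loci (pop %s)\n",
              length(x$families), min(k), max(k), length(x$loci), x$pop))
  cat(sprintf("  maternal genotypes: %d/%d known\n",
              sum(!vapply(x$families, function(f) is.null(f$mother), TRUE)),
              length(x$families)))
  invisible(x)
}

#' Temporal sample pair
#'
#' Two genotype samples of the same population taken `generations_elapsed`
#' generations apart, the input to drift-based effective-size estimation.
#'
#' @param sample0,sample1 `genotype_matrix` objects sharing one locus list.
#' @param generations_elapsed positive integer number of generations between
#'   the two samples.
#' @return An object of class `temporal_pair`.
#' @export
temporal_pair <- function(sample0, sample1, generations_elapsed = 1L) {
  stopifnot(inherits(sample0, "genotype_matrix"), inherits(sample1, "genotype_matrix"))
  if (!identical(sample0$loci, sample1$loci)) stop("samples must share the same locus list")
  g <- as.integer(generations_elapsed)
  if (is.na(g) || g < 1L) stop("generations_elapsed must be a positive integer")
  structure(list(sample0 = sample0, sample1 = sample1, generations_elapsed = g),
            class = "temporal_pair")
}
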