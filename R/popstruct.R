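#' Weir-Cockerham variance components for a set of populations
#'
#' Per locus and allele, computes the (a, b, c) variance components of the
#' Weir & Cockerham (1984) ANOVA estimators; multilocus statistics combine
#' components by ratio of sums (theta = sum a / sum(a+b+c),
#' f = 1 - sum c / sum(b+c), F = 1 - sum c / sum(a+b+c)).
#'
#' @param pops list of [genotype_matrix()] objects sharing one locus list.
#' @return list with `theta`, `f`, `F_IT`, and the per-locus component sums.
#' @keywords internal
wc_stats <- function(pops) {
  st <- wc_sufficient(pops)
  comp <- wc_components(st, seq_along(pops))
  list(theta = comp$a / (comp$a + comp$b + comp$c),
       f = 1 - comp$c / (comp$b + comp$c),
       F_IT = 1 - comp$c / (comp$a + comp$b + comp$c),
       components = comp)
}

# per locus-allele per population sufficient statistics: n_i (individuals
# with data), p_i (allele frequency), h_i (heterozygote frequency involving
# the allele)
wc_sufficient <- function(pops) {
  loci <- pops[[1L]]$loci
  for (g in pops) if (!identical(g$loci, loci)) stop("populations must share the locus list")
  r <- length(pops)
  out <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    alleles <- sort(unique(unlist(lapply(pops, function(g) c(g$calls[, l, ])))))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) { out[[l]] <- NULL; next }
    n <- matrix(0, r, 1L); p <- matrix(0, r, length(alleles)); h <- p
    for (i in seq_len(r)) {
      a1 <- pops[[i]]$calls[, l, 1L]; a2 <- pops[[i]]$calls[, l, 2L]
      ok <- !is.na(a1)
      n[i] <- sum(ok)
      if (n[i] == 0L) next
      for (k in seq_along(alleles)) {
        al <- alleles[k]
        p[i, k] <- (sum(a1[ok] == al) + sum(a2[ok] == al)) / (2 * n[i])
        h[i, k] <- sum(ok & (a1 == al) != (a2 == al), na.rm = TRUE) / n[i]
      }
    }
    out[[l]] <- list(alleles = alleles, n = n[, 1L], p = p, h = h)
  }
  names(out) <- loci
  out
}

# (a, b, c) sums over loci and alleles for a subset of populations
wc_components <- function(st, idx, per_locus = FALSE) {
  acc <- function(ll) {
    a_s <- b_s <- c_s <- 0
    for (z in ll) {
      if (is.null(z)) next
      ni <- z$n[idx]
      use <- ni > 0
      ni <- ni[use]
      r <- length(ni)
      if (r < 1L || sum(ni) == 0) next
      nbar <- mean(ni)
      for (k in seq_along(z$alleles)) {
        pi <- z$p[idx, k][use]; hi <- z$h[idx, k][use]
        pbar <- sum(ni * pi) / sum(ni)
        hbar <- sum(ni * hi) / sum(ni)
        if (r >= 2L) {
          nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
          s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
          a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
          b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        } else {
          a <- 0
          b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
        }
        cc <- hbar / 2
        a_s <- a_s + a; b_s <- b_s + b; c_s <- c_s + cc
      }
    }
    c(a = a_s, b = b_s, c = c_s)
  }
  if (!per_locus) {
    v <- acc(st)
    return(list(a = v[["a"]], b = v[["b"]], c = v[["c"]]))
  }
  t(vapply(st, function(z) acc(list(z)), c(a = 0, b = 0, c = 0)))
}

#' Per-population genetic-diversity table
#'
#' Mean number of alleles per locus, observed heterozygosity, unbiased
#' expected heterozygosity (gene diversity with the 2n/(2n-1) correction),
#' and the Weir-Cockerham within-population inbreeding coefficient F_IS with
#' a 95% bootstrap-over-loci confidence interval and a flag marking F_IS
#' values whose CI excludes zero.
#'
#' @param pops named list of [genotype_matrix()] objects.
#' @param n_boot locus bootstrap replicates for the F_IS CI.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame, one row per population.
#' @export
diversity_table <- function(pops, n_boot = 1000L, seed = NULL) {
  rows <- lapply(names(pops), function(nm) {
    g <- pops[[nm]]
    if (n_ind(g) < 2L) stop("need >= 2 individuals per population: ", nm)
    fr <- suppressWarnings(allele_freqs(g))
    nall <- vapply(fr$freqs, function(f) if (is.null(f)) NA_integer_ else length(f), 1L)
    A <- mean(nall, na.rm = TRUE)
    hobs_l <- hexp_l <- rep(NA_real_, n_loci(g))
    for (l in seq_len(n_loci(g))) {
      a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
      ok <- !is.na(a1)
      if (!any(ok)) next
      hobs_l[l] <- mean(a1[ok] != a2[ok])
      f <- fr$freqs[[l]]
      n2 <- 2 * sum(ok)
      hexp_l[l] <- n2 / (n2 - 1) * (1 - sum(f^2))
    }
    st <- wc_sufficient(list(g))
    comp_l <- wc_components(st, 1L, per_locus = TRUE)
    fis_from <- function(idx) {
      b <- sum(comp_l[idx, "b"]); cc <- sum(comp_l[idx, "c"])
      if (b + cc <= 0) NA_real_ else 1 - cc / (b + cc)
    }
    poly <- which(!is.na(nall) & nall > 1L)
    fis <- if (length(poly)) fis_from(seq_len(nrow(comp_l))) else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (!is.na(fis) && n_boot > 0L) {
      bs <- with_seed(seed, vapply(seq_len(n_boot), function(i)
        fis_from(sample(nrow(comp_l), replace = TRUE)), 0))
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    }
    data.frame(population = nm, ecotype = g$ecotype, n = n_ind(g),
               A = A, H_obs = mean(hobs_l, na.rm = TRUE),
               H_exp = mean(hexp_l, na.rm = TRUE),
               F_IS = fis, F_IS_lo = ci[1L], F_IS_hi = ci[2L],
               F_IS_nonzero = !is.na(ci[1L]) && (ci[1L] > 0 || ci[2L] < 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Weir-Cockerham F_ST matrix
#'
#' Multilocus theta for every population pair, combined by ratio of summed
#' variance components.
#'
#' @param pops named list of [genotype_matrix()] objects.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_fst <- function(pops) {
  r <- length(pops)
  if (r < 2L) stop("need at least 2 populations")
  st <- wc_sufficient(pops)
  m <- matrix(0, r, r, dimnames = list(names(pops), names(pops)))
  for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
    comp <- wc_components(st, c(i, j))
    tot <- comp$a + comp$b + comp$c
    m[i, j] <- m[j, i] <- if (tot <= 0) NA_real_ else comp$a / tot
  }
  m
}

#' Hierarchical fixation indexes (ecotype / population / individual)
#'
#' Partitions gene-copy variance by unbalanced nested ANOVA over four levels
#' (group, population within group, individual within population, gene copy
#' within individual), per allele and locus, combining variance components
#' by ratio of sums. Reported indexes: among groups
#' (relative to total), among populations within groups, and among
#' individuals within populations (the within-population fixation index).
#' CIs are bootstrap over loci.
#'
#' @param pops named list of [genotype_matrix()] objects.
#' @param assignment named vector population -> group; defaults to the
#'   ecotype metadata.
#' @param n_boot locus bootstrap replicates.
#' @param seed RNG seed.
#' @return data.frame with index estimates and 95% CIs.
#' @export
hierarchical_f <- function(pops, assignment = NULL, n_boot = 1000L, seed = NULL) {
  if (is.null(assignment))
    assignment <- vapply(pops, function(g) as.character(g$ecotype), "")
  if (length(unique(assignment)) < 2L) stop("need a two-level grouping")
  single <- table(assignment)
  if (any(single < 2L))
    warning("group(s) with a single population: ",
            paste(names(single)[single < 2L], collapse = ", "),
            "; that level's CI is degenerate")
  comp_l <- nested_varcomp_by_locus(pops, assignment)
  idx_from <- function(rows) {
    v <- colSums(comp_l[rows, , drop = FALSE])
    tot <- sum(v)
    c(among_groups = v[["eco"]] / tot,
      among_pops_within = v[["pop"]] / (v[["pop"]] + v[["ind"]] + v[["copy"]]),
      among_ind_within = v[["ind"]] / (v[["ind"]] + v[["copy"]]))
  }
  est <- idx_from(seq_len(nrow(comp_l)))
  ci <- matrix(NA_real_, 2L, 3L)
  if (n_boot > 0L) {
    bs <- with_seed(seed, vapply(seq_len(n_boot), function(i)
      idx_from(sample(nrow(comp_l), replace = TRUE)), est))
    ci <- apply(bs, 1L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  data.frame(level = c("among groups", "among populations within groups",
                       "among individuals within populations"),
             index = unname(est), ci_lo = ci[1L, ], ci_hi = ci[2L, ],
             stringsAsFactors = FALSE)
}

# per-locus nested variance components (columns eco, pop, ind, copy), summed
# over alleles; moment estimators from the unbalanced nested ANOVA with
# exact E[SS] coefficients (traces of the averaging quadratic forms)
nested_varcomp_by_locus <- function(pops, assignment) {
  loci <- pops[[1L]]$loci
  eco_of <- assignment[names(pops)]
  out <- matrix(0, length(loci), 4L,
                dimnames = list(loci, c("eco", "pop", "ind", "copy")))
  for (l in seq_along(loci)) {
    # gene copies with factors
    y_all <- list(); eco_f <- pop_f <- ind_f <- integer(0)
    alleles <- sort(unique(unlist(lapply(pops, function(g) c(g$calls[, l, ])))))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) < 2L) next
    copies <- list()
    for (i in seq_along(pops)) {
      g <- pops[[i]]
      a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
      ok <- which(!is.na(a1))
      if (!length(ok)) next
      copies[[i]] <- list(a = c(a1[ok], a2[ok]),
                          ind = paste0(i, "_", c(ok, ok)),
                          pop = rep(i, 2L * length(ok)),
                          eco = rep(eco_of[i], 2L * length(ok)))
    }
    copies <- copies[!vapply(copies, is.null, TRUE)]
    if (!length(copies)) next
    a <- unlist(lapply(copies, `[[`, "a"))
    ind <- unlist(lapply(copies, `[[`, "ind"))
    pop <- unlist(lapply(copies, `[[`, "pop"))
    eco <- unlist(lapply(copies, `[[`, "eco"))
    N <- length(a)
    f_ind <- as.integer(factor(ind)); f_pop <- as.integer(factor(pop))
    f_eco <- as.integer(factor(eco))
    n_ind_g <- tabulate(f_ind); n_pop_g <- tabulate(f_pop); n_eco_g <- tabulate(f_eco)
    # trace of A_f Z_v Z_v' for averaging form A_f and random level v
    tr <- function(cell_f, n_cell, v_f, n_v, v_in_cell) {
      if (is.null(cell_f)) return(sum(n_v^2) / N)             # grand mean form
      if (v_in_cell) {
        # v groups nested in cells: sum over v-groups n_vg^2 / n_cell(vg)
        cell_of_v <- cell_f[match(seq_along(n_v), v_f)]
        sum(n_v^2 / n_cell[cell_of_v])
      } else N
    }
    lv <- list(eco = list(f = f_eco, n = n_eco_g),
               pop = list(f = f_pop, n = n_pop_g),
               ind = list(f = f_ind, n = n_ind_g),
               copy = list(f = seq_len(N), n = rep(1L, N)))
    forms <- list(grand = NULL, eco = lv$eco, pop = lv$pop, ind = lv$ind)
    # nesting: eco > pop > ind > copy ; v_in_cell when v is finer than form
    finer <- function(v, f) match(v, names(lv)) >= match(f, names(forms))
    Tr <- matrix(0, 4L, 4L, dimnames = list(names(forms), names(lv)))
    for (fnm in names(forms)) for (vnm in names(lv)) {
      fo <- forms[[fnm]]
      Tr[fnm, vnm] <- tr(fo$f, fo$n, lv[[vnm]]$f, lv[[vnm]]$n,
                         is.null(fo) || finer(vnm, fnm))
    }
    # E[SS] coefficient matrix: SS rows eco, pop|eco, ind|pop, copy|ind
    C <- rbind(Tr["eco", ] - Tr["grand", ],
               Tr["pop", ] - Tr["eco", ],
               Tr["ind", ] - Tr["pop", ],
               c(N, N, N, N) - Tr["ind", ])
    for (k in seq_along(alleles)) {
      y <- as.numeric(a == alleles[k])
      Tv <- function(f, n) sum(tapply(y, f, sum)^2 / n)
      T_grand <- sum(y)^2 / N
      T_eco <- Tv(f_eco, n_eco_g); T_pop <- Tv(f_pop, n_pop_g)
      T_ind <- Tv(f_ind, n_ind_g); T_w <- sum(y^2)
      SS <- c(T_eco - T_grand, T_pop - T_eco, T_ind - T_pop, T_w - T_ind)
      sig <- tryCatch(solve(C, SS), error = function(e) rep(NA_real_, 4L))
      if (!anyNA(sig)) out[l, ] <- out[l, ] + sig
    }
  }
  out
}

#' Permutation comparison of a diversity statistic between two groups
#'
#' Compares the group means of a per-population statistic (H_obs, H_exp,
#' F_IS) or the within-group multilocus F_ST between two groups of
#' populations, permuting whole populations between groups. Two-sided
#' p-value with the +1 correction.
#'
#' @param pops named list of [genotype_matrix()] objects.
#' @param stat one of `"H_obs"`, `"H_exp"`, `"F_IS"`, `"F_ST"`.
#' @param assignment named vector population -> group (default: ecotype).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed` (group difference), `p_value`, `n_perm`.
#' @export
permutation_compare <- function(pops, stat = c("H_obs", "H_exp", "F_IS", "F_ST"),
                                assignment = NULL, n_perm = 5000L, seed = NULL) {
  stat <- match.arg(stat)
  if (is.null(assignment))
    assignment <- vapply(pops, function(g) as.character(g$ecotype), "")
  groups <- unique(assignment)
  if (length(groups) != 2L) stop("exactly 2 groups required")
  if (any(table(assignment) < 2L)) stop("need >= 2 populations per group")
  idx1 <- which(assignment == groups[1L])
  if (stat == "F_ST") {
    st <- wc_sufficient(pops)
    statfun <- function(i1) {
      i2 <- setdiff(seq_along(pops), i1)
      th <- function(ii) {
        comp <- wc_components(st, ii)
        comp$a / (comp$a + comp$b + comp$c)
      }
      th(i1) - th(i2)
    }
  } else {
    dt <- diversity_table(pops, n_boot = 0L)
    vals <- dt[[stat]]
    statfun <- function(i1) mean(vals[i1]) - mean(vals[-i1])
  }
  obs <- statfun(idx1)
  k <- length(idx1)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    statfun(sample(length(pops), k)), 0))
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = n_perm, stat = stat)
}

#' Linkage-disequilibrium screen over locus pairs
#'
#' Per population and locus pair, a permutation G-test on the genotype
#' contingency table plus a composite genotypic correlation (the largest
#' absolute correlation between per-allele dosages at the two loci). A pair
#' is flagged for removal only when it is both significant and correlated
#' above `r_threshold` in more than `pop_count_threshold` populations.
#'
#' @param pops named list of [genotype_matrix()] objects.
#' @param r_threshold composite correlation threshold.
#' @param pop_count_threshold flag only pairs exceeding the criteria in more
#'   than this many populations.
#' @param n_perm permutations for the G-test.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return data.frame per locus pair: `n_pops_assoc`, `remove`.
#' @export
ld_screen <- function(pops, r_threshold = 0.5, pop_count_threshold = 2L,
                      n_perm = 500L, alpha = 0.05, seed = NULL) {
  loci <- pops[[1L]]$loci
  L <- length(loci)
  if (L < 2L) stop("need >= 2 loci")
  pairs <- utils::combn(L, 2L)
  n_assoc <- integer(ncol(pairs))
  with_seed(seed, {
    for (g in pops) {
      for (pi in seq_len(ncol(pairs))) {
        l1 <- pairs[1L, pi]; l2 <- pairs[2L, pi]
        ok <- !is.na(g$calls[, l1, 1L]) & !is.na(g$calls[, l2, 1L])
        if (sum(ok) < 5L) next
        c1 <- paste0(pmin(g$calls[ok, l1, 1L], g$calls[ok, l1, 2L]), "/",
                     pmax(g$calls[ok, l1, 1L], g$calls[ok, l1, 2L]))
        c2 <- paste0(pmin(g$calls[ok, l2, 1L], g$calls[ok, l2, 2L]), "/",
                     pmax(g$calls[ok, l2, 1L], g$calls[ok, l2, 2L]))
        f1 <- as.integer(factor(c1)); f2 <- as.integer(factor(c2))
        k1 <- max(f1); k2 <- max(f2)
        if (k1 < 2L || k2 < 2L) next
        gstat <- function(f2v) {
          o <- tabulate(f1 + (f2v - 1L) * k1, nbins = k1 * k2)
          e <- as.vector(outer(tabulate(f1, k1), tabulate(f2v, k2))) / length(f1)
          keep <- o > 0
          2 * sum(o[keep] * log(o[keep] / e[keep]))
        }
        obs <- gstat(f2)
        perm <- vapply(seq_len(n_perm), function(i) gstat(sample(f2)), 0)
        pval <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
        # composite genotypic correlation via allele dosages
        rmax <- 0
        for (al in unique(c(g$calls[ok, l1, ]))) {
          d1 <- (g$calls[ok, l1, 1L] == al) + (g$calls[ok, l1, 2L] == al)
          if (stats::var(d1) == 0) next
          for (bl in unique(c(g$calls[ok, l2, ]))) {
            d2 <- (g$calls[ok, l2, 1L] == bl) + (g$calls[ok, l2, 2L] == bl)
            if (stats::var(d2) == 0) next
            rmax <- max(rmax, abs(stats::cor(d1, d2)))
          }
        }
        if (pval < alpha && rmax > r_threshold) n_assoc[pi] <- n_assoc[pi] + 1L
      }
    }
  })
  data.frame(locus1 = loci[pairs[1L, ]], locus2 = loci[pairs[2L, ]],
             n_pops_assoc = n_assoc,
             remove = n_assoc > pop_count_threshold,
             stringsAsFactors = FALSE)
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances on a 6371-km sphere from decimal-degree coordinates.
#' Populations with missing coordinates get `NA` rows/columns (excluded from
#' isolation-by-distance downstream).
#'
#' @param coords data.frame with columns `population`, `lat`, `lon`.
#' @return symmetric matrix of distances in km.
#' @export
geo_distances <- function(coords) {
  n <- nrow(coords)
  m <- matrix(NA_real_, n, n, dimnames = list(coords$population, coords$population))
  diag(m) <- 0
  bad <- is.na(coords$lat) | is.na(coords$lon)
  if (any(bad)) warning("missing coordinates for: ",
                        paste(coords$population[bad], collapse = ", "))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (bad[i] || bad[j]) next
    d <- geosphere::distHaversine(c(coords$lon[i], coords$lat[i]),
                                  c(coords$lon[j], coords$lat[j]),
                                  r = 6371000) / 1000
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements, with significance from
#' joint row/column permutation of the second matrix. One-sided (positive
#' association), as customary for isolation-by-distance.
#'
#' @param dist_a,dist_b symmetric matrices of equal dimension.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `r`, `p_value`, `n_perm`.
#' @export
mantel <- function(dist_a, dist_b, n_perm = 5000L, seed = NULL) {
  stopifnot(all(dim(dist_a) == dim(dist_b)))
  lt <- lower.tri(dist_a)
  x <- dist_a[lt]; y <- dist_b[lt]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stop("too few complete distance pairs for a Mantel test")
  if (stats::var(x[keep]) == 0 || stats::var(y[keep]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(x[keep], y[keep])
  n <- nrow(dist_a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- sample(n)
    while (all(s == seq_len(n))) s <- sample(n)  # identity counted via the +1
    yp <- dist_b[s, s][lt]
    k <- !is.na(x) & !is.na(yp)
    stats::cor(x[k], yp[k])
  }, 0))
  p <- (sum(perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
  list(r = r_obs, p_value = p, n_perm = n_perm)
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearised differentiation `F_ST / (1 - F_ST)`
#' on `log(distance)`, with the slope's significance from a Mantel-style
#' permutation of populations (pairs are not independent, so the parametric
#' p-value is not reported as primary).
#'
#' @param fst_matrix pairwise F_ST matrix.
#' @param dist_matrix distance matrix in km (positive distances).
#' @param n_perm permutations for the slope test.
#' @param seed RNG seed.
#' @return list with `slope`, `intercept`, `p_value`, `n_pairs`.
#' @export
ibd_regression <- function(fst_matrix, dist_matrix, n_perm = 5000L, seed = NULL) {
  stopifnot(all(dim(fst_matrix) == dim(dist_matrix)))
  lt <- lower.tri(fst_matrix)
  f <- fst_matrix[lt]; d <- dist_matrix[lt]
  drop1 <- !is.na(f) & f >= 1
  if (any(drop1)) warning(sum(drop1), " pair(s) with F_ST = 1 dropped")
  slope_of <- function(fm) {
    ff <- fm[lt]
    keep <- !is.na(ff) & !is.na(d) & ff < 1 & d > 0
    y <- ff[keep] / (1 - ff[keep]); x <- log(d[keep])
    cf <- stats::coef(stats::lm(y ~ x))
    cf
  }
  cf <- slope_of(fst_matrix)
  n <- nrow(fst_matrix)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- sample(n)
    slope_of(fst_matrix[s, s])[2L]
  }, 0))
  p <- (sum(abs(perm) >= abs(cf[2L]) - 1e-12) + 1) / (n_perm + 1)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]), p_value = p,
       n_pairs = sum(!is.na(f) & !is.na(d) & f < 1 & d > 0))
}

#' Centred, non-scaled PCA on individual allele dosages
#'
#' Individuals are coded by per-allele dosage (0/1/2 gene copies), columns
#' are centred but not scaled, missing dosages are imputed at the column
#' mean, and the decomposition is by singular values. Inertia fractions are
#' the normalised eigenvalues.
#'
#' @param pops named list of [genotype_matrix()] objects (pooled).
#' @return list with `scores` (individuals x components), `inertia`
#'   (fractions, non-increasing), `population` (row grouping).
#' @export
pca_freqs <- function(pops) {
  if (inherits(pops, "genotype_matrix")) pops <- list(pops)
  loci <- pops[[1L]]$loci
  cols <- list(); popv <- character(0)
  alleles_l <- lapply(seq_along(loci), function(l)
    sort(unique(unlist(lapply(pops, function(g) c(g$calls[, l, ]))))))
  X <- NULL
  for (g in pops) {
    n <- n_ind(g)
    row_blocks <- list()
    for (l in seq_along(loci)) {
      als <- alleles_l[[l]]; als <- als[!is.na(als)]
      if (!length(als)) next
      d <- vapply(als, function(al)
        (g$calls[, l, 1L] == al) + (g$calls[, l, 2L] == al), numeric(n))
      if (is.null(dim(d))) d <- matrix(d, nrow = n)
      row_blocks[[l]] <- d
    }
    X <- rbind(X, do.call(cbind, row_blocks))
    popv <- c(popv, rep(g$pop, n))
  }
  keep <- colSums(!is.na(X)) > 0
  X <- X[, keep, drop = FALSE]
  for (jj in seq_len(ncol(X))) {
    mis <- is.na(X[, jj])
    if (any(mis)) X[mis, jj] <- mean(X[, jj], na.rm = TRUE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ev <- sv$d^2
  list(scores = sv$u %*% diag(sv$d), inertia = ev / sum(ev), population = popv)
}

#' Relative reduction in effective size due to higher selfing
#'
#' Under partial selfing the effective size scales as `N / (1 + F)` with
#' `F = s/(2 - s)`; comparing two selfing rates gives the relative reduction
#' `1 - (1 + F(s1)) / (1 + F(s2))`, positive when `s2 > s1`.
#'
#' @param s1,s2 selfing rates in `[0, 1]`.
#' @return relative reduction in `(-1, 1)`.
#' @export
ne_reduction_from_selfing <- function(s1, s2) {
  stopifnot(s1 >= 0, s1 <= 1, s2 >= 0, s2 <= 1)
  1 - (1 + equilibrium_fis(s1)) / (1 + equilibrium_fis(s2))
}

#' Inbreeding depression needed to explain an adult-stage selfing deficit
#'
#' If selfed offspring survive to the sampled stage at relative rate
#' `1 - delta`, a primary selfing rate `s_primary` is observed among adults
#' as `s_adult = s_primary (1 - delta) / (1 - s_primary delta)`. This solves
#' for `delta = (s_primary - s_adult) / (s_primary (1 - s_adult))` and
#' forward-checks the solution.
#'
#' @param s_primary selfing rate at fertilisation.
#' @param s_adult selfing rate observed among surviving adults.
#' @return `delta` in `[0, 1]`.
#' @export
required_inbreeding_depression <- function(s_primary, s_adult) {
  stopifnot(s_primary > 0, s_primary <= 1, s_adult >= 0)
  if (s_adult > s_primary)
    stop("s_adult > s_primary would require negative inbreeding depression")
  delta <- (s_primary - s_adult) / (s_primary * (1 - s_adult))
  back <- s_primary * (1 - delta) / (1 - s_primary * delta)
  stopifnot(abs(back - s_adult) < 1e-10)
  delta
}
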