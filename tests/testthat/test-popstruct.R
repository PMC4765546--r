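test_that("Weir-Cockerham statistics hit their textbook boundary values", {
  # all homozygotes, both alleles present: f = 1
  g <- gm(cbind(c(rep(1, 5), rep(2, 5)), c(rep(1, 5), rep(2, 5))))
  dt <- diversity_table(list(p1 = g), n_boot = 0)
  expect_equal(dt$F_IS, 1)
  # fixed difference between two samples: theta = 1
  m <- pairwise_fst(list(a = gm(matrix(1, 8, 2)), b = gm(matrix(2, 8, 2))))
  expect_equal(m["a", "b"], 1)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0))
})

test_that("multilocus theta matches an independent component oracle", {
  set.seed(3)
  pops <- lapply(1:3, function(i) {
    bf <- mixmating:::sim_base_freqs(4, 3)
    sim_population(bf, 0.2, 12)
  })
  names(pops) <- c("a", "b", "c")
  got <- mixmating:::wc_stats(pops)
  # oracle: re-derive components per locus and allele from raw counts
  a_s <- b_s <- c_s <- 0
  for (l in 1:4) {
    alleles <- sort(unique(unlist(lapply(pops, function(g) c(g$calls[, l, ])))))
    for (al in alleles) {
      n <- vapply(pops, function(g) sum(!is.na(g$calls[, l, 1])), 0)
      p <- vapply(pops, function(g)
        sum(g$calls[, l, ] == al, na.rm = TRUE) / (2 * sum(!is.na(g$calls[, l, 1]))), 0)
      h <- vapply(pops, function(g)
        mean((g$calls[, l, 1] == al) != (g$calls[, l, 2] == al), na.rm = TRUE), 0)
      cmp <- oracle_wc_theta(n, p, h)
      a_s <- a_s + cmp["a"]; b_s <- b_s + cmp["b"]; c_s <- c_s + cmp["c"]
    }
  }
  expect_equal(got$theta, unname(a_s / (a_s + b_s + c_s)), tolerance = 1e-10)
  expect_equal(got$f, unname(1 - c_s / (b_s + c_s)), tolerance = 1e-10)
})

test_that("panmictic samples show no spurious differentiation or inbreeding", {
  bf <- mixmating:::with_seed(7, mixmating:::sim_base_freqs(8, 5))
  th <- vapply(1:15, function(i) {
    p1 <- sim_population(bf, 0, 50, seed = 700 + i)
    p2 <- sim_population(bf, 0, 50, seed = 800 + i)
    pairwise_fst(list(a = p1, b = p2))[1, 2]
  }, 0)
  expect_lt(abs(mean(th)), 0.02)
  fis <- vapply(1:15, function(i)
    diversity_table(list(p = sim_population(bf, 0, 50, seed = 900 + i)),
                    n_boot = 0)$F_IS, 0)
  expect_lt(abs(mean(fis)), 0.02)
})

test_that("hierarchical decomposition is consistent and collapse-invariant", {
  cfg <- sim_config(seed = 8, mu_s = c(MET = 0.44, NONMET = 0.44),
                    theta_pop = 0.25, n_ind = 40, n_loci = 10)
  mp <- sim_metapopulation(cfg)
  hf <- hierarchical_f(mp$pops, n_boot = 50, seed = 1)
  expect_lt(abs(hf$index[1]), 0.04)            # no true ecotype structure
  expect_equal(hf$index[2], 0.25, tolerance = 0.06)
  expect_equal(hf$index[3], equilibrium_fis(0.44), tolerance = 0.05)
  # relabeling ecotypes into one group must not move the population level;
  # compare against an alternative two-group split of the same populations
  alt <- stats::setNames(rep(c("X", "Y"), 5), names(mp$pops))
  hf2 <- hierarchical_f(mp$pops, assignment = alt, n_boot = 0)
  expect_equal(hf2$index[2], hf$index[2], tolerance = 0.03)
  # identical haplotype pools: all indexes near zero
  bf <- mixmating:::with_seed(9, mixmating:::sim_base_freqs(8, 4))
  same <- lapply(1:4, function(i) sim_population(bf, 0, 40, seed = 40 + i,
                                                 ecotype = c("A", "B")[1 + i %% 2]))
  names(same) <- paste0("p", 1:4)
  hf3 <- hierarchical_f(same, n_boot = 0)
  expect_true(all(abs(hf3$index) < 0.05))
})

test_that("population permutation tests calibrate and detect", {
  cfg <- sim_config(seed = 12, n_ind = 40, n_loci = 10)
  mp <- sim_metapopulation(cfg)  # MET s = 0.25 vs NONMET s = 0.40
  pc <- permutation_compare(mp$pops, "F_IS", n_perm = 300, seed = 2)
  expect_lt(pc$observed, 0)                     # MET less inbred
  expect_true(pc$p_value > 0 && pc$p_value <= 1)
  # duplicated populations across groups: no signal
  dup <- c(mp$pops[1:3], mp$pops[1:3])
  names(dup) <- paste0("d", 1:6)
  asn <- stats::setNames(rep(c("A", "B"), each = 3), names(dup))
  pd <- permutation_compare(dup, "H_exp", assignment = asn, n_perm = 200, seed = 3)
  expect_gt(pd$p_value, 0.5)
  # completely separated groups reach the minimal attainable p
  ps <- permutation_compare(mp$pops, "F_IS", n_perm = 300, seed = 4)
  expect_gte(ps$p_value, 1 / 301)
})

test_that("the linkage screen flags duplicated loci but respects the rule", {
  bf <- mixmating:::with_seed(21, mixmating:::sim_base_freqs(3, 4))
  dup_pop <- function(seed, duplicate) {
    g <- sim_population(bf, 0.2, 40, seed = seed)
    if (duplicate) g$calls[, 3, ] <- g$calls[, 1, ]  # locus 3 := copy of locus 1
    else {
      g2 <- sim_population(bf, 0.2, 40, seed = seed + 500)
      g$calls[, 3, ] <- g2$calls[, 3, ]
    }
    g
  }
  # duplicated in all four populations -> removed
  pops <- lapply(1:4, function(i) dup_pop(i, TRUE)); names(pops) <- paste0("p", 1:4)
  sc <- ld_screen(pops, n_perm = 150, seed = 5)
  row <- sc[sc$locus1 == "L1" & sc$locus2 == "L3", ]
  expect_equal(row$n_pops_assoc, 4L)
  expect_true(row$remove)
  # duplicated in exactly two populations -> kept (rule needs more than two)
  pops2 <- lapply(1:4, function(i) dup_pop(10 + i, i <= 2)); names(pops2) <- paste0("p", 1:4)
  sc2 <- ld_screen(pops2, n_perm = 150, seed = 6)
  row2 <- sc2[sc2$locus1 == "L1" & sc2$locus2 == "L3", ]
  expect_equal(row2$n_pops_assoc, 2L)
  expect_false(row2$remove)
})

test_that("great-circle distances match closed forms", {
  co <- data.frame(population = c("a", "b", "c", "d"),
                   lat = c(10, 10, 0, 0), lon = c(20, 20, 0, 1))
  D <- geo_distances(co)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["c", "d"], pi * 6371 / 180, tolerance = 1e-6)  # ~111.19 km
  co2 <- data.frame(population = c("x", "y"), lat = c(0, 0), lon = c(0, 180))
  expect_equal(geo_distances(co2)["x", "y"], pi * 6371, tolerance = 1e-6)
  co3 <- data.frame(population = c("x", "y"), lat = c(0, NA), lon = c(0, NA))
  expect_warning(D3 <- geo_distances(co3), "missing")
  expect_true(is.na(D3["x", "y"]))
})

test_that("Mantel statistics agree with exact enumeration and vegan", {
  set.seed(31)
  A <- as.matrix(dist(matrix(rnorm(8), 4)))
  B <- as.matrix(dist(matrix(rnorm(8), 4)))
  # identity association
  self <- mantel(A, A, n_perm = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 200)
  # exact p by enumeration of all 4! relabelings
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  r_all <- apply(perms, 1, function(s) cor(A[lt], B[s, s][lt]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  mt <- mantel(A, B, n_perm = 4000, seed = 2)
  expect_equal(mt$r, r_obs)
  expect_equal(mt$p_value, p_exact, tolerance = 0.04)
  expect_error(mantel(matrix(1, 4, 4), A, n_perm = 10), "constant")
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::mantel(A, B, permutations = 999)
    expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
  }
})

test_that("isolation-by-distance regression is exact on linear data", {
  set.seed(41)
  n <- 6
  D <- as.matrix(dist(matrix(runif(n * 2) * 5 + 1, n)))
  slope <- 0.07; intercept <- -0.12
  lin <- intercept + slope * log(D)
  fst <- lin / (1 + lin)  # so fst/(1-fst) = lin exactly
  diag(fst) <- 0
  ib <- ibd_regression(fst, D, n_perm = 99, seed = 1)
  expect_equal(ib$slope, slope, tolerance = 1e-10)
  expect_equal(ib$intercept, intercept, tolerance = 1e-10)
  # island model: slope centred at zero, p not extreme
  cfg <- sim_config(seed = 43, n_ind = 30, n_loci = 8)
  mp <- sim_metapopulation(cfg)
  co <- data.frame(population = names(mp$pops), lat = mp$truth$lat,
                   lon = mp$truth$lon)
  ib0 <- ibd_regression(pairwise_fst(mp$pops), geo_distances(co),
                        n_perm = 200, seed = 2)
  expect_gt(ib0$p_value, 0.01)
})

test_that("the dosage PCA separates diverged populations", {
  cfg <- sim_config(seed = 51, theta_pop = 0.6, n_pop_per_ecotype = 1,
                    n_ind = 30, n_loci = 14)
  mp <- sim_metapopulation(cfg)
  pc <- pca_freqs(mp$pops)
  expect_equal(sum(pc$inertia), 1, tolerance = 1e-10)
  expect_true(all(diff(pc$inertia) <= 1e-10))
  # silhouette of the two populations on PC1
  x <- pc$scores[, 1]; grp <- pc$population
  sil <- vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[grp == grp[i]][-match(i, which(grp == grp[i]))]))
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.8)
  # duplicating individuals leaves the leading direction unchanged
  dup <- c(mp$pops, mp$pops)
  names(dup) <- paste0("q", seq_along(dup))
  pc2 <- pca_freqs(dup)
  n <- length(x)
  expect_gt(abs(cor(pc2$scores[1:n, 1], x)), 0.999)
})

test_that("closed-form selfing arithmetic matches the stated relations", {
  expect_equal(ne_reduction_from_selfing(0.3, 0.3), 0)
  expect_equal(ne_reduction_from_selfing(0.25, 0.40), 0.0857, tolerance = 1e-3)
  expect_equal(ne_reduction_from_selfing(0, 1), 0.5)
  expect_lt(ne_reduction_from_selfing(0.4, 0.25), 0)  # sign convention
  expect_equal(required_inbreeding_depression(0.4, 0.25), 0.5)
  expect_equal(required_inbreeding_depression(0.3, 0.3), 0)
  expect_equal(required_inbreeding_depression(0.5, 1 / 3), 0.5)
  expect_error(required_inbreeding_depression(0.25, 0.4), "negative")
})
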