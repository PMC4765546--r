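test_that("individual likelihood matches closed forms and brute-force sums", {
  # no selfing: P(het) = h
  expect_equal(individual_loglik(1, selfing_params(0, 0.5)), log(0.5))
  # geometric closed form: s = 0.5, h = 1 -> h (1-s) / (1 - s/2) = 2/3
  expect_equal(individual_loglik(1, selfing_params(0.5, 1)), log(2 / 3),
               tolerance = 1e-12)
  # two loci, arbitrary params: explicit term-by-term oracle at n_max = 6
  set.seed(5)
  for (i in 1:10) {
    s <- runif(1, 0, 0.9); h <- runif(2)
    x <- sample(0:1, 2, replace = TRUE)
    p <- selfing_params(s, h, n_max = 6)
    expect_equal(individual_loglik(x, p), log(oracle_rmes_prob(x, s, h, 6)),
                 tolerance = 1e-12)
  }
  # masked loci contribute a factor of one
  p <- selfing_params(0.3, c(0.5, 0.7))
  expect_equal(individual_loglik(c(1, NA), p),
               individual_loglik(1, selfing_params(0.3, 0.5)))
  expect_error(individual_loglik(c(NA, NA), p), "no information")
})

test_that("pattern probabilities sum to one over all heterozygosity patterns", {
  set.seed(17)
  for (L in c(3, 8)) {
    s <- runif(1, 0, 0.95); h <- runif(L)
    p <- selfing_params(s, h)
    pats <- as.matrix(expand.grid(rep(list(0:1), L)))
    tot <- sum(apply(pats, 1, function(x) exp(individual_loglik(x, p))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("single-locus heterozygote frequency matches the equilibrium form", {
  # P(het) = h (1-s) / (1 - s/2) = h (1 - F_eq), F_eq = s/(2-s)
  s <- 0.4; h_true <- 0.8
  bf <- list(L1 = c(`1` = 0.1, `2` = 0.45, `3` = 0.45))
  # h in the mixture is the outbred heterozygosity 1 - sum(p^2) ... use the
  # simulator as Monte-Carlo oracle on the realised heterozygote frequency
  h_outbred <- 1 - sum(bf$L1^2)
  g <- sim_population(bf, s, 20000, seed = 21)
  expect_equal(mean(het_patterns(g)), h_outbred * (1 - s / (2 - s)),
               tolerance = 0.01)
})

test_that("profile fit recovers boundary and generic cases", {
  # every individual heterozygous at every locus -> s_hat = 0
  g <- gm(matrix(rep(c(1, 2), 20), nrow = 5, byrow = TRUE))
  f <- fit_selfing(g, grid_step = 0.01)
  expect_equal(f$s_hat, 0)
  expect_true(f$boundary)
  # no heterozygote at all -> boundary at grid max with warning
  ghom <- gm(rbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 1, 1)))
  expect_warning(fhom <- fit_selfing(ghom, grid_step = 0.01), "unidentifiable")
  expect_gte(fhom$s_hat, 0.99)
  # all loci monomorphic -> error
  gmono <- gm(rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 2)))
  expect_error(fit_selfing(gmono, grid_step = 0.01), "monomorphic")
})

test_that("fit is invariant to allele relabeling and locus order", {
  bf <- with_seed(31, sim_base_freqs(6, 4))
  g <- sim_population(bf, 0.35, 60, seed = 32)
  f0 <- fit_selfing(g, grid_step = 0.005)
  # relabel alleles (per locus bijection) and permute loci
  g2 <- g
  g2$calls <- g$calls[, c(3, 1, 6, 2, 5, 4), , drop = FALSE] * 10L
  f2 <- fit_selfing(g2, grid_step = 0.005)
  expect_equal(f2$s_hat, f0$s_hat, tolerance = 1e-6)
  expect_equal(f2$loglik, f0$loglik, tolerance = 1e-6)
})

test_that("estimates are consistent and the CI covers the truth", {
  bf <- with_seed(41, sim_base_freqs(14, 6))
  f <- fit_selfing(sim_population(bf, 0.4, 200, seed = 42))
  expect_gte(f$ci95[2], 0.4 * 0.85)  # truth inside or near the interval
  expect_lte(f$ci95[1], 0.4 * 1.15)
  # bias shrinks with sample size (n = 50 vs 800, 25 replicates each)
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(sd)
      fit_selfing(sim_population(bf, 0.4, n, seed = sd),
                  grid_step = 0.005)$s_hat, 0)) - 0.4
  }
  b50 <- bias_at(50, 101:125)
  b800 <- bias_at(800, 201:225)
  expect_lt(abs(b800), 0.03)
  expect_lt(abs(b50), 0.08)
})

test_that("F_IS conversions are exact and mutually inverse", {
  expect_equal(selfing_from_fis(0), 0)
  expect_equal(selfing_from_fis(1), 1)
  expect_equal(selfing_from_fis(0.25), 0.4)
  expect_equal(selfing_from_fis(0.22), 2 * 0.22 / 1.22, tolerance = 1e-12)
  expect_warning(s <- selfing_from_fis(-0.1), "negative")
  expect_equal(s, 0)
  expect_error(selfing_from_fis(-1), "F")
  expect_equal(equilibrium_fis(0), 0)
  expect_equal(equilibrium_fis(0.25), 1 / 7, tolerance = 1e-12)
  expect_equal(equilibrium_fis(0.4), 0.25)
  sgrid <- seq(0, 1, length.out = 101)
  expect_equal(selfing_from_fis(equilibrium_fis(sgrid)), sgrid, tolerance = 1e-12)
})

test_that("profiles serialise to TSV and JSON", {
  bf <- with_seed(51, sim_base_freqs(5, 4))
  f <- fit_selfing(sim_population(bf, 0.3, 40, seed = 52), grid_step = 0.01)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_selfing_profile(f, tsv = tsv, json = js)
  d <- read.delim(tsv)
  expect_equal(d$s, f$grid)
  expect_equal(d$loglik, f$loglik, tolerance = 1e-9)
  j <- jsonlite::read_json(js)
  expect_equal(j$s_hat, f$s_hat)
  unlink(c(tsv, js))
})
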