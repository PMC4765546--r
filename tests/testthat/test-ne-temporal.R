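test_that("drift transitions match binomial closed forms", {
  # one diploid: binomial(2, 0.5)
  dt <- drift_transition(0.5, 1, 1)
  expect_equal(dt$prob, c(0.25, 0.5, 0.25))
  expect_equal(dt$x, c(0, 0.5, 1))
  # martingale mean and the standard drift variance, several settings
  for (ne in c(10, 40)) for (g in c(1, 3)) {
    dt <- drift_transition(0.3, ne, g)
    m <- sum(dt$x * dt$prob)
    v <- sum((dt$x - m)^2 * dt$prob)
    expect_equal(m, 0.3, tolerance = 1e-8)
    expect_equal(v, 0.3 * 0.7 * (1 - (1 - 1 / (2 * ne))^g), tolerance = 1e-8)
  }
  # rows sum to one and the boundaries absorb
  dt <- drift_transition(0, 20, 2)
  expect_equal(dt$prob[1], 1)
  dt <- drift_transition(1, 20, 2)
  expect_equal(dt$prob[length(dt$prob)], 1)
  expect_error(drift_transition(0.5, 20, 0), "g")
})

test_that("approximate and exact drift kernels agree in their overlap", {
  e <- drift_transition(0.4, 300, 3, "exact")
  a <- drift_transition(0.4, 300, 3, "approx")
  expect_lt(0.5 * sum(abs(e$prob - a$prob)), 0.01)
})

test_that("temporal likelihood favours large sizes when nothing changed", {
  cts <- list(stats::setNames(c(30L, 20L), c("1", "2")))
  ll <- vapply(c(50, 100, 500, 2000, 10000), function(ne)
    temporal_loglik(cts, cts, ne, 1), 0)
  expect_true(all(diff(ll) > 0))
})

test_that("exact likelihood equals the exhaustive lattice sum", {
  for (case in list(c(7, 20, 12, 20, 12, 2), c(3, 16, 9, 18, 8, 1))) {
    k0 <- case[1]; n0 <- case[2]; k1 <- case[3]; n1 <- case[4]
    Ne <- case[5]; g <- case[6]
    m <- 2 * Ne
    brute <- 0
    for (i in 1:(m - 1)) {
      x0 <- i / m
      w0 <- dbinom(k0, n0, x0) / (m - 1)
      # propagate g generations by explicit nested sums
      v <- numeric(m + 1); v[i + 1] <- 1
      for (gen in seq_len(g)) {
        vn <- numeric(m + 1)
        for (j in 0:m) if (v[j + 1] > 0)
          vn <- vn + v[j + 1] * dbinom(0:m, m, j / m)
        v <- vn
      }
      brute <- brute + w0 * sum(v * dbinom(k1, n1, (0:m) / m))
    }
    cts0 <- list(stats::setNames(c(k0, n0 - k0), c("1", "2")))
    cts1 <- list(stats::setNames(c(k1, n1 - k1), c("1", "2")))
    got <- temporal_loglik(cts0, cts1, Ne, g, mode = "exact")
    # a two-allele locus contributes both the focal and complement collapse
    brute_c <- 0
    for (i in 1:(m - 1)) {
      x0 <- i / m
      w0 <- dbinom(n0 - k0, n0, x0) / (m - 1)
      v <- numeric(m + 1); v[i + 1] <- 1
      for (gen in seq_len(g)) {
        vn <- numeric(m + 1)
        for (j in 0:m) if (v[j + 1] > 0)
          vn <- vn + v[j + 1] * dbinom(0:m, m, j / m)
        v <- vn
      }
      brute_c <- brute_c + w0 * sum(v * dbinom(n1 - k1, n1, (0:m) / m))
    }
    expect_equal(got, log(brute) + log(brute_c), tolerance = 1e-10)
  }
})

test_that("the initial-frequency grid is converged in approximate mode", {
  cts0 <- list(stats::setNames(c(40L, 30L, 20L), c("1", "2", "3")))
  cts1 <- list(stats::setNames(c(35L, 33L, 22L), c("1", "2", "3")))
  l64 <- temporal_loglik(cts0, cts1, 2000, 1, mode = "approx", grid_init = 64)
  l128 <- temporal_loglik(cts0, cts1, 2000, 1, mode = "approx", grid_init = 128)
  expect_lt(abs(l128 - l64), 1e-4)
})

test_that("identical samples saturate at the cap and fits are invariant", {
  bf <- mixmating:::with_seed(4, mixmating:::sim_base_freqs(10, 5))
  g1 <- sim_population(bf, 0, 100, seed = 5)
  tp <- temporal_pair(g1, g1, 1)
  f <- fit_ne(tp)
  expect_true(f$at_cap)
  expect_equal(f$Ne_hat, f$cap)
  expect_true(fk_moment_ne(tp)$at_cap)
  # locus order and allele relabeling leave the estimate unchanged
  cfg <- sim_config(seed = 16, Ne = 80, generations = 1, n_loci = 8, n_ind = 60)
  st <- sim_temporal(cfg)
  f0 <- fit_ne(st$pair)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  relab <- function(g) { g$calls <- g$calls[, perm, , drop = FALSE] * 7L; g }
  f1 <- fit_ne(temporal_pair(relab(st$pair$sample0), relab(st$pair$sample1), 1))
  expect_equal(f1$Ne_hat, f0$Ne_hat, tolerance = 1e-6)
})

test_that("moment and likelihood estimators track the true size", {
  cfg <- function(ne) sim_config(seed = 100 + ne, Ne = ne, generations = 2,
                                 n_loci = 15, n_alleles = 5, n_ind = 80)
  med <- vapply(c(25, 100, 400), function(ne) {
    est <- vapply(1:10, function(i) {
      st <- sim_temporal(cfg(ne), seed = ne * 37 + i)
      fit_ne(st$pair)$Ne_hat
    }, 0)
    median(est)
  }, 0)
  expect_true(all(diff(med) > 0))   # stochastic ordering of the estimates
  # moment estimate within a factor of ~2 of the likelihood one, typically
  st <- sim_temporal(cfg(100), seed = 77)
  ml <- fit_ne(st$pair)$Ne_hat
  mo <- fk_moment_ne(st$pair)$Ne_hat
  expect_lt(abs(log(ml / mo)), log(2.5))
  # halving Ne raises the standardised frequency change
  f_small <- median(vapply(1:8, function(i)
    fk_moment_ne(sim_temporal(cfg(50), seed = 900 + i)$pair)$F_hat, 0))
  f_large <- median(vapply(1:8, function(i)
    fk_moment_ne(sim_temporal(cfg(400), seed = 950 + i)$pair)$F_hat, 0))
  expect_gt(f_small, f_large)
})
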