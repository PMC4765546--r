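test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_config(seed = 3, n_ind = 20, n_loci = 5, n_families = 3,
                    progeny_per_family = 4)
  a <- sim_metapopulation(cfg); b <- sim_metapopulation(cfg)
  expect_identical(a$pops[[1]]$calls, b$pops[[1]]$calls)
  expect_identical(a$truth$s, b$truth$s)
  pa <- sim_progeny_arrays(cfg); pb <- sim_progeny_arrays(cfg)
  expect_identical(pa$arrays$families[[2]]$progeny$calls,
                   pb$arrays$families[[2]]$progeny$calls)
  ta <- sim_temporal(cfg); tb <- sim_temporal(cfg)
  expect_identical(ta$pair$sample1$calls, tb$pair$sample1$calls)
  # and the RNG stream of the caller is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sim_metapopulation(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("outbred simulation sits at Hardy-Weinberg", {
  bf <- list(L1 = c(`1` = 0.5, `2` = 0.3, `3` = 0.2))
  ok <- vapply(1:20, function(i) {
    g <- sim_population(bf, 0, 500, seed = 1000 + i)
    a1 <- g$calls[, 1, 1]; a2 <- g$calls[, 1, 2]
    codes <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
    p <- bf$L1
    gl <- c("1/1", "1/2", "1/3", "2/2", "2/3", "3/3")
    ex <- c(p[1]^2, 2 * p[1] * p[2], 2 * p[1] * p[3], p[2]^2, 2 * p[2] * p[3], p[3]^2)
    obs <- vapply(gl, function(z) sum(codes == z), 0)
    suppressWarnings(stats::chisq.test(obs, p = ex)$p.value) > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("partial selfing produces the equilibrium heterozygote deficit", {
  bf <- mixmating:::with_seed(61, mixmating:::sim_base_freqs(10, 5))
  f <- vapply(1:30, function(i)
    diversity_table(list(p = sim_population(bf, 0.4, 60, seed = 2000 + i)),
                    n_boot = 0)$F_IS, 0)
  expect_lt(abs(mean(f) - 0.25), 0.02)
})

test_that("null alleles inflate the apparent heterozygote deficit", {
  bf <- mixmating:::with_seed(71, mixmating:::sim_base_freqs(10, 5))
  d <- vapply(1:12, function(i) {
    clean <- sim_population(bf, 0.3, 60, seed = 3000 + i)
    drop <- sim_population(bf, 0.3, 60, dropout = c(rep(0.2, 4), rep(0, 6)),
                           seed = 3000 + i)
    diversity_table(list(p = drop), n_boot = 0)$F_IS -
      diversity_table(list(p = clean), n_boot = 0)$F_IS
  }, 0)
  expect_gt(mean(d), 0.02)       # upward bias from hidden alleles
  # null homozygotes appear as missing calls at affected loci
  g <- sim_population(bf, 0.3, 400, dropout = c(0.3, rep(0, 9)), seed = 77)
  expect_gt(sum(is.na(g$calls[, 1, 1])), 0)
  expect_equal(sum(is.na(g$calls[, 2, 1])), 0)
})

test_that("metapopulation truth records reproduce the design", {
  cfg <- sim_config(seed = 81, sigma_logit = c(MET = 0.3, NONMET = 0.3),
                    n_ind = 10, n_loci = 4)
  mp <- sim_metapopulation(cfg)
  expect_length(mp$pops, 10)
  expect_equal(as.integer(table(mp$truth$ecotype)), c(5L, 5L))
  expect_true(all(mp$truth$s > 0 & mp$truth$s < 1))
  expect_true(all(vapply(mp$pops, function(g) n_ind(g) == 10, TRUE)))
  # ecotype label is carried onto each population
  expect_equal(unname(vapply(mp$pops, `[[`, "", "ecotype")),
               unname(mp$truth$ecotype))
})

test_that("fully outcrossed shared-father sibships are single-father clutches", {
  cfg <- sim_config(seed = 91, t_m = 1, r_p = 1, r_t = 0, n_families = 10,
                    progeny_per_family = 5, n_loci = 4)
  sim <- sim_progeny_arrays(cfg)
  for (tr in sim$truth$families) {
    expect_true(all(!tr$selfed))
    expect_equal(length(unique(tr$father)), 1L)
  }
})

test_that("temporal drift behaves like the configured Wright-Fisher model", {
  # no drift: fit saturates at the cap
  cfg_inf <- sim_config(seed = 95, Ne = Inf, n_loci = 10, n_ind = 80)
  st <- sim_temporal(cfg_inf)
  expect_true(fit_ne(st$pair)$at_cap)
  # seasonal within-population differentiation stays small at Ne = 100
  cfg <- sim_config(seed = 96, Ne = 100, generations = 1, n_ind = 45)
  fst <- vapply(1:5, function(i) {
    st <- sim_temporal(cfg, seed = 960 + i)
    pairwise_fst(list(a = st$pair$sample0, b = st$pair$sample1))[1, 2]
  }, 0)
  expect_lt(mean(fst), 0.06)
  # longer intervals mean larger frequency change
  delta <- function(gg, i) {
    cfgg <- sim_config(seed = 97, Ne = 50, generations = gg, n_loci = 10)
    st <- sim_temporal(cfgg, seed = 970 + i)
    mean(abs(vapply(seq_along(st$truth$freqs0), function(l)
      st$truth$freqs_g[[l]][1] - st$truth$freqs0[[l]][1], 0)))
  }
  d1 <- mean(vapply(1:10, function(i) delta(1, i), 0))
  d4 <- mean(vapply(1:10, function(i) delta(4, i), 0))
  expect_gt(d4, d1)
})

test_that("synthetic quadratic profiles behave like real ones", {
  pr <- sim_profiles(c(-0.5, 0.3), 0.2)
  expect_s3_class(pr[[1]], "selfing_profile")
  expect_equal(pr[[1]]$s_hat, plogis(-0.5), tolerance = 2e-3)
  # fit on a single profile returns its centre
  names(pr) <- c("a", "b")
  f <- fit_hier(pr["a"], hier_spec(c(a = "G"), "shared", "zero"))
  expect_equal(f$mu[[1]], -0.5, tolerance = 1e-3)
})
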