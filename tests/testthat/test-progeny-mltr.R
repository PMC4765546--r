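toy_family <- function(progeny_calls, mother = NULL, loci = NULL) {
  g <- gm(progeny_calls)
  if (!is.null(loci)) g$loci <- loci
  list(mother = if (!is.null(mother)) matrix(as.integer(mother), nrow = 2) else NULL,
       progeny = g)
}

test_that("progeny genotype probabilities are normalised", {
  set.seed(7)
  p <- c(`1` = 0.5, `2` = 0.3, `3` = 0.2)
  freqs <- list(L1 = p)
  genos <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  for (rep in 1:4) {
    pars <- mating_params(runif(1), runif(1), runif(1), runif(1))
    for (mother in list(c(1, 2), NULL)) {
      tot <- sum(vapply(genos, function(g)
        exp(family_loglik(toy_family(matrix(g, 1), mother), pars, freqs)), 0))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("family likelihood equals exhaustive latent-class enumeration", {
  p <- c(`1` = 0.6, `2` = 0.4)
  freqs <- list(L1 = p)
  set.seed(11)
  for (rep in 1:6) {
    pars <- mating_params(runif(1, 0.2, 0.9), runif(1), runif(1), runif(1))
    prog <- matrix(sample(1:2, 4, replace = TRUE), 2)  # 2 progeny, 1 locus
    for (mother in list(c(1, 2), c(1, 1), NULL)) {
      fam <- toy_family(prog, mother)
      want <- oracle_family_lik(list(prog), if (is.null(mother)) NULL else
                                  list(as.integer(mother)),
                                freqs, pars$t_m, pars$r_t, pars$r_p,
                                pars$F_p, pars$F_m)
      expect_equal(family_loglik(fam, pars, freqs), log(unname(want)), tolerance = 1e-10)
    }
  }
  # two loci, three progeny against the same oracle
  freqs2 <- list(L1 = p, L2 = c(`1` = 0.3, `2` = 0.3, `3` = 0.4))
  prog2 <- rbind(c(1, 2, 1, 3), c(1, 1, 2, 3), c(2, 2, 3, 3))
  pars <- mating_params(0.7, 0.25, 0.4, 0.1)
  fam <- toy_family(prog2, c(1, 2, 1, 3))
  want <- oracle_family_lik(list(prog2[, 1:2], prog2[, 3:4]),
                            list(c(1L, 2L), c(1L, 3L)),
                            freqs2, 0.7, 0.25, 0.4, 0.1, pars$F_m)
  expect_equal(family_loglik(fam, pars, freqs2), log(unname(want)), tolerance = 1e-10)
})

test_that("with r_t = r_p = 0 the family likelihood factorises over progeny", {
  freqs <- list(L1 = c(`1` = 0.5, `2` = 0.5), L2 = c(`1` = 0.2, `2` = 0.8))
  pars <- mating_params(0.6, 0, 0, 0)
  prog <- rbind(c(1, 2, 1, 1), c(1, 1, 2, 2), c(2, 2, 1, 2))
  fam <- toy_family(prog, c(1, 2, 1, 2))
  whole <- family_loglik(fam, pars, freqs)
  parts <- sum(vapply(1:3, function(j)
    family_loglik(toy_family(prog[j, , drop = FALSE], c(1, 2, 1, 2)),
                  pars, freqs), 0))
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("certain outcrossing drives the outcrossing rate to its boundary", {
  # homozygous mothers 1/1; every progeny carries allele 2 somewhere
  L <- 4
  fams <- lapply(1:6, function(i) {
    calls <- array(1L, c(4, L, 2))
    calls[, , 2] <- 2L  # every progeny heterozygous 1/2 at every locus
    list(mother = matrix(1L, 2, L), progeny = genotype_matrix(calls))
  })
  arr <- progeny_array_set(fams, loci = paste0("L", 1:L))
  fit <- suppressWarnings(fit_mating(arr, n_boot = 0, n_starts = 2))
  expect_gte(fit$estimates$t_m, 0.999)
  expect_true(fit$boundary[["t_m"]])
})

test_that("impossible progeny genotypes are reported with their location", {
  # known mother 1/1: an outcrossed progeny still carries one maternal
  # allele, so genotype 2/2 is impossible under every latent path
  fams <- list(fam_a = list(mother = matrix(1L, 2, 1),
                            progeny = gm(rbind(c(1, 1), c(2, 2)))))
  arr <- progeny_array_set(fams)
  fq <- list(L1 = c(`1` = 0.7, `2` = 0.3))
  expect_error(progeny_tables(arr, fq), "fam_a.*L1|L1.*fam_a")
})

test_that("composite likelihood is order-invariant and matches pairs exactly", {
  cfg <- sim_config(seed = 61, n_loci = 5, n_alleles = 4, n_families = 6,
                    progeny_per_family = 2, t_m = 0.7, r_t = 0.3, r_p = 0.4)
  arr <- sim_progeny_arrays(cfg)$arrays
  fq <- mating_freqs(arr)
  pars <- mating_params(0.7, 0.3, 0.4, 0.15)
  tabs <- progeny_tables(arr, fq)
  cl <- mixmating:::.progeny_composite_loglik_cpp(tabs, 0.7, 0.3, 0.4, 0.15, pars$F_m,
                                      rep(1, 6), 0L)
  fl <- sum(vapply(arr$families, function(f) family_loglik(f, pars, fq), 0))
  expect_equal(cl, fl, tolerance = 1e-10)
  # permute families and progeny within a family
  arr2 <- arr
  arr2$families <- rev(arr2$families)
  arr2$families[[1]]$progeny <- arr2$families[[1]]$progeny[2:1, ]
  tabs2 <- progeny_tables(arr2, fq)
  cl2 <- mixmating:::.progeny_composite_loglik_cpp(tabs2, 0.7, 0.3, 0.4, 0.15, pars$F_m,
                                       rep(1, 6), 0L)
  expect_equal(cl2, cl, tolerance = 1e-10)
})

test_that("simulated sibships realise the pairwise correlation parameters", {
  cfg <- sim_config(seed = 71, n_loci = 1, n_alleles = 2, n_families = 4000,
                    progeny_per_family = 2, t_m = 0.6, r_t = 0.25, r_p = 0.35)
  truth <- sim_progeny_arrays(cfg)$truth$families
  selfed <- t(vapply(truth, `[[`, logical(2), "selfed"))
  fathers <- t(vapply(truth, `[[`, integer(2), "father"))
  expect_lt(abs(cor(selfed[, 1], selfed[, 2]) - 0.25), 0.03)
  both_out <- !selfed[, 1] & !selfed[, 2]
  share <- fathers[both_out, 1] == fathers[both_out, 2]
  expect_lt(abs(mean(share) - 0.35), 0.03)
})

test_that("known and marginalised mothers give concordant estimates", {
  cfg <- sim_config(seed = 81, n_loci = 8, n_alleles = 5, n_families = 15,
                    progeny_per_family = 8)
  known <- sim_progeny_arrays(cfg)
  hidden <- known
  for (i in seq_along(hidden$arrays$families))
    hidden$arrays$families[[i]]$mother <- NULL
  fk <- fit_mating(known$arrays, n_boot = 0, n_starts = 2)
  fh <- fit_mating(hidden$arrays, n_boot = 0, n_starts = 2)
  expect_lt(abs(fh$estimates$t_m - fk$estimates$t_m), 0.1)
  # plug-in ML mother assignment errs occasionally at this small design,
  # so its agreement band is wider than the marginalised route's
  fml <- fit_mating(hidden$arrays, n_boot = 0, n_starts = 2, infer_mother = "ml")
  expect_lt(abs(fml$estimates$t_m - fk$estimates$t_m), 0.16)
})

test_that("single-locus and multilocus rates coincide on one-locus data", {
  cfg <- sim_config(seed = 91, n_loci = 1, n_alleles = 6, n_families = 12,
                    progeny_per_family = 10, r_t = 0, r_p = 0.2)
  arr <- sim_progeny_arrays(cfg)$arrays
  fit <- suppressWarnings(fit_mating(arr, n_boot = 0, n_starts = 2))
  expect_equal(fit$estimates$mean_ts, fit$estimates$t_m, tolerance = 1e-3)
  expect_equal(fit$estimates$biparental, 0, tolerance = 1e-3)
})

test_that("bootstrap intervals bracket their point estimates", {
  cfg <- sim_config(seed = 95, n_loci = 6, n_alleles = 4, n_families = 10,
                    progeny_per_family = 6)
  arr <- sim_progeny_arrays(cfg)$arrays
  fit <- fit_mating(arr, n_boot = 60, seed = 2, n_starts = 2)
  for (par in c("t_m", "r_p")) {
    expect_gte(fit$estimates[[par]] + 0.02, fit$ci["2.5%", par])
    expect_lte(fit$estimates[[par]] - 0.02, fit$ci["97.5%", par])
  }
  bp <- biparental_inbreeding(fit)
  expect_true(bp$ci95[1] <= bp$estimate && bp$estimate <= bp$ci95[2])
})

test_that("effective father counts invert the correlation of paternity", {
  expect_equal(effective_fathers(0.032)$n_fathers, 31L)
  expect_equal(effective_fathers(0.35)$n_fathers, 3L)
  expect_equal(effective_fathers(1)$n_fathers, 1L)
  expect_true(effective_fathers(0)$unbounded)
  expect_equal(effective_fathers(0.25)$exact, 4)
})
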