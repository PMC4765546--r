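make_profiles <- function(m, v, groups) {
  pr <- sim_profiles(m, v)
  names(pr) <- paste0("p", seq_along(m))
  list(profiles = pr, assignment = stats::setNames(groups, names(pr)))
}

test_that("marginal likelihood matches the conjugate closed form", {
  set.seed(3)
  m <- rnorm(6, 0, 0.8); v <- 0.25
  mp <- make_profiles(m, v, rep("A", 6))
  spec <- hier_spec(mp$assignment, "shared", "shared")
  for (sg in c(0.2, 0.5, 1)) {
    got <- marginal_loglik(mp$profiles, spec, mu = 0.3, sigma = sg)
    want <- sum(0.5 * log(v / (v + sg^2)) - (m - 0.3)^2 / (2 * (v + sg^2)))
    expect_equal(got, want, tolerance = 1e-4)
  }
  # sigma = 0 collapses exactly to the profile sum
  got0 <- marginal_loglik(mp$profiles, spec, mu = 0.3, sigma = 0)
  expect_equal(got0, sum(-(0.3 - m)^2 / (2 * v)), tolerance = 1e-6)
  # doubling quadrature nodes changes nothing appreciable
  g32 <- marginal_loglik(mp$profiles, spec, 0.3, 0.5, gh_nodes = 32)
  g64 <- marginal_loglik(mp$profiles, spec, 0.3, 0.5, gh_nodes = 64)
  expect_lt(abs(g64 - g32), 1e-6)
})

test_that("hierarchical fit recovers conjugate and degenerate solutions", {
  set.seed(13)
  m <- rnorm(8, -0.5, 0.9); v <- 0.3
  mp <- make_profiles(m, v, rep("A", 8))
  spec <- hier_spec(mp$assignment, "shared", "shared")
  fit <- fit_hier(mp$profiles, spec)
  muhat <- mean(m); s2 <- max(mean((m - muhat)^2) - v, 0)
  expect_equal(fit$mu[[1]], muhat, tolerance = 1e-3)
  expect_equal(fit$sigma[[1]], sqrt(s2), tolerance = 1e-2)
  # small v: sigma_hat approaches the spread of the centres (the quadrature
  # needs profiles no narrower than the node spacing, so v stays moderate)
  mp0 <- make_profiles(m, 0.05, rep("A", 8))
  fit0 <- fit_hier(mp0$profiles, spec)
  expect_lt(abs(fit0$sigma[[1]] - sqrt(mean((m - muhat)^2) - 0.05)), 0.05)
  # single sharply peaked profile: mu at its centre, sigma at the floor
  mp1 <- make_profiles(-0.2, 1e-4, "A")
  f1 <- fit_hier(mp1$profiles, hier_spec(mp1$assignment, "by_group", "by_group"))
  expect_equal(f1$mu[[1]], -0.2, tolerance = 1e-2)
  expect_true(f1$sigma_boundary[[1]])
})

test_that("nested fits never beat the full model", {
  set.seed(23)
  for (rep in 1:5) {
    m <- rnorm(8, rnorm(1), 0.6)
    mp <- make_profiles(m, 0.2, rep(c("A", "B"), each = 4))
    full <- fit_hier(mp$profiles, hier_spec(mp$assignment, "by_group", "shared"))
    con <- fit_hier(mp$profiles, hier_spec(mp$assignment, "shared", "shared"))
    expect_gte(full$loglik, con$loglik - 1e-6)
    con0 <- fit_hier(mp$profiles, hier_spec(mp$assignment, "shared", "zero"))
    expect_gte(con$loglik, con0$loglik - 1e-6)
  }
})

test_that("sigma -> 0 continuity holds at the numerical floor", {
  set.seed(29)
  mp <- make_profiles(rnorm(5, 0, 0.1), 0.15, rep("A", 5))
  spec <- hier_spec(mp$assignment, "shared", "shared")
  at_floor <- marginal_loglik(mp$profiles, spec, 0.1, 0.002)
  collapsed <- marginal_loglik(mp$profiles, spec, 0.1, 0)
  expect_lt(abs(at_floor - collapsed), 1e-4)
})

test_that("likelihood-ratio tests behave like chi-square comparisons", {
  set.seed(31)
  mp <- make_profiles(rnorm(6, 0, 0.3), 0.2, rep(c("A", "B"), each = 3))
  f <- fit_hier(mp$profiles, hier_spec(mp$assignment, "by_group", "zero"))
  expect_error(lrt(f, fit_hier(mp$profiles, hier_spec(mp$assignment, "by_group", "shared"))),
               "nested")
  same <- lrt(f, f)
  expect_equal(same$deviance, 0)
  expect_equal(same$df, 0)
  # a deviance of 4.68 on 1 df sits just under 0.05
  expect_equal(pchisq(4.68, 1, lower.tail = FALSE), 0.0305, tolerance = 2e-3)
  con <- fit_hier(mp$profiles, hier_spec(mp$assignment, "shared", "zero"))
  lt <- lrt(f, con)
  expect_equal(lt$df, 1)
  expect_equal(lt$p_value, pchisq(lt$deviance, 1, lower.tail = FALSE))
})

test_that("group means are recovered from separated two-group profiles", {
  set.seed(37)
  m <- c(rnorm(5, qlogis(0.25), 0.05), rnorm(5, qlogis(0.40), 0.05))
  mp <- make_profiles(m, 0.02, rep(c("MET", "NONMET"), each = 5))
  lad <- ecotype_pipeline(mp$profiles, mp$assignment)
  rates <- lad$group_rates
  expect_equal(rates$s[rates$group == "MET"], 0.25, tolerance = 0.03)
  expect_equal(rates$s[rates$group == "NONMET"], 0.40, tolerance = 0.03)
  expect_lt(lad$tests$p_value[lad$tests$comparison == "equal means (s.d. = 0)"], 0.05)
  expect_true(all(lad$tests$deviance >= 0))
  # CIs contain the point estimates
  expect_true(all(rates$ci_lo <= rates$s & rates$s <= rates$ci_hi))
})

test_that("among-population spread is recovered when present", {
  # five populations give a chi-square(4)-spread spread estimate: the
  # conjugate rate of landing in [0.2, 0.9] at true 0.5 is about 0.82
  set.seed(43)
  hits <- 0L
  for (rep in 1:20) {
    m <- rnorm(5, 0, 0.5)
    mp <- make_profiles(m, 0.05, rep("A", 5))
    f <- fit_hier(mp$profiles, hier_spec(mp$assignment, "shared", "shared"),
                  n_starts = 2)
    if (f$sigma[[1]] >= 0.2 && f$sigma[[1]] <= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})

test_that("seasonal profiles from one constant rate stay non-significant", {
  set.seed(47)
  p_vals <- vapply(1:20, function(i) {
    m <- rnorm(4, qlogis(0.3), 0.12)  # four seasons, one underlying rate
    mp <- make_profiles(m, 0.015, paste0("season", 1:4))
    f_by <- fit_hier(mp$profiles, hier_spec(mp$assignment, "by_group", "zero"))
    f_1 <- fit_hier(mp$profiles, hier_spec(mp$assignment, "shared", "zero"))
    lt <- lrt(f_by, f_1)
    expect_equal(lt$df, 3)
    lt$p_value
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.9)
})
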