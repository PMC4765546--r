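#' Specification of the hierarchical logit-normal selfing model
#'
#' Population selfing rates are modelled as logit-normal random effects
#' within groups (typically the two ecotypes): `logit(s_i) ~ N(mu_g, sigma_g)`
#' for population `i` in group `g`. The mean structure may estimate one `mu`
#' per group or a single shared `mu`; the standard-deviation structure may be
#' per group, shared, or fixed at zero (all populations of a group share one
#' selfing rate). Fixed numeric values may also be supplied.
#'
#' @param assignment named character vector mapping population names to group
#'   labels.
#' @param mean one of `"by_group"`, `"shared"`, or a named numeric vector of
#'   fixed logit-scale means.
#' @param sd one of `"by_group"`, `"shared"`, `"zero"`, or a fixed numeric.
#' @return list of class `hier_spec`.
#' @export
hier_spec <- function(assignment, mean = "by_group", sd = "by_group") {
  stopifnot(!is.null(names(assignment)))
  groups <- sort(unique(unname(assignment)))
  if (is.character(mean)) mean <- match.arg(mean, c("by_group", "shared"))
  if (is.character(sd)) sd <- match.arg(sd, c("by_group", "shared", "zero"))
  structure(list(assignment = assignment, groups = groups,
                 mean = mean, sd = sd),
            class = "hier_spec")
}

n_free_params <- function(spec) {
  G <- length(spec$groups)
  p <- 0L
  if (is.character(spec$mean)) p <- p + if (spec$mean == "by_group") G else 1L
  if (is.character(spec$sd) && spec$sd != "zero")
    p <- p + if (spec$sd == "by_group") G else 1L
  p
}

# expand mu/sigma to per-population vectors
expand_params <- function(spec, mu, sigma) {
  g <- spec$assignment
  G <- spec$groups
  mu_g <- if (length(mu) == 1L) stats::setNames(rep(mu, length(G)), G)
          else mu[G]
  sg_g <- if (length(sigma) == 1L) stats::setNames(rep(sigma, length(G)), G)
          else sigma[G]
  list(mu = stats::setNames(mu_g[g], names(g)),
       sigma = stats::setNames(sg_g[g], names(g)))
}

#' Marginal log-likelihood of the hierarchical model
#'
#' Combines population likelihood profiles with the logit-normal random
#' effect: `ln L = sum_i ln int exp(l_i(plogis(z))) phi(z; mu_g(i), sigma_g(i)) dz`,
#' computed by Gauss-Hermite quadrature (64 nodes by default) with spline
#' interpolation of each profile between its grid points. `sigma = 0`
#' collapses exactly to the profile sum at `s = plogis(mu)`.
#'
#' @param profiles named list of `selfing_profile` objects (names must match
#'   the populations of the spec's assignment).
#' @param spec a [hier_spec()].
#' @param mu group means on the logit scale (single value if shared, or a
#'   named vector by group).
#' @param sigma group standard deviations (same shape convention; `0` allowed).
#' @param gh_nodes number of Gauss-Hermite nodes.
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(profiles, spec, mu, sigma, gh_nodes = 64L) {
  stopifnot(inherits(spec, "hier_spec"))
  pops <- names(spec$assignment)
  if (!all(pops %in% names(profiles))) stop("profiles missing for some populations")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  par <- expand_params(spec, mu, sigma)
  gh <- pracma::gaussHermite(gh_nodes)
  total <- 0
  for (p in pops) {
    pr <- profiles[[p]]
    m <- par$mu[[p]]; sg <- par$sigma[[p]]
    if (sg == 0) {
      s <- stats::plogis(m)
      if (s < pr$grid[1L] || s > pr$grid[length(pr$grid)])
        warning("group mean outside profile support; boundary value used")
      total <- total + suppressWarnings(profile_loglik(pr, s))
    } else {
      z <- m + sqrt(2) * sg * gh$x
      ll <- suppressWarnings(profile_loglik(pr, stats::plogis(z)))
      v <- log(gh$w) - 0.5 * log(pi) + ll
      mx <- max(v)
      total <- total + mx + log(sum(exp(v - mx)))
    }
  }
  total
}

#' Fit the hierarchical logit-normal selfing model
#'
#' Maximises the marginal likelihood over the free group means and standard
#' deviations by multi-start Nelder-Mead (derivative-free; the interpolated
#' profiles are only piecewise smooth). Standard deviations are constrained
#' to a numerical floor of 0.002; an estimate at the floor is reported as a
#' boundary (effectively zero spread among populations). Models with
#' `sd = "zero"` reduce to exact one-dimensional optimisations per group and
#' also report 95% profile-likelihood intervals for the back-transformed
#' group selfing rates.
#'
#' @param profiles named list of `selfing_profile` objects.
#' @param spec a [hier_spec()].
#' @param gh_nodes Gauss-Hermite nodes for the marginal integral.
#' @param n_starts number of optimiser starts.
#' @param sigma_floor numerical lower bound for sigma.
#' @param ci compute 95% profile-likelihood intervals for the group rates
#'   in `sd = "zero"` models (skip in large replicate studies).
#' @return object of class `hier_fit`: `mu`, `sigma`, `mean_selfing` (the
#'   back-transformed group medians), `loglik`, `n_par`, `convergence`,
#'   `sigma_boundary`, optional `group_ci`.
#' @export
fit_hier <- function(profiles, spec, gh_nodes = 64L, n_starts = 3L,
                     sigma_floor = 0.002, ci = TRUE) {
  stopifnot(inherits(spec, "hier_spec"))
  G <- spec$groups
  pops <- names(spec$assignment)
  s_hat <- vapply(profiles[pops], function(p) p$s_hat, 0)
  s_hat <- pmin(pmax(s_hat, 1e-3), 1 - 1e-3)
  z_hat <- stats::qlogis(s_hat)

  if (identical(spec$sd, "zero")) {
    # exact per-group (or global) 1-D maximisation on the profile sum
    obj1 <- function(mu, pops_g) sum(vapply(pops_g, function(p)
      suppressWarnings(profile_loglik(profiles[[p]], stats::plogis(mu))), 0))
    lims <- c(-12, stats::qlogis(0.9985))
    if (identical(spec$mean, "shared")) {
      o <- stats::optimize(obj1, lims, pops_g = pops, maximum = TRUE, tol = 1e-7)
      mu <- stats::setNames(rep(o$maximum, length(G)), G)
      ll <- o$objective
    } else {
      mu <- stats::setNames(numeric(length(G)), G)
      ll <- 0
      for (g in G) {
        pg <- pops[spec$assignment == g]
        o <- stats::optimize(obj1, lims, pops_g = pg, maximum = TRUE, tol = 1e-7)
        mu[g] <- o$maximum; ll <- ll + o$objective
      }
    }
    cis <- if (!ci) NULL else lapply(stats::setNames(G, G), function(g) {
      pg <- pops[spec$assignment == g]
      sgrid <- seq(0.001, 0.999, by = 0.001)
      lls <- vapply(sgrid, function(s) obj1(stats::qlogis(s), pg), 0)
      likelihood_interval(sgrid, lls, max(lls) - stats::qchisq(0.95, 1) / 2)
    })
    return(structure(list(spec = spec, mu = mu,
                          sigma = stats::setNames(rep(0, length(G)), G),
                          mean_selfing = stats::plogis(mu),
                          loglik = ll, n_par = n_free_params(spec),
                          convergence = TRUE, sigma_boundary = stats::setNames(rep(TRUE, length(G)), G),
                          group_ci = cis),
                     class = "hier_fit"))
  }

  nmu <- if (identical(spec$mean, "shared")) 1L else length(G)
  nsg <- if (identical(spec$sd, "shared")) 1L else length(G)
  unpack <- function(th) {
    mu <- th[seq_len(nmu)]
    u <- th[nmu + seq_len(nsg)]
    sigma <- sigma_floor + u^2
    if (nmu > 1L) names(mu) <- G
    if (nsg > 1L) names(sigma) <- G
    list(mu = mu, sigma = sigma)
  }
  negll <- function(th) {
    p <- unpack(th)
    -marginal_loglik(profiles, spec, p$mu, p$sigma, gh_nodes = gh_nodes)
  }
  mu0 <- if (nmu == 1L) mean(z_hat) else
    vapply(G, function(g) mean(z_hat[spec$assignment == g]), 0)
  sd0 <- if (nsg == 1L) stats::sd(z_hat) else
    vapply(G, function(g) stats::sd(z_hat[spec$assignment == g]), 0)
  sd0[!is.finite(sd0) | sd0 < 0.05] <- 0.05
  # deterministic start grid: moment start plus fixed perturbations (keeps
  # fits byte-reproducible; no RNG is consumed)
  offsets <- c(0, -0.4, 0.4, -0.8, 0.8)
  scales <- c(1, 2, 0.5, 3, 0.25)
  starts <- lapply(seq_len(max(1L, n_starts)), function(k)
    c(mu0 + offsets[(k - 1L) %% length(offsets) + 1L],
      sqrt(pmax(sd0 * scales[(k - 1L) %% length(scales) + 1L] - sigma_floor, 1e-4))))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # Nelder-Mead benefits from one restart at the incumbent optimum
  o <- stats::optim(best$par, negll, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  if (o$value < best$value) best <- o
  if (best$convergence != 0) stop("hierarchical fit did not converge; trace: ",
                                  paste(signif(best$par, 4), collapse = ", "))
  p <- unpack(best$par)
  sgv <- if (nsg == 1L) stats::setNames(rep(p$sigma, length(G)), G) else p$sigma
  muv <- if (nmu == 1L) stats::setNames(rep(p$mu, length(G)), G) else p$mu
  loglik <- -best$value
  boundary <- sgv <= sigma_floor + 1e-4
  if (all(boundary)) {
    # at the floor the quadrature can sit a hair below the sigma = 0 limit;
    # the supremum of the model is the collapsed fit, so adopt it when better
    zf <- fit_hier(profiles, hier_spec(spec$assignment, spec$mean, "zero"), ci = FALSE)
    if (zf$loglik > loglik) {
      muv <- zf$mu[G]; sgv <- stats::setNames(rep(0, length(G)), G)
      loglik <- zf$loglik
    }
  }
  structure(list(spec = spec, mu = muv, sigma = sgv,
                 mean_selfing = stats::plogis(muv),
                 loglik = loglik, n_par = n_free_params(spec),
                 convergence = TRUE,
                 sigma_boundary = boundary,
                 group_ci = NULL),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("hier_fit: logit-normal selfing model\n")
  for (g in x$spec$groups)
    cat(sprintf("  %s: mu = %.3f (s = %.3f), sigma = %.4f%s\n", g, x$mu[[g]],
                x$mean_selfing[[g]], x$sigma[[g]],
                if (isTRUE(x$sigma_boundary[[g]])) " [~0]" else ""))
  cat(sprintf("  logLik %.4f (%d free parameters)\n", x$loglik, x$n_par))
  invisible(x)
}

#' Likelihood-ratio test between nested hierarchical fits
#'
#' @param full,constrained `hier_fit` objects; the constrained spec must be
#'   nested in the full spec.
#' @return list of class `hier_lrt`: `deviance` (2 delta lnL, clipped at 0),
#'   `df`, `p_value` (chi-square upper tail).
#' @export
lrt <- function(full, constrained) {
  stopifnot(inherits(full, "hier_fit"), inherits(constrained, "hier_fit"))
  if (!is_nested(constrained$spec, full$spec))
    stop("constrained spec is not nested in the full spec")
  df <- full$n_par - constrained$n_par
  dev <- 2 * (full$loglik - constrained$loglik)
  if (dev < -1e-6 - 1e-8 * abs(full$loglik))
    warning("constrained fit exceeds full fit beyond numerical tolerance")
  dev <- max(dev, 0)
  p <- if (df > 0) stats::pchisq(dev, df, lower.tail = FALSE) else NA_real_
  structure(list(deviance = dev, df = df, p_value = p), class = "hier_lrt")
}

#' @export
print.hier_lrt <- function(x, ...) {
  cat(sprintf("LRT: deviance %.3f, df %d, p = %.4g\n", x$deviance, x$df, x$p_value))
  invisible(x)
}

mean_rank <- function(m) if (identical(m, "shared")) 1L else 2L
sd_rank <- function(s) switch(s, zero = 1L, shared = 2L, by_group = 3L)

is_nested <- function(con, full) {
  identical(con$assignment, full$assignment) &&
    mean_rank(con$mean) <= mean_rank(full$mean) &&
    sd_rank(con$sd) <= sd_rank(full$sd)
}

#' Model ladder comparing selfing-rate distributions between groups
#'
#' Fits the ladder of hierarchical models used to compare two ecotypes (or
#' seasons): free means and s.d. per group; free means with shared s.d.;
#' equal means with shared s.d.; then, with the among-population s.d. fixed
#' at zero, one selfing rate per group versus a single common rate. Each
#' adjacent nested pair is compared by a likelihood-ratio test against the
#' chi-square reference.
#'
#' @param profiles named list of `selfing_profile` objects.
#' @param assignment named vector mapping population to group.
#' @param gh_nodes Gauss-Hermite nodes.
#' @return list of class `hier_ladder`: `fits` (named list of `hier_fit`),
#'   `tests` (data.frame: comparison, deviance, df, p_value), and
#'   `group_rates` (per-group selfing estimates with 95% likelihood CIs from
#'   the s.d.-zero model).
#' @export
ecotype_pipeline <- function(profiles, assignment, gh_nodes = 64L) {
  groups <- unique(unname(assignment))
  if (length(groups) < 2L) stop("need at least 2 groups to compare")
  specs <- list(
    mu_g_sd_g   = hier_spec(assignment, "by_group", "by_group"),
    mu_g_sd_1   = hier_spec(assignment, "by_group", "shared"),
    mu_1_sd_1   = hier_spec(assignment, "shared", "shared"),
    mu_g_sd_0   = hier_spec(assignment, "by_group", "zero"),
    mu_1_sd_0   = hier_spec(assignment, "shared", "zero"))
  fits <- lapply(specs, function(sp) fit_hier(profiles, sp, gh_nodes = gh_nodes))
  cmp <- list(c("mu_g_sd_g", "mu_g_sd_1", "equal s.d. between groups"),
              c("mu_g_sd_1", "mu_1_sd_1", "equal means (shared s.d.)"),
              c("mu_g_sd_0", "mu_1_sd_0", "equal means (s.d. = 0)"))
  tests <- do.call(rbind, lapply(cmp, function(cc) {
    lt <- lrt(fits[[cc[1L]]], fits[[cc[2L]]])
    data.frame(comparison = cc[3L], full = cc[1L], constrained = cc[2L],
               loglik_full = fits[[cc[1L]]]$loglik,
               loglik_constrained = fits[[cc[2L]]]$loglik,
               deviance = lt$deviance, df = lt$df, p_value = lt$p_value,
               stringsAsFactors = FALSE)
  }))
  f0 <- fits$mu_g_sd_0
  group_rates <- data.frame(group = f0$spec$groups,
                            s = unname(f0$mean_selfing[f0$spec$groups]),
                            ci_lo = vapply(f0$group_ci, `[`, 0, 1L),
                            ci_hi = vapply(f0$group_ci, `[`, 0, 2L),
                            stringsAsFactors = FALSE)
  structure(list(fits = fits, tests = tests, group_rates = group_rates),
            class = "hier_ladder")
}

#' @export
print.hier_ladder <- function(x, ...) {
  cat("hier_ladder model comparisons:\n")
  print(x$tests[, c("comparison", "deviance", "df", "p_value")], row.names = FALSE)
  cat("group selfing rates (s.d. = 0 model):\n")
  print(x$group_rates, row.names = FALSE)
  invisible(x)
}
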