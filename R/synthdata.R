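#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' generators are pure functions of (configuration, seed).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for the study-shaped synthetic data set
#'
#' Defaults emulate a two-ecotype, ten-population microsatellite survey:
#' 5 + 5 populations, 45 plants each, 14 loci with 6 alleles per locus,
#' ecotype mean selfing rates 0.25 and 0.40 with zero among-population spread
#' on the logit scale, population divergence theta 0.25 (Balding-Nichols),
#' no ecotype-level divergence, progeny arrays of 20 mothers x 15 seeds, and
#' two consecutive seasonal samples linked by Wright-Fisher drift at Ne 100.
#'
#' @param seed integer seed driving every stochastic choice.
#' @param n_pop_per_ecotype populations per ecotype.
#' @param ecotypes the two group labels.
#' @param n_ind individuals sampled per population.
#' @param n_loci,n_alleles locus count and alleles per locus.
#' @param mu_s per-ecotype mean selfing rate (natural scale; logit applied
#'   internally).
#' @param sigma_logit per-ecotype s.d. of logit selfing rate.
#' @param theta_pop Balding-Nichols divergence of populations from the base
#'   frequencies.
#' @param theta_ecotype optional ecotype-level divergence (default 0).
#' @param dropout per-locus null-allele frequency (scalar recycled, or vector;
#'   0 disables).
#' @param n_families,progeny_per_family progeny-array design.
#' @param t_m,r_t,r_p,F_p mixed-mating generating parameters: multilocus
#'   outcrossing rate, correlation of selfing, correlation of paternity,
#'   paternal inbreeding.
#' @param Ne,generations temporal design: effective size and generations
#'   between the two seasonal samples.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pop_per_ecotype = 5L,
                       ecotypes = c("MET", "NONMET"), n_ind = 45L,
                       n_loci = 14L, n_alleles = 6L,
                       mu_s = c(MET = 0.25, NONMET = 0.40),
                       sigma_logit = c(MET = 0, NONMET = 0),
                       theta_pop = 0.25, theta_ecotype = 0,
                       dropout = 0,
                       n_families = 20L, progeny_per_family = 15L,
                       t_m = 0.75, r_t = 0.10, r_p = 0.30, F_p = 0.10,
                       Ne = 100, generations = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Dirichlet draw
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

# random base frequencies for n_loci loci
sim_base_freqs <- function(n_loci, n_alleles, concentration = 1) {
  lapply(seq_len(n_loci), function(l) {
    f <- rdirichlet1(rep(concentration, n_alleles))
    names(f) <- seq_len(n_alleles)
    f
  })
}

#' Simulate one partially selfing population
#'
#' Each individual carries a latent count `n` of consecutive selfing
#' generations since its last outbred ancestor, drawn geometric with
#' parameter `s`; the genotype starts as an outbred Hardy-Weinberg draw and
#' passes through `n` rounds of Mendelian selfing. Null alleles emulate
#' allele-specific non-amplification: at a locus with `dropout > 0` an extra
#' null allele of that frequency segregates; heterozygotes carrying it appear
#' homozygous for their other allele and null homozygotes are missing.
#'
#' @param base_freqs list of per-locus named allele-frequency vectors.
#' @param s selfing rate in `[0, 1)`.
#' @param n number of individuals.
#' @param dropout per-locus null-allele frequency (scalar or vector).
#' @param pop,ecotype,year,lat,lon metadata passed to [genotype_matrix()].
#' @param seed optional seed.
#' @return a [genotype_matrix()]; attribute `truth` records `s`, the selfing
#'   generation counts, and any null-allele labels.
#' @export
sim_population <- function(base_freqs, s, n, dropout = 0, pop = "pop1",
                           ecotype = NA_character_, year = NA,
                           lat = NA_real_, lon = NA_real_, seed = NULL) {
  with_seed(seed, {
    L <- length(base_freqs)
    dropout <- rep_len(dropout, L)
    null_lab <- rep(NA_integer_, L)
    freqs <- base_freqs
    for (l in seq_len(L)) {
      if (dropout[l] > 0) {
        f <- freqs[[l]] * (1 - dropout[l])
        nl <- max(as.integer(names(freqs[[l]]))) + 1L
        f <- c(f, stats::setNames(dropout[l], nl))
        freqs[[l]] <- f
        null_lab[l] <- nl
      }
    }
    ngen <- pmin(stats::rgeom(n, prob = 1 - s), 60L)
    A1 <- matrix(NA_integer_, n, L); A2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      lab <- as.integer(names(freqs[[l]]))
      A1[, l] <- sample(lab, n, replace = TRUE, prob = freqs[[l]])
      A2[, l] <- sample(lab, n, replace = TRUE, prob = freqs[[l]])
    }
    gmax <- max(ngen, 0L)
    if (gmax > 0L) for (g in seq_len(gmax)) {
      act <- ngen >= g
      if (!any(act)) break
      m <- sum(act)
      u1 <- matrix(stats::runif(m * L) < 0.5, m, L)
      u2 <- matrix(stats::runif(m * L) < 0.5, m, L)
      a1 <- A1[act, , drop = FALSE]; a2 <- A2[act, , drop = FALSE]
      A1[act, ] <- ifelse(u1, a1, a2)
      A2[act, ] <- ifelse(u2, a1, a2)
    }
    # apply null-allele masking
    for (l in which(!is.na(null_lab))) {
      nl <- null_lab[l]
      both <- A1[, l] == nl & A2[, l] == nl
      one1 <- A1[, l] == nl & !both
      one2 <- A2[, l] == nl & !both
      A1[one1, l] <- A2[one1, l]
      A2[one2, l] <- A1[one2, l]
      A1[both, l] <- NA_integer_; A2[both, l] <- NA_integer_
    }
    calls <- array(NA_integer_, dim = c(n, L, 2L))
    calls[, , 1L] <- A1; calls[, , 2L] <- A2
    g <- genotype_matrix(calls, loci = names(base_freqs) %||% paste0("L", seq_len(L)),
                         pop = pop, ecotype = ecotype, year = year,
                         lat = lat, lon = lon)
    attr(g, "truth") <- list(s = s, ngen = ngen, null_allele = null_lab)
    g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the full two-ecotype metapopulation
#'
#' Population allele frequencies are drawn around shared base frequencies by
#' the Balding-Nichols model (Dirichlet with concentration
#' `(1 - theta)/theta`), optionally through an intermediate ecotype level;
#' population selfing rates are logit-normal within ecotype. Populations are
#' placed at random coordinates inside a ~40 km box so that geographic
#' analyses have distances to work with.
#'
#' @param cfg a [sim_config()].
#' @return list with `pops` (named list of [genotype_matrix()]), and `truth`
#'   (base/population frequencies, per-population selfing rates, assignment).
#' @export
sim_metapopulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_pop <- 2L * cfg$n_pop_per_ecotype
    eco <- rep(cfg$ecotypes, each = cfg$n_pop_per_ecotype)
    pop_names <- paste0(rep(cfg$ecotypes, each = cfg$n_pop_per_ecotype),
                        rep(seq_len(cfg$n_pop_per_ecotype), 2L))
    base <- sim_base_freqs(cfg$n_loci, cfg$n_alleles)
    names(base) <- paste0("L", seq_len(cfg$n_loci))
    s_true <- stats::setNames(numeric(n_pop), pop_names)
    lat <- stats::setNames(43.9 + stats::runif(n_pop, 0, 0.36), pop_names)
    lon <- stats::setNames(3.5 + stats::runif(n_pop, 0, 0.50), pop_names)
    pops <- list(); pop_freqs <- list()
    eco_base <- list()
    for (e in cfg$ecotypes) {
      eco_base[[e]] <- if (cfg$theta_ecotype > 0) {
        lapply(base, function(f) {
          d <- rdirichlet1(f * (1 - cfg$theta_ecotype) / cfg$theta_ecotype)
          names(d) <- names(f); d
        })
      } else base
    }
    for (i in seq_len(n_pop)) {
      fb <- eco_base[[eco[i]]]
      fi <- if (cfg$theta_pop > 0) {
        lapply(fb, function(f) {
          d <- rdirichlet1(f * (1 - cfg$theta_pop) / cfg$theta_pop)
          names(d) <- names(f); d
        })
      } else fb
      mu <- stats::qlogis(cfg$mu_s[[eco[i]]])
      sd_e <- cfg$sigma_logit[[eco[i]]]
      s_i <- stats::plogis(stats::rnorm(1, mu, sd_e))
      s_true[i] <- s_i
      pops[[pop_names[i]]] <- sim_population(
        fi, s_i, cfg$n_ind, dropout = cfg$dropout, pop = pop_names[i],
        ecotype = eco[i], year = 1L, lat = lat[i], lon = lon[i])
      pop_freqs[[pop_names[i]]] <- fi
    }
    list(pops = pops,
         truth = list(s = s_true, ecotype = stats::setNames(eco, pop_names),
                      base_freqs = base, pop_freqs = pop_freqs,
                      lat = lat, lon = lon))
  })
}

#' Simulate progeny arrays under the correlated mixed-mating model
#'
#' Mothers are drawn from the base frequencies at inbreeding
#' `F_m = equilibrium_fis(1 - t_m)`. Each family draws a shared-selfing class
#' (probability `r_t`: one Bernoulli outcrossing draw for the whole sibship)
#' and a shared-father class (probability `r_p`: all outcrossed sibs receive
#' gametes from one father, whose genotype follows the pollen frequencies at
#' inbreeding `F_p`); otherwise draws are independent per progeny.
#'
#' @param cfg a [sim_config()]; the family-design fields are used.
#' @param base_freqs optional per-locus frequencies (default drawn from cfg).
#' @param known_mother store the maternal genotypes (TRUE) or strip them.
#' @param seed optional override of `cfg$seed`.
#' @return list with `arrays` (a [progeny_array_set()]) and `truth`
#'   (per-family selfing flags and father assignments).
#' @export
sim_progeny_arrays <- function(cfg, base_freqs = NULL, known_mother = TRUE,
                               seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed %||% cfg$seed, {
    L <- cfg$n_loci
    if (is.null(base_freqs)) {
      base_freqs <- sim_base_freqs(L, cfg$n_alleles)
      names(base_freqs) <- paste0("L", seq_len(L))
    }
    loci <- names(base_freqs)
    t_m <- cfg$t_m; F_m <- equilibrium_fis(1 - t_m)
    kvec <- rep_len(cfg$progeny_per_family, cfg$n_families)
    draw_geno <- function(Fcoef) {
      # one multilocus genotype at inbreeding Fcoef: 2 x L matrix
      vapply(base_freqs, function(f) {
        lab <- as.integer(names(f))
        a1 <- sample(lab, 1L, prob = f)
        a2 <- if (stats::runif(1) < Fcoef) a1 else sample(lab, 1L, prob = f)
        c(a1, a2)
      }, integer(2L))
    }
    fams <- list(); truth <- list()
    father_id <- 0L
    for (fi in seq_len(cfg$n_families)) {
      k <- kvec[fi]
      mother <- draw_geno(F_m)
      shared_self <- stats::runif(1) < cfg$r_t
      selfed <- if (shared_self) rep(stats::runif(1) < (1 - t_m), k)
                else stats::runif(k) < (1 - t_m)
      shared_father <- stats::runif(1) < cfg$r_p
      fathers <- vector("list", k); fids <- integer(k)
      if (shared_father) {
        father_id <- father_id + 1L
        fg <- draw_geno(cfg$F_p)
        for (j in which(!selfed)) { fathers[[j]] <- fg; fids[j] <- father_id }
      } else {
        for (j in which(!selfed)) {
          father_id <- father_id + 1L
          fathers[[j]] <- draw_geno(cfg$F_p); fids[j] <- father_id
        }
      }
      calls <- array(NA_integer_, dim = c(k, L, 2L))
      for (j in seq_len(k)) {
        mg <- mother[cbind(1L + (stats::runif(L) < 0.5), seq_len(L))]
        pg <- if (selfed[j]) mother[cbind(1L + (stats::runif(L) < 0.5), seq_len(L))]
              else fathers[[j]][cbind(1L + (stats::runif(L) < 0.5), seq_len(L))]
        calls[j, , 1L] <- mg; calls[j, , 2L] <- pg
      }
      prog <- genotype_matrix(calls, individuals = paste0("f", fi, "_p", seq_len(k)),
                              loci = loci, pop = "sim", year = 1L)
      fams[[paste0("fam_", fi)]] <- list(
        mother = if (known_mother) mother else NULL, progeny = prog)
      truth[[paste0("fam_", fi)]] <- list(selfed = selfed, father = fids,
                                          shared_self = shared_self,
                                          shared_father = shared_father)
    }
    list(arrays = progeny_array_set(fams, loci = loci, pop = "sim"),
         truth = list(families = truth, t_m = t_m, r_t = cfg$r_t,
                      r_p = cfg$r_p, F_p = cfg$F_p, F_m = F_m,
                      base_freqs = base_freqs))
  })
}

#' Simulate a temporal sample pair under Wright-Fisher drift
#'
#' Allele counts drift for `generations` multinomial Wright-Fisher steps at
#' size `2*Ne` gene copies; `Ne = Inf` disables drift. Each season a sample of
#' Hardy-Weinberg genotypes is drawn from the season's frequencies.
#'
#' @param cfg a [sim_config()]; `Ne` and `generations` are used.
#' @param base_freqs optional per-locus starting frequencies.
#' @param n_sample individuals sampled each season (default `cfg$n_ind`).
#' @param seed optional override.
#' @param s selfing rate of the sampled individuals (0 draws plain
#'   Hardy-Weinberg samples, the temporal estimator's nominal sampling
#'   model; a positive rate reproduces the heterozygote deficit real
#'   seasonal samples of a selfing population carry).
#' @return list with `pair` (a [temporal_pair()]) and `truth`.
#' @export
sim_temporal <- function(cfg, base_freqs = NULL, n_sample = NULL, seed = NULL,
                         s = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed %||% cfg$seed, {
    L <- cfg$n_loci
    if (is.null(base_freqs)) {
      base_freqs <- sim_base_freqs(L, cfg$n_alleles)
      names(base_freqs) <- paste0("L", seq_len(L))
    }
    S <- n_sample %||% cfg$n_ind
    f0 <- base_freqs
    fg <- f0
    if (is.finite(cfg$Ne)) {
      m <- 2L * as.integer(cfg$Ne)
      for (gen in seq_len(cfg$generations)) {
        fg <- lapply(fg, function(f) {
          cnt <- stats::rmultinom(1L, m, f)[, 1L]
          stats::setNames(cnt / m, names(f))
        })
      }
    }
    draw_sample <- function(freqs, n, year) {
      if (s > 0) {
        g <- sim_population(freqs, s, n, pop = "sim", year = year)
        g$loci <- names(base_freqs)
        return(g)
      }
      calls <- array(NA_integer_, dim = c(n, L, 2L))
      for (l in seq_len(L)) {
        lab <- as.integer(names(freqs[[l]]))
        calls[, l, 1L] <- sample(lab, n, replace = TRUE, prob = freqs[[l]])
        calls[, l, 2L] <- sample(lab, n, replace = TRUE, prob = freqs[[l]])
      }
      genotype_matrix(calls, loci = names(base_freqs), pop = "sim", year = year)
    }
    s0 <- draw_sample(f0, S, 1L)
    s1 <- draw_sample(fg, S, 2L)
    list(pair = temporal_pair(s0, s1, cfg$generations),
         truth = list(Ne = cfg$Ne, g = cfg$generations,
                      freqs0 = f0, freqs_g = fg))
  })
}

#' Synthetic selfing profiles with analytically known shape
#'
#' Quadratic log-likelihood profiles on the logit scale,
#' `l_i(s) = -(logit(s) - m_i)^2 / (2 v)`, for exercising the hierarchical
#' model against normal-normal conjugate algebra.
#'
#' @param m vector of profile centres on the logit scale.
#' @param v profile curvature parameter (variance of the implied likelihood).
#' @param grid_step grid spacing.
#' @return list of `selfing_profile` objects.
#' @export
sim_profiles <- function(m, v, grid_step = 0.001) {
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  lapply(m, function(mi) {
    z <- stats::qlogis(grid)
    ll <- -(z - mi)^2 / (2 * v)
    best <- which.max(ll)
    out <- structure(list(grid = grid, loglik = ll, s_hat = grid[best],
                          loglik_max = ll[best],
                          ci95 = likelihood_interval(grid, ll, ll[best] - 1.92),
                          h_hat = NULL, n_individuals = NA_integer_,
                          n_loci = NA_integer_, boundary = FALSE),
                     class = "selfing_profile")
    attr(out, ".spline") <- stats::splinefun(grid, ll, method = "natural")
    out
  })
}
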