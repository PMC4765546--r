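#' Mixed-mating model parameters
#'
#' Parameter bundle for the correlated mixed-mating model: multilocus
#' outcrossing rate `t_m` (selfing rate `s_m = 1 - t_m`), correlation of
#' selfing `r_t` (probability that a whole sibship shares one selfing draw),
#' correlation of paternity `r_p` (probability that the outcrossed sibship
#' shares one father), paternal inbreeding `F_p`, and optionally the maternal
#' inbreeding `F_m` used as prior when the mother is marginalised (default:
#' the selfing equilibrium `equilibrium_fis(1 - t_m)`).
#'
#' @param t_m,r_t,r_p,F_p model parameters in `[0, 1]`.
#' @param F_m maternal inbreeding for the marginalised-mother prior.
#' @return list of class `mating_params`.
#' @export
mating_params <- function(t_m, r_t = 0, r_p = 0, F_p = 0, F_m = NULL) {
  stopifnot(t_m >= 0, t_m <= 1, r_t >= 0, r_t <= 1, r_p >= 0, r_p <= 1,
            F_p >= 0, F_p <= 1)
  if (is.null(F_m)) F_m <- equilibrium_fis(1 - t_m)
  structure(list(t_m = t_m, r_t = r_t, r_p = r_p, F_p = F_p, F_m = F_m),
            class = "mating_params")
}

# pollen/ovule allele frequencies from the arrays (gene-copy counts over
# progeny and known mothers); observed alleles absent from user-supplied
# frequencies are smoothed by one gene copy
mating_freqs <- function(arrays, freqs = NULL) {
  L <- length(arrays$loci)
  obs <- vector("list", L)
  for (l in seq_len(L)) {
    a <- unlist(lapply(arrays$families, function(fam) {
      c(fam$progeny$calls[, l, ], if (!is.null(fam$mother)) fam$mother[, l])
    }))
    a <- a[!is.na(a)]
    obs[[l]] <- table(a)
  }
  if (is.null(freqs)) {
    out <- lapply(obs, function(tb) {
      f <- as.numeric(tb) / sum(tb); names(f) <- names(tb); f
    })
  } else {
    stopifnot(length(freqs) == L)
    out <- vector("list", L)
    for (l in seq_len(L)) {
      f <- freqs[[l]]
      missing_alleles <- setdiff(names(obs[[l]]), names(f))
      if (length(missing_alleles)) {
        message("locus ", arrays$loci[l], ": ", length(missing_alleles),
                " observed allele(s) absent from supplied frequencies; ",
                "smoothed by one gene copy each")
        n_eq <- sum(obs[[l]])
        f <- c(f * n_eq, stats::setNames(rep(1, length(missing_alleles)),
                                         missing_alleles))
        f <- f / sum(f)
      }
      out[[l]] <- f
    }
  }
  names(out) <- arrays$loci
  out
}

# recode arrays to 1-based per-locus allele indices for the C++ tables
progeny_recode <- function(arrays, freqs) {
  L <- length(arrays$loci)
  labs <- lapply(freqs, names)
  fams <- lapply(arrays$families, function(fam) {
    k <- n_ind(fam$progeny)
    geno <- matrix(0L, k, 2L * L)
    for (l in seq_len(L)) {
      geno[, 2L * l - 1L] <- match(as.character(fam$progeny$calls[, l, 1L]), labs[[l]])
      geno[, 2L * l] <- match(as.character(fam$progeny$calls[, l, 2L]), labs[[l]])
    }
    geno[is.na(geno)] <- 0L
    mother <- integer(2L * L)
    if (!is.null(fam$mother)) {
      for (l in seq_len(L)) {
        m <- match(as.character(fam$mother[, l]), labs[[l]])
        if (!anyNA(m)) {
          mother[2L * l - 1L] <- min(m); mother[2L * l] <- max(m)
        }
      }
    }
    list(geno = geno, mother = mother)
  })
  list(families = fams, freq_vectors = lapply(freqs, unname))
}

progeny_tables <- function(arrays, freqs) {
  rc <- progeny_recode(arrays, freqs)
  tabs <- .progeny_build_tables_cpp(rc$families, rc$freq_vectors)
  for (f in seq_along(tabs)) {
    bad <- tabs[[f]]$bad
    if (any(bad == 1L)) {
      w <- which(bad == 1L, arr.ind = TRUE)[1L, ]
      fam <- arrays$families[[f]]
      stop(sprintf(
        "progeny genotype impossible under the model: family %s, locus %s, individual %s",
        names(arrays$families)[f], arrays$loci[w[2L]],
        fam$progeny$individuals[w[1L]]))
    }
  }
  tabs
}

#' Exact log-likelihood of one progeny family
#'
#' Full-family likelihood of the correlated mixed-mating model, marginalising
#' exactly over the latent classes (shared vs independent selfing draw,
#' shared vs independent fathers), every selfed/outcrossed configuration of
#' the sibship, the shared father's per-locus genotype, and (when unknown)
#' the maternal genotype. The configuration sum is exponential in family
#' size, so this is intended for small families and for validating the
#' composite likelihood used by [fit_mating()]; families over 16 progeny are
#' refused.
#'
#' @param family list with `progeny` (a [genotype_matrix()]) and optional
#'   `mother` (2 x L allele matrix).
#' @param params a [mating_params()].
#' @param freqs per-locus named allele-frequency vectors (pollen = ovule).
#' @param infer_mother marginalise the mother when her genotype is absent
#'   (`TRUE`, default); if `FALSE`, a missing mother is an error.
#' @return scalar log-likelihood.
#' @export
family_loglik <- function(family, params, freqs, infer_mother = TRUE) {
  stopifnot(inherits(params, "mating_params"))
  k <- n_ind(family$progeny)
  if (k > 16L) stop("exact family likelihood is exponential in family size; k > 16 refused")
  L <- dim(family$progeny$calls)[2L]
  stopifnot(length(freqs) == L)
  if (is.null(family$mother) && !infer_mother)
    stop("maternal genotype absent and infer_mother = FALSE")
  t <- params$t_m; rt <- params$r_t; rp <- params$r_p
  Fp <- params$F_p; Fm <- params$F_m
  # per locus: mother states, priors, and per-progeny S, O, B arrays
  loc <- vector("list", L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]; lab <- names(p); A <- length(p)
    gi <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
    g1 <- gi[, 1L]; g2 <- gi[, 2L]; ng <- length(g1)
    prG <- (1 - Fp) * ifelse(g1 == g2, p[g1]^2, 2 * p[g1] * p[g2]) +
      Fp * ifelse(g1 == g2, p[g1], 0)
    if (!is.null(family$mother) && !anyNA(family$mother[, l])) {
      mi <- match(as.character(family$mother[, l]), lab)
      mstates <- cbind(min(mi), max(mi)); prM <- 1
    } else {
      mstates <- cbind(g1, g2)
      prM <- (1 - Fm) * ifelse(g1 == g2, p[g1]^2, 2 * p[g1] * p[g2]) +
        Fm * ifelse(g1 == g2, p[g1], 0)
    }
    nm <- nrow(mstates)
    Ncnt <- matrix(0, nm, A)
    for (m in seq_len(nm)) {
      Ncnt[m, mstates[m, 1L]] <- Ncnt[m, mstates[m, 1L]] + 1
      Ncnt[m, mstates[m, 2L]] <- Ncnt[m, mstates[m, 2L]] + 1
    }
    NG <- matrix(0, ng, A)
    for (m in seq_len(ng)) {
      NG[m, g1[m]] <- NG[m, g1[m]] + 1
      NG[m, g2[m]] <- NG[m, g2[m]] + 1
    }
    S <- matrix(1, k, nm); O <- matrix(1, k, nm)
    B <- array(1, dim = c(k, nm, ng))
    for (j in seq_len(k)) {
      x <- match(as.character(family$progeny$calls[j, l, 1L]), lab)
      y <- match(as.character(family$progeny$calls[j, l, 2L]), lab)
      if (is.na(x)) next
      if (x == y) {
        S[j, ] <- 0.25 * Ncnt[, x]^2
        O[j, ] <- 0.5 * Ncnt[, x] * p[x]
        B[j, , ] <- 0.25 * outer(Ncnt[, x], NG[, x])
      } else {
        S[j, ] <- 0.5 * Ncnt[, x] * Ncnt[, y]
        O[j, ] <- 0.5 * (Ncnt[, x] * p[y] + Ncnt[, y] * p[x])
        B[j, , ] <- 0.25 * (outer(Ncnt[, x], NG[, y]) + outer(Ncnt[, y], NG[, x]))
      }
    }
    loc[[l]] <- list(S = S, O = O, B = B, prM = prM, prG = prG)
  }
  term <- function(selfed, shared_father) {
    # product over loci of the mother- (and father-) marginalised factor
    out <- 1
    for (l in seq_len(L)) {
      z <- loc[[l]]
      nm <- length(z$prM)
      per_m <- rep(1, nm)
      for (j in which(selfed)) per_m <- per_m * z$S[j, ]
      if (shared_father && any(!selfed)) {
        inner <- matrix(1, nm, length(z$prG))
        for (j in which(!selfed)) inner <- inner * z$B[j, , , drop = TRUE]
        if (is.null(dim(inner))) inner <- matrix(inner, nm)
        per_m <- per_m * as.vector(inner %*% z$prG)
      } else {
        for (j in which(!selfed)) per_m <- per_m * z$O[j, ]
      }
      out <- out * sum(z$prM * per_m)
    }
    out
  }
  total <- 0
  for (code in 0:(2^k - 1L)) {
    selfed <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    w_ind <- prod(ifelse(selfed, 1 - t, t))
    fa <- rp * term(selfed, TRUE) + (1 - rp) * term(selfed, FALSE)
    total <- total + (1 - rt) * w_ind * fa
    if (all(selfed)) total <- total + rt * (1 - t) * fa
    if (all(!selfed)) total <- total + rt * t * fa
  }
  log(total)
}


# Exact per-locus machinery shared by the full-likelihood tables and the
# single-locus fits: genotype enumeration, maternal transmission closed
# forms, and per-genotype shared-father transmission probabilities.
progeny_locus_terms <- function(fam, l, p, lab) {
  A <- length(p)
  gi <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
  g1 <- gi[, 1L]; g2 <- gi[, 2L]; ng <- length(g1)
  prHW <- ifelse(g1 == g2, p[g1]^2, 2 * p[g1] * p[g2])
  prHom <- ifelse(g1 == g2, p[g1], 0)
  ncnt_of <- function(a1, a2) {
    n <- numeric(A); n[a1] <- n[a1] + 1; n[a2] <- n[a2] + 1; n
  }
  NG <- matrix(0, ng, A)
  for (m in seq_len(ng)) NG[m, ] <- ncnt_of(g1[m], g2[m])
  k <- n_ind(fam$progeny)
  mi <- match(as.character(fam$mother[, l]), lab)
  if (anyNA(mi)) {
    # maternal genotype unscored at this locus: plug in the per-locus ML
    # assignment given the progeny (outcrossing-agnostic mixture)
    ll <- log(prHW)
    for (j in seq_len(k)) {
      x <- match(as.character(fam$progeny$calls[j, l, 1L]), lab)
      y <- match(as.character(fam$progeny$calls[j, l, 2L]), lab)
      if (is.na(x)) next
      pj <- vapply(seq_len(ng), function(m) {
        n <- NG[m, ]
        S <- if (x == y) 0.25 * n[x]^2 else 0.5 * n[x] * n[y]
        O <- if (x == y) 0.5 * n[x] * p[x] else 0.5 * (n[x] * p[y] + n[y] * p[x])
        0.3 * S + 0.7 * O
      }, 0)
      ll <- ll + log(pj)
    }
    mi <- c(g1[which.max(ll)], g2[which.max(ll)])
  }
  ncm <- ncnt_of(mi[1L], mi[2L])
  S <- O <- rep(1, k)
  B <- matrix(1, k, ng)
  for (j in seq_len(k)) {
    x <- match(as.character(fam$progeny$calls[j, l, 1L]), lab)
    y <- match(as.character(fam$progeny$calls[j, l, 2L]), lab)
    if (is.na(x)) next
    if (x == y) {
      S[j] <- 0.25 * ncm[x]^2
      O[j] <- 0.5 * ncm[x] * p[x]
      B[j, ] <- 0.25 * ncm[x] * NG[, x]
    } else {
      S[j] <- 0.5 * ncm[x] * ncm[y]
      O[j] <- 0.5 * (ncm[x] * p[y] + ncm[y] * p[x])
      B[j, ] <- 0.25 * (ncm[x] * NG[, y] + ncm[y] * NG[, x])
    }
    if (S[j] + O[j] <= 0)
      stop(sprintf(
        "progeny genotype impossible under the model: family %s, locus %s, individual %s",
        "<fam>", "<loc>", fam$progeny$individuals[j]))
  }
  list(S = S, O = O, B = B, prHW = prHW, prHom = prHom)
}

# Tables for the full-family likelihood (known mothers): exact per-progeny
# S/O products, exact all-outcrossed shared-father components, and seeded
# importance-sampling draws of the shared father from his per-locus
# full-outcross posterior at reference inbreeding Fp0.
progeny_full_tables <- function(arrays, fq, M = 600L, Fp0 = 0.1, seed = NULL) {
  L <- length(arrays$loci)
  with_seed(if (is.null(seed)) 1L else seed + 7L, {
    lapply(seq_along(arrays$families), function(fi) {
      fam <- arrays$families[[fi]]
      if (is.null(fam$mother))
        stop("full-likelihood tables need a maternal genotype for every family")
      k <- n_ind(fam$progeny)
      S <- O <- rep(1, k)
      PB <- matrix(1, k, M)
      HW <- HM <- matrix(1, L, M)   # locus-major for the evaluator
      LCm <- numeric(M)
      A0 <- A1 <- numeric(L)
      for (l in seq_len(L)) {
        p <- fq[[l]]; lab <- names(p)
        z <- tryCatch(progeny_locus_terms(fam, l, p, lab), error = function(e)
          stop(sub("<fam>", names(arrays$families)[fi],
                   sub("<loc>", arrays$loci[l], conditionMessage(e))), call. = FALSE))
        S <- S * z$S; O <- O * z$O
        Btil <- apply(z$B, 2L, prod)
        A0[l] <- sum(z$prHW * Btil); A1[l] <- sum(z$prHom * Btil)
        # proposal matched to the mixed selfed/outcrossed integrand at a
        # reference outcrossing rate (strictly positive on feasible data,
        # unlike the all-outcross product, which is zero whenever no single
        # father is compatible with every progeny)
        mixtil <- apply(0.3 * z$S + 0.7 * z$B, 2L, prod)
        pr0 <- (1 - Fp0) * z$prHW + Fp0 * z$prHom
        qw <- pr0 * mixtil
        Z0 <- sum(qw)
        if (Z0 <= 0) {
          # no single father is compatible with every obligate-outcrossed
          # progeny: the shared-father configuration has probability zero
          # (some progeny then has S = 0 too, so zeroing PB zeroes the term)
          idx <- sample.int(length(pr0), M, replace = TRUE, prob = pr0 / sum(pr0))
          PB <- PB * 0
          HW[l, ] <- z$prHW[idx]; HM[l, ] <- z$prHom[idx]
          next
        }
        idx <- sample.int(length(qw), M, replace = TRUE, prob = qw / Z0)
        PB <- PB * z$B[, idx, drop = FALSE]
        HW[l, ] <- z$prHW[idx]; HM[l, ] <- z$prHom[idx]
        LCm <- LCm + log(Z0) - log(pr0[idx]) - log(mixtil[idx])
      }
      list(S = S, O = O, PB = PB, HW = HW, HM = HM, LCm = LCm,
           A0 = A0, A1 = A1, k = k)
    })
  })
}

# Exact single-locus full-family log-likelihood (father genotype enumerable
# at one locus), used for the per-locus outcrossing rates t_s.
ts_full_loglik <- function(locterms, t, rt, rp, Fp, weights) {
  total <- 0
  for (f in seq_along(locterms)) {
    if (weights[f] == 0) next
    z <- locterms[[f]]
    prG <- (1 - Fp) * z$prHW + Fp * z$prHom
    base <- (1 - t) * z$S + t * z$O
    T4 <- prod(base)
    allself <- (1 - t) * prod(z$S)
    allind <- t * prod(z$O)
    mixg <- (1 - t) * z$S + t * z$B          # k x ng
    T5 <- sum(prG * exp(colSums(log(mixg))))
    allsh <- t * sum(prG * exp(colSums(log(z$B))))
    Lf <- rt * (allself + rp * allsh + (1 - rp) * allind) +
      (1 - rt) * (rp * T5 + (1 - rp) * T4)
    if (!(Lf > 0)) return(-Inf)
    total <- total + weights[f] * log(Lf)
  }
  total
}

#' Fit the correlated mixed-mating model to progeny arrays
#'
#' Maximises the correlated mixed-mating likelihood in
#' `(t_m, r_t, r_p, F_p)` on the logit scale with multiple starts, using
#' either the full family likelihood (default with known mothers) or a
#' pairwise composite likelihood over within-family sib pairs (exact at the
#' pair level, where the correlation parameters are defined). Allele frequencies are profiled at the sample frequencies, with
#' pollen pool and ovule pool assumed equal. Single-locus outcrossing rates
#' `t_s` are refitted per locus with the correlation parameters held at
#' their multilocus estimates; `t_m - mean(t_s)` estimates biparental
#' inbreeding. Confidence intervals are percentile bootstrap over whole
#' families.
#'
#' @param arrays a [progeny_array_set()].
#' @param n_boot bootstrap replicates (0 disables CIs).
#' @param freqs optional externally estimated per-locus allele frequencies.
#' @param infer_mother `"marginal"` integrates unknown maternal genotypes
#'   over ovule frequencies at `F_m = equilibrium_fis(1 - t_m)`; `"ml"`
#'   plugs in the per-locus maximum-likelihood maternal genotype.
#' @param seed seed for the bootstrap resampling.
#' @param n_starts optimiser starts.
#' @param boot_ts also bootstrap the single-locus rates (needed for a
#'   biparental-inbreeding CI; disable to speed up large replicate studies).
#' @param fit_ts_rates fit the per-locus single-locus rates at all (disable
#'   when only the multilocus parameters are of interest).
#' @param method `"full"` maximises the sum of family log-likelihoods (the
#'   shared-father term of each family is integrated by seeded importance
#'   sampling from the father's per-locus posterior; all other latent-class
#'   terms are exact); it requires maternal genotypes. `"composite"`
#'   maximises the pairwise sib-pair likelihood (exact at the pair level)
#'   and supports marginalised mothers. `"auto"` picks `"full"` when every
#'   family has a mother, `"composite"` otherwise.
#' @param mc_fathers importance-sampling draws for the shared-father term.
#' @return object of class `mating_fit` with `estimates` (t_m, s_m, r_t,
#'   r_p, F_p, t_s, mean_ts, biparental), `ci` (95% percentile intervals),
#'   `boot` (replicate draws), `family_selfing` (per-family expected selfed
#'   fraction), `boundary`, `convergence`.
#' @export
fit_mating <- function(arrays, n_boot = 1000L, freqs = NULL,
                       infer_mother = c("marginal", "ml"), seed = NULL,
                       n_starts = 5L, boot_ts = TRUE, fit_ts_rates = TRUE,
                       method = c("auto", "full", "composite"),
                       mc_fathers = 600L) {
  stopifnot(inherits(arrays, "progeny_array_set"))
  infer_mother <- match.arg(infer_mother)
  method <- match.arg(method)
  nf <- length(arrays$families)
  if (nf < 5L) warning("fewer than 5 families: estimates will be unstable")
  fq <- mating_freqs(arrays, freqs)
  npoly <- sum(vapply(fq, length, 1L) > 1L)
  if (npoly < 1L) stop("no polymorphic locus: mating system not estimable")
  if (npoly < 2L) warning("a single polymorphic locus gives weak estimates")
  if (infer_mother == "ml") arrays <- assign_ml_mothers(arrays, fq)
  L <- length(arrays$loci)
  any_unknown <- any(vapply(arrays$families, function(f) is.null(f$mother), TRUE))
  if (method == "auto") method <- if (any_unknown) "composite" else "full"
  if (method == "full" && any_unknown)
    stop("method = 'full' needs maternal genotypes; use infer_mother = 'ml' or method = 'composite'")
  w1 <- rep(1, nf)

  if (method == "full") {
    ftabs <- progeny_full_tables(arrays, fq, M = mc_fathers, seed = seed)
    locterms <- lapply(seq_len(L), function(l)
      lapply(arrays$families, function(fam)
        progeny_locus_terms(fam, l, fq[[l]], names(fq[[l]]))))
    nll <- function(z, weights = w1) {
      p <- stats::plogis(z)
      -.progeny_full_loglik_cpp(ftabs, p[1L], p[2L], p[3L], p[4L], weights)
    }
    nll_locus <- function(zt, z_corr, weights, locus) {
      pc <- stats::plogis(z_corr)
      -ts_full_loglik(locterms[[locus]], stats::plogis(zt), pc[2L], pc[3L],
                      pc[4L], weights)
    }
    tabs <- progeny_tables(arrays, fq)   # singleton marginals for posteriors
  } else {
    tabs <- progeny_tables(arrays, fq)
    nll <- function(z, weights = w1) {
      p <- stats::plogis(z)
      Fm <- if (any_unknown) equilibrium_fis(1 - p[1L]) else 0
      -.progeny_composite_loglik_cpp(tabs, p[1L], p[2L], p[3L], p[4L],
                                     Fm, weights, 0L)
    }
    nll_locus <- function(zt, z_corr, weights, locus) {
      p <- stats::plogis(c(zt, z_corr[2:4]))
      Fm <- if (any_unknown) equilibrium_fis(1 - p[1L]) else 0
      -.progeny_composite_loglik_cpp(tabs, p[1L], p[2L], p[3L], p[4L],
                                     Fm, weights, locus)
    }
  }
  fit_once <- function(z0, weights = w1, maxit = 500L, reltol = 1e-10) {
    stats::optim(z0, nll, weights = weights, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  }
  starts <- list(stats::qlogis(c(0.7, 0.2, 0.2, 0.1)))
  extra <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    lapply(seq_len(n_starts - 1L), function(i)
      stats::qlogis(pmin(pmax(stats::runif(4, 0.05, 0.95), 0.05), 0.95)))
  })
  starts <- c(starts, extra)
  fits <- lapply(starts, fit_once)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  if (best$convergence != 0) {
    best <- fit_once(best$par, maxit = 2000L)   # restart at the incumbent
    if (best$convergence != 0)
      stop("mixed-mating fit did not converge; best values per start: ",
           paste(signif(vapply(fits, `[[`, 0, "value"), 6), collapse = ", "))
  }
  est <- stats::plogis(best$par)
  names(est) <- c("t_m", "r_t", "r_p", "F_p")

  fit_ts <- function(weights = w1, z_corr = best$par) {
    vapply(seq_len(L), function(l) {
      if (length(fq[[l]]) < 2L) return(NA_real_)
      o <- stats::optimize(nll_locus, c(-9, 9), z_corr = z_corr,
                           weights = weights, locus = l, tol = 1e-6)
      stats::plogis(o$minimum)
    }, 0)
  }
  if (fit_ts_rates) {
    t_s <- fit_ts()
    mean_ts <- mean(t_s, na.rm = TRUE)
  } else {
    t_s <- rep(NA_real_, L); mean_ts <- NA_real_
  }

  boot <- NULL; ci <- NULL
  if (n_boot > 0L) {
    boot <- with_seed(seed, {
      b <- matrix(NA_real_, n_boot, 6L,
                  dimnames = list(NULL, c("t_m", "r_t", "r_p", "F_p",
                                          "mean_ts", "biparental")))
      # resampled fits restart from the neutral default start rather than
      # the incumbent: boundary estimates sit in flat likelihood regions
      # where a warm start would pin every replicate to the boundary and
      # artificially concentrate the bootstrap distribution
      z0b <- starts[[1L]]
      for (r in seq_len(n_boot)) {
        wts <- tabulate(sample.int(nf, nf, replace = TRUE), nbins = nf)
        o <- fit_once(z0b, weights = wts, maxit = 250L, reltol = 1e-7)
        pb <- stats::plogis(o$par)
        tsb <- if (boot_ts) mean(fit_ts(weights = wts, z_corr = o$par), na.rm = TRUE)
               else NA_real_
        b[r, ] <- c(pb, tsb, pb[1L] - tsb)
      }
      b
    })
    ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }

  # per-family expected selfed fraction from the singleton marginals
  Fm_hat <- if (any_unknown) equilibrium_fis(1 - est[["t_m"]]) else 0
  fam_self <- vapply(seq_len(nf), function(f) {
    sing <- tabs[[f]]$sing; k <- tabs[[f]]$k
    dim(sing) <- c(k, L, 4L)
    Ps <- apply((1 - Fm_hat) * sing[, , 1L, drop = FALSE] +
                  Fm_hat * sing[, , 2L, drop = FALSE], 1L, prod)
    Po <- apply((1 - Fm_hat) * sing[, , 3L, drop = FALSE] +
                  Fm_hat * sing[, , 4L, drop = FALSE], 1L, prod)
    mean((1 - est[["t_m"]]) * Ps / ((1 - est[["t_m"]]) * Ps + est[["t_m"]] * Po))
  }, 0)
  names(fam_self) <- names(arrays$families)

  estimates <- list(t_m = est[["t_m"]], s_m = 1 - est[["t_m"]],
                    r_t = est[["r_t"]], r_p = est[["r_p"]], F_p = est[["F_p"]],
                    t_s = stats::setNames(t_s, arrays$loci), mean_ts = mean_ts,
                    biparental = est[["t_m"]] - mean_ts)
  boundary <- est < 1e-4 | est > 1 - 1e-4
  structure(list(estimates = estimates, ci = ci, boot = boot,
                 family_selfing = fam_self, boundary = boundary,
                 convergence = TRUE, loglik = -best$value, method = method,
                 infer_mother = infer_mother, n_families = nf),
            class = "mating_fit")
}

# per-locus ML maternal genotype assignment for families lacking a mother
assign_ml_mothers <- function(arrays, fq, t0 = 0.7) {
  L <- length(arrays$loci)
  for (f in seq_along(arrays$families)) {
    fam <- arrays$families[[f]]
    if (!is.null(fam$mother)) next
    mother <- matrix(NA_integer_, 2L, L)
    for (l in seq_len(L)) {
      p <- fq[[l]]; lab <- names(p); A <- length(p)
      gi <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
      pr <- ifelse(gi[, 1L] == gi[, 2L], p[gi[, 1L]]^2, 2 * p[gi[, 1L]] * p[gi[, 2L]])
      ll <- log(pr)
      for (j in seq_len(n_ind(fam$progeny))) {
        x <- match(as.character(fam$progeny$calls[j, l, 1L]), lab)
        y <- match(as.character(fam$progeny$calls[j, l, 2L]), lab)
        if (is.na(x)) next
        pj <- vapply(seq_len(nrow(gi)), function(m) {
          n <- numeric(A); n[gi[m, 1L]] <- n[gi[m, 1L]] + 1; n[gi[m, 2L]] <- n[gi[m, 2L]] + 1
          S <- if (x == y) 0.25 * n[x]^2 else 0.5 * n[x] * n[y]
          O <- if (x == y) 0.5 * n[x] * p[x] else 0.5 * (n[x] * p[y] + n[y] * p[x])
          (1 - t0) * S + t0 * O
        }, 0)
        ll <- ll + log(pj)
      }
      m <- which.max(ll)
      mother[, l] <- as.integer(lab[c(gi[m, 1L], gi[m, 2L])])
    }
    arrays$families[[f]]$mother <- mother
  }
  arrays
}

#' @export
print.mating_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("mating_fit (correlated mixed-mating model, %s likelihood)\n",
              if (identical(x$method, "full")) "family" else "pairwise composite"))
  show <- c(s_m = e$s_m, t_m = e$t_m, `t_m - t_s` = e$biparental,
            r_t = e$r_t, r_p = e$r_p, F_p = e$F_p)
  for (nm in names(show)) {
    ci <- switch(nm, s_m = 1 - rev(x$ci[, "t_m"]), t_m = x$ci[, "t_m"],
                 `t_m - t_s` = x$ci[, "biparental"], r_t = x$ci[, "r_t"],
                 r_p = x$ci[, "r_p"], F_p = x$ci[, "F_p"])
    if (!is.null(x$ci))
      cat(sprintf("  %-9s %.3f  (95%% CI %.3f-%.3f)\n", nm, show[[nm]], ci[1L], ci[2L]))
    else cat(sprintf("  %-9s %.3f\n", nm, show[[nm]]))
  }
  invisible(x)
}

#' Biparental inbreeding estimate
#'
#' The difference between the multilocus and mean single-locus outcrossing
#' rates, `t_m - mean(t_s)`: mating among relatives inflates apparent
#' selfing at single loci but not the multilocus rate. Values are clipped to
#' `[-1, 1]`; mildly negative values arise from sampling noise.
#'
#' @param fit a [fit_mating()] result.
#' @return list with `estimate` and `ci95` (from the family bootstrap).
#' @export
biparental_inbreeding <- function(fit) {
  stopifnot(inherits(fit, "mating_fit"))
  list(estimate = max(-1, min(1, fit$estimates$biparental)),
       ci95 = if (!is.null(fit$ci)) unname(fit$ci[, "biparental"]) else c(NA_real_, NA_real_))
}

#' Effective number of fathers per sibship
#'
#' The reciprocal of the correlation of paternity, rounded to the nearest
#' integer; `r_p = 0` means unboundedly many fathers.
#'
#' @param r_p correlation of paternity in `[0, 1]`.
#' @return list with `n_fathers` (rounded), `exact` (1/r_p), `unbounded`.
#' @export
effective_fathers <- function(r_p) {
  stopifnot(r_p >= 0, r_p <= 1)
  if (r_p == 0) return(list(n_fathers = Inf, exact = Inf, unbounded = TRUE))
  list(n_fathers = as.integer(round(1 / r_p)), exact = 1 / r_p, unbounded = FALSE)
}
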