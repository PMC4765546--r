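# Independent brute-force oracles used across the suite. These are written
# directly from the model definitions (explicit enumerations and Mendelian
# tables) and never call the package's own likelihood code paths.

# selfing-mixture probability of a 0/1 heterozygosity vector by explicit
# term-by-term summation over the (renormalised, truncated) generation count
oracle_rmes_prob <- function(x, s, h, n_max) {
  obs <- !is.na(x)
  total <- 0
  norm <- if (s > 0) 1 - s^(n_max + 1) else 1
  for (n in 0:n_max) {
    w <- if (s > 0) (1 - s) * s^n / norm else as.numeric(n == 0)
    p <- prod(ifelse(x[obs] == 1, h[obs] * 2^-n, 1 - h[obs] * 2^-n))
    total <- total + w * p
  }
  total
}

# Mendelian offspring probabilities by enumeration of ordered gamete pairs
# (each of the four combinations has probability 1/4); unordered genotypes
# compared as multisets
same_geno <- function(a, b) all(sort(as.numeric(a)) == sort(as.numeric(b)))

oracle_self_prob <- function(geno, mother) {
  tot <- 0
  for (u in mother) for (v in mother)
    if (same_geno(c(u, v), geno)) tot <- tot + 0.25
  tot
}

oracle_cross_prob <- function(geno, mother, father) {
  tot <- 0
  for (u in mother) for (v in father)
    if (same_geno(c(u, v), geno)) tot <- tot + 0.25
  tot
}

# genotype prior at inbreeding F over allele frequencies p (named vector)
oracle_geno_prior <- function(p, Fcoef) {
  lab <- names(p)
  gl <- list(); pr <- numeric(0)
  for (i in seq_along(p)) for (j in i:length(p)) {
    gl[[length(gl) + 1]] <- c(as.integer(lab[i]), as.integer(lab[j]))
    pr <- c(pr, if (i == j) (1 - Fcoef) * p[i]^2 + Fcoef * p[i] else (1 - Fcoef) * 2 * p[i] * p[j])
  }
  list(genos = gl, prob = pr)
}

# full-family likelihood by explicit enumeration over every latent
# combination: selfing-share class, per-progeny selfing flags, father-share
# class, shared-father multilocus genotype, and (if unknown) the maternal
# multilocus genotype. Exponential in everything; only for tiny cases.
oracle_family_lik <- function(progeny, mother, freqs, t, rt, rp, Fp, Fm) {
  L <- length(freqs)
  k <- nrow(progeny[[1]])
  # enumerate multilocus genotypes as lists of per-locus genotype indices
  enum_multi <- function(priors) {
    idx <- lapply(priors, function(z) seq_along(z$prob))
    grid <- expand.grid(idx)
    list(grid = grid, priors = priors)
  }
  fpriors <- lapply(freqs, oracle_geno_prior, Fcoef = Fp)
  fe <- enum_multi(fpriors)
  if (is.null(mother)) {
    mpriors <- lapply(freqs, oracle_geno_prior, Fcoef = Fm)
    me <- enum_multi(mpriors)
  }
  lik_given_mother <- function(mo) {
    total <- 0
    for (code in 0:(2^k - 1)) {
      selfed <- bitwAnd(code, 2^(seq_len(k) - 1)) > 0
      w_ind <- prod(ifelse(selfed, 1 - t, t))
      w_sh <- if (all(selfed)) (1 - t) else if (all(!selfed)) t else 0
      # independent fathers: per progeny marginal paternal allele ~ p
      ind_term <- 1
      for (j in seq_len(k)) for (l in seq_len(L)) {
        g <- progeny[[l]][j, ]
        if (anyNA(g)) next
        if (selfed[j]) ind_term <- ind_term * oracle_self_prob(g, mo[[l]])
        else {
          p <- freqs[[l]]
          acc <- 0
          for (a in seq_along(p)) {
            fa <- as.integer(names(p)[a])
            acc <- acc + p[a] * oracle_cross_prob(g, mo[[l]], c(fa, fa))
          }
          ind_term <- ind_term * acc
        }
      }
      # shared father: sum over his multilocus genotype
      sh_term <- 0
      if (any(!selfed)) {
        for (r in seq_len(nrow(fe$grid))) {
          w <- 1; termp <- 1
          for (l in seq_len(L)) {
            gi <- fe$grid[r, l]
            w <- w * fe$priors[[l]]$prob[gi]
          }
          for (j in seq_len(k)) for (l in seq_len(L)) {
            g <- progeny[[l]][j, ]
            if (anyNA(g)) next
            if (selfed[j]) termp <- termp * oracle_self_prob(g, mo[[l]])
            else termp <- termp * oracle_cross_prob(
              g, mo[[l]], fe$priors[[l]]$genos[[fe$grid[r, l]]])
          }
          sh_term <- sh_term + w * termp
        }
      } else sh_term <- ind_term
      fa <- rp * sh_term + (1 - rp) * ind_term
      total <- total + (1 - rt) * w_ind * fa + rt * w_sh * fa
    }
    total
  }
  if (!is.null(mother)) return(lik_given_mother(mother))
  total <- 0
  for (r in seq_len(nrow(me$grid))) {
    w <- 1
    mo <- vector("list", L)
    for (l in seq_len(L)) {
      gi <- me$grid[r, l]
      w <- w * me$priors[[l]]$prob[gi]
      mo[[l]] <- me$priors[[l]]$genos[[gi]]
    }
    total <- total + w * lik_given_mother(mo)
  }
  total
}

# Weir-Cockerham theta by direct transcription of the 1984 component
# formulas for one biallelic-coded allele count table
oracle_wc_theta <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# small helper: genotype matrix from an individuals x (2*loci) integer matrix
gm <- function(m, ...) genotype_matrix(as.matrix(m), ...)
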