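#' Selfing-mixture parameters
#'
#' Parameters of the multilocus heterozygosity mixture: an individual whose
#' most recent outbred ancestor lies `n` selfing generations back (with
#' `n` geometric with success probability `1 - s`) is heterozygous at locus
#' `l` with probability `h_l / 2^n` — heterozygosity halves with each selfing
#' generation. The geometric is truncated at `n_max` and renormalised so that
#' pattern probabilities sum exactly to one; by default `n_max` is the
#' smallest `n` with `s^(n+1) < 1e-13`, capped at 60.
#'
#' @param s selfing rate in `[0, 1)`.
#' @param h vector of per-locus outbred heterozygosities in `[0, 1]`.
#' @param n_max truncation of the selfing-generation count (default as above).
#' @return list of class `selfing_params`.
#' @export
selfing_params <- function(s, h, n_max = NULL) {
  stopifnot(s >= 0, s < 1, all(h >= 0), all(h <= 1))
  if (is.null(n_max)) n_max <- default_nmax(s)
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 0)
  structure(list(s = s, h = h, n_max = n_max), class = "selfing_params")
}

default_nmax <- function(s, tail_tol = 1e-13, cap = 60L) {
  if (s <= 0) return(0L)
  min(cap, max(1L, as.integer(ceiling(log(tail_tol) / log(s))) - 1L))
}

#' Log-likelihood of one heterozygosity pattern
#'
#' Probability of an individual's 0/1 heterozygosity vector under the selfing
#' mixture, with missing loci masked (contributing a factor of one).
#'
#' @param x 0/1 vector of per-locus heterozygosity; `NA` = masked.
#' @param params a [selfing_params()] object.
#' @return scalar log-probability.
#' @export
individual_loglik <- function(x, params) {
  stopifnot(inherits(params, "selfing_params"), length(x) == length(params$h))
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("no information: all loci masked")
  s <- params$s; h <- params$h; nm <- params$n_max
  n <- 0:nm
  logw <- if (s <= 0) 0 else log1p(-s) + n * log(s) - log(1 - s^(nm + 1))
  ll_n <- vapply(n, function(nn) {
    p <- h[obs] * 0.5^nn
    sum(ifelse(x[obs] == 1, log(p), log1p(-p)))
  }, 0)
  v <- logw + ll_n
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Fit the selfing rate of one population by profile maximum likelihood
#'
#' Computes the profile log-likelihood of the selfing rate `s` on a regular
#' grid, maximising the per-locus outbred heterozygosities `h` by EM at each
#' grid point (warm-started along the grid), then refines the maximum to
#' 1e-4 by golden-section search and reports the 95% likelihood interval
#' (1.92 log-likelihood drop, chi-square with 1 d.f.).
#'
#' Individuals missing at every locus are dropped (with a message of the
#' count). Loci monomorphic in the raw genotypes carry no heterozygosity
#' information; if no locus is polymorphic an error is raised, and if no
#' heterozygote is observed at any locus the estimate sits at the grid
#' maximum with an "unidentifiable h" warning.
#'
#' @param g a [genotype_matrix()], or a 0/1 heterozygosity matrix with `NA`
#'   mask (individuals x loci).
#' @param grid_step grid spacing for the profile (default 0.001).
#' @param n_max optional truncation override for the selfing-generation count.
#' @return object of class `selfing_profile`: `grid`, `loglik`, `s_hat`,
#'   `loglik_max`, `ci95`, `h_hat`, `n_individuals`, `n_loci`, `boundary`.
#' @export
fit_selfing <- function(g, grid_step = 0.001, n_max = NULL) {
  X <- if (inherits(g, "genotype_matrix")) het_patterns(g) else as.matrix(g)
  storage.mode(X) <- "integer"
  keep <- rowSums(!is.na(X)) > 0L
  if (any(!keep)) {
    message(sum(!keep), " individual(s) with no non-missing locus dropped")
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("need at least 2 individuals with data")
  poly <- colSums(!is.na(X)) > 0L
  X <- X[, poly, drop = FALSE]
  if (ncol(X) == 0L) stop("no locus with data")
  if (inherits(g, "genotype_matrix")) {
    nall <- vapply(allele_freqs(g)$freqs[poly], function(f) if (is.null(f)) 0L else length(f), 1L)
    if (all(nall <= 1L)) stop("all loci monomorphic: selfing rate not estimable")
  }
  tail_tol <- 1e-13; cap <- if (is.null(n_max)) 60L else as.integer(n_max)
  grid <- seq(0, 0.999, by = grid_step)
  fit <- .rmes_profile_cpp(X, grid, tail_tol, cap, 1e-7, 500L)
  ll <- fit$loglik
  best <- which.max(ll)
  boundary <- FALSE
  no_het <- sum(X == 1L, na.rm = TRUE) == 0L
  if (no_het) {
    warning("no heterozygote observed at any locus: unidentifiable h, boundary estimate")
    boundary <- TRUE
  }
  # golden-section refinement to 1e-4 around the best grid point
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(length(grid), best + 1L)]
  h_warm <- fit$h[, best]
  f_at <- function(s) .rmes_loglik_at_cpp(X, s, h_warm, tail_tol, cap, 1e-9, 500L)$loglik
  opt <- stats::optimize(f_at, lower = lo, upper = hi, maximum = TRUE, tol = 1e-5)
  s_hat <- round(opt$maximum, 4)
  ll_max <- max(opt$objective, ll[best])
  if (opt$objective < ll[best]) s_hat <- grid[best]
  if (s_hat <= grid[1L] + 1e-9 || s_hat >= grid[length(grid)] - 1e-9) boundary <- TRUE
  # likelihood interval: crossings of ll = ll_max - 1.92, linear interpolation
  thr <- ll_max - stats::qchisq(0.95, 1) / 2
  ci <- likelihood_interval(grid, ll, thr)
  hfin <- .rmes_loglik_at_cpp(X, s_hat, h_warm, tail_tol, cap, 1e-9, 500L)$h
  h_all <- rep(NA_real_, length(poly)); h_all[poly] <- hfin
  out <- structure(list(grid = grid, loglik = ll, s_hat = s_hat, loglik_max = ll_max,
                        ci95 = ci, h_hat = h_all,
                        n_individuals = nrow(X), n_loci = ncol(X), boundary = boundary),
                   class = "selfing_profile")
  attr(out, ".spline") <- stats::splinefun(grid, ll, method = "natural")
  out
}

likelihood_interval <- function(grid, ll, thr) {
  above <- ll >= thr
  if (!any(above)) return(c(NA_real_, NA_real_))
  i1 <- which(above)[1L]; i2 <- rev(which(above))[1L]
  lo <- grid[i1]
  if (i1 > 1L) {
    # interpolate between i1-1 (below) and i1 (above)
    lo <- grid[i1 - 1L] + (thr - ll[i1 - 1L]) / (ll[i1] - ll[i1 - 1L]) * (grid[i1] - grid[i1 - 1L])
  }
  hi <- grid[i2]
  if (i2 < length(grid)) {
    hi <- grid[i2] + (thr - ll[i2]) / (ll[i2 + 1L] - ll[i2]) * (grid[i2 + 1L] - grid[i2])
  }
  c(lo, hi)
}

#' @export
print.selfing_profile <- function(x, ...) {
  cat(sprintf("selfing_profile: s_hat = %.4f (95%% CI %.3f-%.3f)%s\n",
              x$s_hat, x$ci95[1L], x$ci95[2L],
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  %d individuals, %d loci, max log-likelihood %.3f\n",
              x$n_individuals, x$n_loci, x$loglik_max))
  invisible(x)
}

#' Evaluate a selfing profile's log-likelihood at arbitrary selfing rates
#'
#' Interpolates the stored grid profile, by natural cubic spline by default
#' (linear interpolation at a 0.001 grid leaves ~1e-5 kinks that dominate
#' quadrature error in the hierarchical model); values outside the grid
#' support are clamped to the boundary value with a warning.
#'
#' @param profile a `selfing_profile`.
#' @param s numeric vector of selfing rates.
#' @param method `"spline"` (default) or `"linear"`.
#' @return numeric vector of log-likelihood values.
#' @export
profile_loglik <- function(profile, s, method = c("spline", "linear")) {
  method <- match.arg(method)
  g <- profile$grid; ll <- profile$loglik
  out_of_range <- s < g[1L] | s > g[length(g)]
  if (any(out_of_range)) {
    warning("selfing rate outside profile support; boundary value used")
    s <- pmin(pmax(s, g[1L]), g[length(g)])
  }
  if (method == "linear" || length(g) < 4L)
    return(stats::approx(g, ll, xout = s, rule = 2)$y)
  f <- attr(profile, ".spline")
  if (is.null(f)) f <- stats::splinefun(g, ll, method = "natural")
  f(s)
}

#' Selfing rate implied by an inbreeding coefficient
#'
#' Inverts the single-generation equilibrium `F = s / (2 - s)` to
#' `s = 2F / (1 + F)`. Negative `F` maps to 0 with a warning.
#'
#' @param f inbreeding coefficient in `(-1, 1]`.
#' @return implied selfing rate in `[0, 1]`.
#' @export
selfing_from_fis <- function(f) {
  if (any(f <= -1)) stop("F must be > -1")
  s <- 2 * f / (1 + f)
  if (any(f < 0)) {
    warning("negative F mapped to selfing rate 0")
    s[f < 0] <- 0
  }
  s
}

#' Equilibrium inbreeding coefficient under constant partial selfing
#'
#' `F = s / (2 - s)`, the stationary inbreeding coefficient of a population
#' selfing at constant rate `s`.
#'
#' @param s selfing rate in `[0, 1]`.
#' @return equilibrium `F` in `[0, 1]`.
#' @export
equilibrium_fis <- function(s) {
  stopifnot(all(s >= 0), all(s <= 1))
  s / (2 - s)
}

#' Serialise a selfing profile
#'
#' Writes the grid profile as a TSV (`s`, `loglik`) and the summary as JSON
#' (`s_hat`, `ci95`, `n_individuals`, `n_loci`).
#'
#' @param profile a `selfing_profile`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @export
write_selfing_profile <- function(profile, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(data.frame(s = profile$grid, loglik = profile$loglik),
                       tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(s_hat = profile$s_hat, ci95 = profile$ci95,
                              n_individuals = profile$n_individuals,
                              n_loci = profile$n_loci),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(profile)
}
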