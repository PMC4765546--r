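#' Pipeline configuration
#'
#' Declarative configuration for the full analysis pipeline: either a
#' synthetic-data configuration ([sim_config()]) or paths to real inputs
#' (Genepop/CSV genotypes, metadata CSV, progeny CSV), stage toggles, and
#' the permutation/bootstrap effort. Defaults match a typical microsatellite
#' survey analysis: 5000 permutations, 1000 bootstraps, selfing-profile grid
#' step 0.001, chi-square likelihood-ratio tests.
#'
#' @param sim a [sim_config()] for synthetic mode (`NULL` for real inputs).
#' @param genotypes path to a genotype CSV ([read_genotype_csv()] dialect)
#'   or Genepop file; required when `sim` is `NULL`.
#' @param metadata optional path to a population metadata CSV.
#' @param progeny optional path to a progeny CSV.
#' @param stages character vector of stages to run, in order, among
#'   `"diversity"`, `"structure"`, `"selfing"`, `"ecotype"`, `"progeny"`,
#'   `"ne"`.
#' @param n_perm,n_boot permutation and bootstrap effort.
#' @param grid_step selfing-profile grid step.
#' @param ne_cap search cap for the temporal effective size.
#' @param seed master seed; each stochastic stage derives its own.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genotypes = NULL,
                            metadata = NULL, progeny = NULL,
                            stages = c("diversity", "structure", "selfing",
                                       "ecotype", "progeny", "ne"),
                            n_perm = 5000L, n_boot = 1000L,
                            grid_step = 0.001, ne_cap = 50000, seed = 1L) {
  if (!is.null(sim) && !is.null(genotypes))
    stop("provide either a sim_config or input paths, not both")
  if (is.null(sim) && is.null(genotypes))
    stop("provide a sim_config or a genotypes path")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, genotypes = genotypes, metadata = metadata,
                 progeny = progeny, stages = stages, n_perm = n_perm,
                 n_boot = n_boot, grid_step = grid_step, ne_cap = ne_cap,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks input files exist and are readable, locus lists agree across
#' populations, and coordinates are present where the isolation-by-distance
#' stage needs them. Warnings allow the run to proceed (with the affected
#' parts skipped); errors do not.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `errors` and `warnings` (character vectors).
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  errors <- character(0); warnings <- character(0)
  if (!is.null(cfg$genotypes)) {
    for (p in c(cfg$genotypes, cfg$metadata, cfg$progeny)) {
      if (!is.null(p) && !file.exists(p))
        errors <- c(errors, paste("missing input file:", p))
    }
    if (file.exists(cfg$genotypes %||% "")) {
      pops <- tryCatch(load_genotype_input(cfg$genotypes),
                       error = function(e) {
                         errors <<- c(errors, conditionMessage(e)); NULL
                       })
      if (!is.null(pops)) {
        loci <- lapply(pops, `[[`, "loci")
        if (length(unique(loci)) > 1L) {
          ref <- loci[[1L]]
          bad <- names(pops)[!vapply(loci, identical, TRUE, ref)]
          errors <- c(errors, paste0(
            "locus-name mismatch between populations: ",
            paste(bad, collapse = ", "), " differ from ", names(pops)[1L],
            " (loci: ", paste(ref, collapse = ","), ")"))
        }
        nocoord <- names(pops)[vapply(pops, function(g) is.na(g$lat) || is.na(g$lon), TRUE)]
        if (length(nocoord) && is.null(cfg$metadata) && "structure" %in% cfg$stages)
          warnings <- c(warnings, paste0(
            "missing GPS coordinates for: ", paste(nocoord, collapse = ", "),
            "; isolation-by-distance will exclude them"))
      }
    }
  }
  list(errors = errors, warnings = warnings)
}

load_genotype_input <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) read_genotype_csv(path)
  else read_genepop(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order, the enabled stages: diversity table; population
#' structure (pairwise F_ST, hierarchical fixation indexes, permutation
#' comparisons between groups, Mantel/IBD, PCA); per-population selfing-rate
#' profiles; the hierarchical ecotype comparison ladder; progeny-array
#' mixed-mating estimation; and temporal effective size. Tables are written
#' as TSV under `out_dir`, a JSON summary as `results.json`, and one
#' structured log line per stage (stage, seed, wall time) to
#' `pipeline_log.txt`. A stage failure records the error, skips dependent
#' stages, and is reported in the returned bundle.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisible list with the stage results, `errors`, and `ok` flag.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  val <- validate_config(cfg)
  if (length(val$errors)) stop("invalid configuration:\n  ",
                               paste(val$errors, collapse = "\n  "))
  for (w in val$warnings) warning(w, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  cat("", file = log_path)
  logln <- function(stage, seed, t0) {
    cat(sprintf("stage=%s seed=%d elapsed=%.2fs\n", stage, seed,
                as.numeric(Sys.time() - t0, units = "secs")),
        file = log_path, append = TRUE)
  }
  res <- list(); errors <- character(0)
  failed <- character(0)
  run_stage <- function(name, seed, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(seed), error = function(e) {
      errors <<- c(errors, paste0(name, ": ", conditionMessage(e)))
      failed <<- c(failed, name)
      NULL
    })
    logln(name, seed, t0)
    out
  }

  # ---- data ----
  synth <- !is.null(cfg$sim)
  t0 <- Sys.time()
  if (synth) {
    mp <- sim_metapopulation(cfg$sim)
    pops1 <- mp$pops
    # second season: per population, drift at the configured Ne
    pops2 <- list()
    for (i in seq_along(pops1)) {
      st <- sim_temporal(cfg$sim, base_freqs = mp$truth$pop_freqs[[i]],
                         seed = cfg$seed + 1000L + i, s = mp$truth$s[[i]])
      g2 <- st$pair$sample1
      g2$pop <- pops1[[i]]$pop; g2$ecotype <- pops1[[i]]$ecotype
      g2$year <- 2L; g2$lat <- pops1[[i]]$lat; g2$lon <- pops1[[i]]$lon
      g2$individuals <- paste0(g2$pop, "_y2_", seq_len(n_ind(g2)))
      dimnames(g2$calls)[[1L]] <- g2$individuals
      pops2[[pops1[[i]]$pop]] <- g2
    }
    years <- list(`1` = pops1, `2` = pops2)
    coords <- data.frame(population = names(pops1),
                         lat = unname(mp$truth$lat), lon = unname(mp$truth$lon),
                         stringsAsFactors = FALSE)
    arrays <- if ("progeny" %in% cfg$stages)
      sim_progeny_arrays(cfg$sim, seed = cfg$seed + 5000L)$arrays else NULL
    res$truth <- mp$truth
  } else {
    pops_all <- load_genotype_input(cfg$genotypes)
    yr <- vapply(pops_all, function(g) as.character(g$year[1L]), "")
    years <- split(pops_all, yr)
    years <- lapply(years, function(ps)
      stats::setNames(ps, vapply(ps, `[[`, "", "pop")))
    if (!is.null(cfg$metadata)) {
      md <- read_metadata_csv(cfg$metadata)
      for (y in names(years)) for (p in names(years[[y]])) {
        i <- match(p, md$population)
        if (!is.na(i)) {
          years[[y]][[p]]$lat <- md$lat[i]; years[[y]][[p]]$lon <- md$lon[i]
        }
      }
    }
    p1 <- years[[1L]]
    coords <- data.frame(population = names(p1),
                         lat = vapply(p1, `[[`, 0, "lat"),
                         lon = vapply(p1, `[[`, 0, "lon"),
                         stringsAsFactors = FALSE)
    arrays <- if (!is.null(cfg$progeny)) read_progeny_csv(cfg$progeny) else NULL
  }
  logln("data", cfg$seed, t0)
  assignment_of <- function(pops) vapply(pops, function(g) as.character(g$ecotype), "")

  # ---- diversity ----
  if ("diversity" %in% cfg$stages) {
    res$diversity <- run_stage("diversity", cfg$seed + 11L, function(seed) {
      tabs <- lapply(names(years), function(y) {
        d <- diversity_table(years[[y]], n_boot = cfg$n_boot, seed = seed)
        cbind(year = y, d)
      })
      out <- do.call(rbind, tabs)
      write_tsv(out, file.path(out_dir, "diversity.tsv"))
      out
    })
  }

  # ---- structure ----
  if ("structure" %in% cfg$stages) {
    res$structure <- run_stage("structure", cfg$seed + 21L, function(seed) {
      out <- list()
      fst_rows <- list()
      for (y in names(years)) {
        fst <- pairwise_fst(years[[y]])
        fst_rows[[y]] <- cbind(data.frame(year = y, population = rownames(fst)),
                               as.data.frame(fst))
        out$fst[[y]] <- fst
      }
      write_tsv(do.call(rbind, fst_rows), file.path(out_dir, "fst_pairwise.tsv"))
      hf <- lapply(names(years), function(y)
        cbind(year = y, hierarchical_f(years[[y]], n_boot = cfg$n_boot,
                                       seed = seed)))
      out$hierarchical <- do.call(rbind, hf)
      write_tsv(out$hierarchical, file.path(out_dir, "hierarchical_f.tsv"))
      perm_rows <- list()
      for (y in names(years)) for (stt in c("H_obs", "H_exp", "F_IS", "F_ST")) {
        pc <- permutation_compare(years[[y]], stt, n_perm = cfg$n_perm,
                                  seed = seed + match(stt, c("H_obs", "H_exp", "F_IS", "F_ST")))
        perm_rows[[paste(y, stt)]] <- data.frame(
          year = y, stat = stt, group_difference = pc$observed,
          p_value = pc$p_value)
      }
      out$permutation <- do.call(rbind, perm_rows)
      D <- geo_distances(coords)
      ibd_rows <- list()
      if (!all(is.na(D[upper.tri(D)]))) {
        for (y in names(years)) {
          mt <- mantel(out$fst[[y]], D, n_perm = cfg$n_perm, seed = seed + 7L)
          ib <- ibd_regression(out$fst[[y]], D, n_perm = cfg$n_perm, seed = seed + 8L)
          ibd_rows[[y]] <- data.frame(year = y, mantel_r = mt$r,
                                      mantel_p = mt$p_value, ibd_slope = ib$slope,
                                      ibd_intercept = ib$intercept,
                                      ibd_p = ib$p_value)
        }
        out$ibd <- do.call(rbind, ibd_rows)
      }
      write_tsv(rbind(out$permutation), file.path(out_dir, "permutation_tests.tsv"))
      if (!is.null(out$ibd)) write_tsv(out$ibd, file.path(out_dir, "ibd.tsv"))
      pca <- pca_freqs(years[[1L]])
      pc_df <- data.frame(population = pca$population,
                          PC1 = pca$scores[, 1L], PC2 = pca$scores[, 2L],
                          PC3 = pca$scores[, 3L], PC4 = pca$scores[, 4L])
      utils::write.csv(pc_df, file.path(out_dir, "pca_coords.csv"), row.names = FALSE)
      out$pca_inertia <- pca$inertia[1:4]
      out
    })
  }

  # ---- selfing profiles ----
  profiles <- NULL
  if ("selfing" %in% cfg$stages) {
    res$selfing <- run_stage("selfing", cfg$seed + 31L, function(seed) {
      profs <- list(); rows <- list()
      for (y in names(years)) for (p in names(years[[y]])) {
        key <- paste0(p, "_y", y)
        pr <- fit_selfing(years[[y]][[p]], grid_step = cfg$grid_step)
        profs[[key]] <- pr
        rows[[key]] <- data.frame(population = p, year = y, s_hat = pr$s_hat,
                                  ci_lo = pr$ci95[1L], ci_hi = pr$ci95[2L],
                                  boundary = pr$boundary)
      }
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out_dir, "selfing_rates.tsv"))
      list(profiles = profs, table = tab)
    })
    profiles <- res$selfing$profiles
  }

  # ---- ecotype comparison ladder ----
  if ("ecotype" %in% cfg$stages) {
    if (is.null(profiles)) {
      errors <- c(errors, "ecotype: selfing stage required but unavailable")
    } else {
      res$ecotype <- run_stage("ecotype", cfg$seed + 41L, function(seed) {
        rows <- list(); rates <- list()
        for (y in names(years)) {
          keys <- paste0(names(years[[y]]), "_y", y)
          asn <- stats::setNames(assignment_of(years[[y]]), keys)
          lad <- ecotype_pipeline(profiles[keys], asn)
          rows[[y]] <- cbind(year = y, lad$tests)
          rates[[y]] <- cbind(year = y, lad$group_rates)
        }
        # temporal comparison within each ecotype: season vs pooled
        eco_all <- assignment_of(years[[1L]])
        for (e in unique(eco_all)) {
          keys <- unlist(lapply(names(years), function(y)
            paste0(names(years[[y]])[assignment_of(years[[y]]) == e], "_y", y)))
          yr <- sub(".*_y", "", keys)
          if (length(unique(yr)) < 2L) next
          asn <- stats::setNames(yr, keys)
          f_by <- fit_hier(profiles[keys], hier_spec(asn, "by_group", "zero"))
          f_1 <- fit_hier(profiles[keys], hier_spec(asn, "shared", "zero"))
          lt <- lrt(f_by, f_1)
          rows[[paste0("temporal_", e)]] <- data.frame(
            year = "all", comparison = paste0("season effect within ", e),
            full = "s per season", constrained = "single s",
            loglik_full = f_by$loglik, loglik_constrained = f_1$loglik,
            deviance = lt$deviance, df = lt$df, p_value = lt$p_value)
        }
        tests <- do.call(rbind, rows)
        write_tsv(tests, file.path(out_dir, "ecotype_tests.tsv"))
        rates <- do.call(rbind, rates)
        write_tsv(rates, file.path(out_dir, "ecotype_selfing.tsv"))
        list(tests = tests, rates = rates)
      })
    }
  }

  # ---- progeny arrays ----
  if ("progeny" %in% cfg$stages && !is.null(arrays)) {
    res$progeny <- run_stage("progeny", cfg$seed + 51L, function(seed) {
      fit <- fit_mating(arrays, n_boot = cfg$n_boot, seed = seed)
      e <- fit$estimates
      tab <- data.frame(
        parameter = c("s_multi", "t_m", "biparental_tm_ts", "r_t", "r_p", "F_p"),
        estimate = c(e$s_m, e$t_m, e$biparental, e$r_t, e$r_p, e$F_p),
        ci_lo = c(1 - fit$ci["97.5%", "t_m"], fit$ci["2.5%", "t_m"],
                  fit$ci["2.5%", "biparental"], fit$ci["2.5%", "r_t"],
                  fit$ci["2.5%", "r_p"], fit$ci["2.5%", "F_p"]),
        ci_hi = c(1 - fit$ci["2.5%", "t_m"], fit$ci["97.5%", "t_m"],
                  fit$ci["97.5%", "biparental"], fit$ci["97.5%", "r_t"],
                  fit$ci["97.5%", "r_p"], fit$ci["97.5%", "F_p"]))
      write_tsv(tab, file.path(out_dir, "mating_system.tsv"))
      list(fit = fit, table = tab)
    })
  }

  # ---- temporal Ne ----
  if ("ne" %in% cfg$stages) {
    res$ne <- run_stage("ne", cfg$seed + 61L, function(seed) {
      if (length(years) < 2L) stop("temporal stage needs two seasonal samples")
      rows <- list()
      for (p in names(years[[1L]])) {
        if (!p %in% names(years[[2L]])) next
        pr <- temporal_pair(years[[1L]][[p]], years[[2L]][[p]], 1L)
        f <- fit_ne(pr, cap = cfg$ne_cap)
        fk <- fk_moment_ne(pr, cap = cfg$ne_cap)
        rows[[p]] <- data.frame(population = p,
                                ecotype = years[[1L]][[p]]$ecotype,
                                Ne_hat = f$Ne_hat, ci_lo = f$ci95[1L],
                                ci_hi = f$ci95[2L], at_cap = f$at_cap,
                                Ne_moment = fk$Ne_hat)
      }
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out_dir, "effective_size.tsv"))
      tab
    })
  }

  summary <- list(
    stages_run = cfg$stages, failed = failed, seed = cfg$seed,
    ecotype_selfing = if (!is.null(res$ecotype)) res$ecotype$rates else NULL,
    mating = if (!is.null(res$progeny)) res$progeny$table else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(errors)) {
    warning("pipeline completed with errors:\n  ",
            paste(errors, collapse = "\n  "), call. = FALSE)
  }
  invisible(c(res, list(errors = errors, ok = length(errors) == 0L)))
}
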