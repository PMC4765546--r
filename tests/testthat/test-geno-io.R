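test_that("Genepop round trip preserves the data model", {
  txt <- c("toy file", "locA", "locB", "Pop",
           "a1, 0101 0203", "a2, 0102 0000", "Pop",
           "b1, 0202 0301", "b2, 0101 0102")
  pops <- read_genepop(text = paste(txt, collapse = "\n"))
  expect_length(pops, 2L)
  expect_equal(pops[[1]]$loci, c("locA", "locB"))
  # "0101" -> allele pair (1,1), not missing
  expect_equal(pops[[1]]$calls[1, 1, ], c(1L, 1L))
  # "0000" -> missing
  expect_true(all(is.na(pops[[1]]$calls[2, 2, ])))
  out <- write_genepop(pops, digits = 2L, title = "toy file")
  norm <- function(x) gsub("\\s+", " ", trimws(x))
  expect_equal(norm(out), norm(txt))

  # property: random matrices survive write -> read
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(2:6, 1); L <- sample(1:4, 1)
    calls <- array(sample(c(1:9, NA), n * L * 2, replace = TRUE), c(n, L, 2))
    g <- genotype_matrix(calls, pop = "x")
    back <- read_genepop(text = paste(write_genepop(list(x = g)), collapse = "\n"))[[1]]
    expect_equal(unname(back$calls[, , 1] + back$calls[, , 2]),
                 unname(g$calls[, , 1] + g$calls[, , 2]))
    expect_equal(unname(abs(back$calls[, , 1] - back$calls[, , 2])),
                 unname(abs(g$calls[, , 1] - g$calls[, , 2])))
  }
})

test_that("malformed Genepop input is rejected with location", {
  bad <- "t\nL1\nL2\nPop\nx, 001002\n"
  expect_error(read_genepop(text = bad), "line")
  mixed <- "t\nL1\nPop\nx, 0102\ny, 001002\n"
  expect_error(read_genepop(text = mixed), "mixed")
})

test_that("missing calls reduce the gene-copy denominator", {
  txt <- "t\nL1\nPop\na, 001001\nb, 001002\nc, 000000\n"
  g <- read_genepop(text = txt)[[1]]
  af <- allele_freqs(g)
  # hand count: 4 copies observed, 3x allele 1, 1x allele 2
  expect_equal(af$counts[["L1"]], 4L)
  expect_equal(unname(af$freqs$L1), c(0.75, 0.25))
})

test_that("allele frequencies are order-invariant and sum to one", {
  g <- gm(rbind(c(1, 1, 3, 4), c(1, 2, 3, 3), c(2, 2, NA, NA)))
  af <- allele_freqs(g)
  expect_equal(unname(af$freqs[[1]]), c(0.5, 0.5))
  for (f in af$freqs) expect_equal(sum(f), 1, tolerance = 1e-12)
  gp <- g[c(3, 1, 2), ]
  expect_equal(allele_freqs(gp)$freqs, af$freqs)
  # monomorphic locus
  gmono <- gm(rbind(c(5, 5), c(5, 5)))
  expect_equal(allele_freqs(gmono)$freqs[[1]], c(`5` = 1))
})

test_that("heterozygosity patterns match hand coding and mask missing", {
  m <- rbind(c(1, 2, 3, 3, NA, NA),
             c(1, 1, 2, 3, 4, 5),
             c(2, 2, 1, 1, 6, 6),
             c(NA, NA, NA, NA, NA, NA))
  g <- gm(m)
  h <- het_patterns(g)
  expect_equal(unname(h), rbind(c(1L, 0L, NA), c(0L, 1L, 1L),
                                c(0L, 0L, 0L), c(NA, NA, NA)))
  # fully masked individual is dropped by the selfing fit with a message
  g2 <- gm(rbind(c(1, 2, 1, 2), c(1, 1, 1, 2), c(NA, NA, NA, NA),
                 c(1, 2, 2, 2), c(1, 2, 1, 1)))
  expect_message(fit_selfing(g2, grid_step = 0.01), "dropped")
})

test_that("half-missing calls become fully missing", {
  calls <- array(c(1L, NA, 2L, 2L), c(1, 2, 2))  # locus 2 half-missing
  g <- genotype_matrix(calls)
  expect_true(all(is.na(g$calls[1, 2, ])))
  expect_false(anyNA(g$calls[1, 1, ]))
})

test_that("pooling concatenates rows but refuses mixed platforms", {
  g1 <- gm(rbind(c(1, 2), c(1, 1)), pop = "p", platform = "A3130")
  g2 <- gm(rbind(c(2, 2)), pop = "p", platform = "A3500")
  expect_error(pool_genotypes(g1, g2), "platform")
  pooled <- pool_genotypes(g1, g2, force = TRUE)
  expect_equal(n_ind(pooled), 3L)
  g3 <- gm(rbind(c(2, 2)), pop = "p", platform = "A3130")
  expect_equal(n_ind(pool_genotypes(g1, g3)), 3L)
})

test_that("CSV genotype and progeny dialects round-trip", {
  g <- gm(rbind(c(1, 2, 3, 3), c(1, 1, NA, NA)), pop = "P1", ecotype = "MET",
          year = 2012)
  f <- tempfile(fileext = ".csv")
  write_genotype_csv(list(P1 = g), f)
  back <- read_genotype_csv(f)[["P1"]]
  expect_equal(unname(back$calls), unname(g$calls))
  expect_equal(back$ecotype, "MET")

  cfg <- sim_config(seed = 9, n_loci = 3, n_alleles = 3, n_families = 2,
                    progeny_per_family = 3)
  arr <- sim_progeny_arrays(cfg)$arrays
  fp <- tempfile(fileext = ".csv")
  write_progeny_csv(arr, fp)
  back <- read_progeny_csv(fp)
  expect_equal(length(back$families), 2L)
  expect_equal(unname(back$families[[1]]$mother),
               unname(arr$families[[1]]$mother))
  expect_equal(unname(back$families[[2]]$progeny$calls),
               unname(arr$families[[2]]$progeny$calls))
  unlink(c(f, fp))
})
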