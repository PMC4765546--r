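#!/usr/bin/env Rscript
# Genetic diversity and among-population structure of the simulated survey:
# per-population diversity with F_IS bootstrap CIs, ecotype permutation
# comparisons, pairwise and hierarchical F-statistics, isolation by
# distance, and a centred PCA on allele dosages.

library(mixmating)

pops <- read_genotype_csv("results/data/genotypes.csv")
md <- read_metadata_csv("results/data/metadata.csv")
year1 <- pops[vapply(pops, function(g) g$year[1] == 1, TRUE)]

div <- diversity_table(year1, n_boot = 1000, seed = 11)
write.table(div, "results/diversity.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("Mean F_IS: MET %.2f, NONMET %.2f (heterozygote deficits in %d/10 populations)\n",
            mean(div$F_IS[div$ecotype == "MET"]),
            mean(div$F_IS[div$ecotype == "NONMET"]), sum(div$F_IS_nonzero)))

for (stat in c("H_exp", "F_IS")) {
  pc <- permutation_compare(year1, stat, n_perm = 5000, seed = 12)
  cat(sprintf("Ecotype difference in %s: %+0.3f (permutation p = %.3f)\n",
              stat, pc$observed, pc$p_value))
}

fst <- pairwise_fst(year1)
write.table(round(fst, 4), "results/fst_pairwise.tsv", sep = "\t", quote = FALSE)
hf <- hierarchical_f(year1, n_boot = 1000, seed = 13)
write.table(hf, "results/hierarchical_f.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("Hierarchical indexes: ecotype %.2f, population %.2f, individual %.2f\n",
            hf$index[1], hf$index[2], hf$index[3]))

popname <- vapply(year1, `[[`, "", "pop")
co <- data.frame(population = popname,
                 lat = md$lat[match(popname, md$population)],
                 lon = md$lon[match(popname, md$population)])
D <- geo_distances(co)
mt <- mantel(fst, D, n_perm = 5000, seed = 14)
ib <- ibd_regression(fst, D, n_perm = 5000, seed = 15)
cat(sprintf("Isolation by distance: Mantel r = %.3f (p = %.2f); slope of F_ST/(1-F_ST) on ln km = %.4f (p = %.2f)\n",
            mt$r, mt$p_value, ib$slope, ib$p_value))

ld <- ld_screen(year1, n_perm = 200, seed = 16)
cat(sprintf("Linkage screen: %d of %d locus pairs flagged for removal\n",
            sum(ld$remove), nrow(ld)))

pca <- pca_freqs(year1)
write.csv(data.frame(population = pca$population, pca$scores[, 1:4]),
          "results/pca_coords.csv", row.names = FALSE)
cat(sprintf("PCA: first four axes carry %.1f%% of the inertia\n",
            100 * sum(pca$inertia[1:4])))
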