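#!/usr/bin/env Rscript
# Fine-scale mating system from the progeny arrays: correlated mixed-mating
# model with family-bootstrap confidence intervals.

library(mixmating)

arr <- read_progeny_csv("results/data/progeny.csv")
fit <- fit_mating(arr, n_boot = 1000, seed = 51)
print(fit)

ef <- effective_fathers(fit$estimates$r_p)
cat(sprintf("Correlation of paternity %.3f -> about %d father(s) per sibship\n",
            fit$estimates$r_p, ef$n_fathers))
bp <- biparental_inbreeding(fit)
cat(sprintf("Biparental inbreeding (t_m - mean t_s): %.3f (95%% CI %.3f-%.3f)\n",
            bp$estimate, bp$ci95[1], bp$ci95[2]))

e <- fit$estimates
tab <- data.frame(parameter = c("s_multi", "t_m", "t_m_minus_ts", "r_t", "r_p", "F_p"),
                  estimate = c(e$s_m, e$t_m, e$biparental, e$r_t, e$r_p, e$F_p),
                  ci_lo = c(1 - fit$ci["97.5%", "t_m"], fit$ci["2.5%", "t_m"],
                            fit$ci["2.5%", "biparental"], fit$ci["2.5%", "r_t"],
                            fit$ci["2.5%", "r_p"], fit$ci["2.5%", "F_p"]),
                  ci_hi = c(1 - fit$ci["2.5%", "t_m"], fit$ci["97.5%", "t_m"],
                            fit$ci["97.5%", "biparental"], fit$ci["97.5%", "r_t"],
                            fit$ci["97.5%", "r_p"], fit$ci["97.5%", "F_p"]))
write.table(tab, "results/mating_system.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
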