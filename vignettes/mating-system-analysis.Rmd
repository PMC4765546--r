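---
title: "Models and methods in mixmating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mixmating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixmating)
```

mixmating characterises the mating system of diploid, partially selfing
plants from co-dominant multilocus genotypes. This vignette records the
models behind each estimator, the tunable parameters and their defaults,
the numerical choices that matter for reproducing results, and what the
bundled synthetic-data generators do and do not emulate.

## Selfing rates from multilocus heterozygosity

The central estimator treats each adult as carrying a latent number $n$ of
consecutive selfing generations since its last outbred ancestor. Under
inbreeding equilibrium at constant selfing rate $s$, $n$ is geometric:
$P(n) = (1-s)\,s^n$. A locus with outbred heterozygosity $h_l$ halves its
heterozygosity with every selfing generation, so the observed 0/1
heterozygosity indicators $x_l$ have likelihood

$$
L(s, h) \;=\; \sum_{n \ge 0} (1-s)\,s^n \prod_{l}
\left(h_l 2^{-n}\right)^{x_l} \left(1 - h_l 2^{-n}\right)^{1 - x_l}.
$$

Because only the joint *pattern* of heterozygosity across loci is used —
the correlation in homozygosity that variance in inbreeding creates
(identity disequilibrium) — the estimator is robust to null alleles and
allelic dropout, which inflate homozygosity locus by locus but do not
create correlation across loci. The $F_{IS}$-based alternative
$s = 2F/(1+F)$ has no such protection; `selfing_from_fis()` and
`equilibrium_fis()` implement the conversion and its inverse
$F = s/(2-s)$ for comparison.

Numerical choices:

* The geometric sum is truncated at the smallest $n_{\max}$ with
  $s^{n_{\max}+1} < 10^{-13}$ (capped at 60) and renormalised, so pattern
  probabilities sum to one exactly and the truncation error stays below
  the $10^{-12}$ level at which the single-locus closed form
  $P(x_l = 1) = h_l(1-s)/(1-s/2)$ is verified.
* `fit_selfing()` profiles the nuisance $h$ out by EM at every point of a
  regular grid of $s$ values (default step 0.001 on $[0, 0.999]$),
  warm-starting $h$ from the previous grid point, then refines the
  maximum to $10^{-4}$ by golden-section search. The 95% interval is the
  1.92 log-likelihood drop ($\chi^2_1$). Replicated simulation studies in
  the test-suite use a step of 0.005 — at that resolution the refined
  maximum is indistinguishable from the full grid for 50-individual
  samples, at a fifth of the cost.
* The inner treatment of $h_l$ is joint profile maximum likelihood (not a
  moment plug-in); the single-locus marginal above is the closed form the
  implementation is checked against.
* Individuals missing at every locus are dropped with a message; samples
  with no heterozygote at all give a boundary estimate at the grid
  maximum with an explicit warning, and fully monomorphic samples are an
  error.

## Comparing selfing-rate distributions between ecotypes

Populations are grouped (here: metallicolous vs non-metallicolous
ecotypes) and their selfing rates modelled as logit-normal random
effects: $\mathrm{logit}(s_i) \sim N(\mu_{g(i)}, \sigma_{g(i)})$. The
marginal likelihood combines each population's *profile* likelihood
$\ell_i(s)$ with the random-effect density,

$$
\ln L = \sum_i \ln \int \exp\{\ell_i(\mathrm{logit}^{-1} z)\}\,
\varphi(z;\mu_{g(i)},\sigma_{g(i)})\, dz ,
$$

evaluated by 64-node Gauss-Hermite quadrature. Constrained variants
(shared $\sigma$, shared $\mu$, $\sigma = 0$) are compared by standard
likelihood-ratio tests against $\chi^2$; `ecotype_pipeline()` runs the
ladder used to test first for unequal spreads, then for unequal means,
and finally the one-rate-per-group versus single-rate comparison with
$\sigma = 0$. Tests of $\sigma = 0$ sit on the parameter boundary; the
plain $\chi^2$ reference is used by default, which is the conservative
direction for declaring spread.

Numerical choices and caveats:

* Treating the profile likelihood as the exact likelihood of $s$ ignores
  the uncertainty in the nuisance $h_l$; this is the standard profile
  approximation and it is what makes per-population results composable.
* Profiles are interpolated between grid points by a natural cubic
  spline. Linear interpolation at the 0.001 grid leaves kinks of order
  $10^{-5}$ that dominate the quadrature error and break node-doubling
  convergence; with the spline, doubling 32 to 64 nodes moves the
  marginal log-likelihood by less than $10^{-6}$.
* $\sigma$ is bounded below by a numerical floor of 0.002 inside the
  optimiser; an estimate at the floor is reported as a boundary
  ("effectively zero spread") rather than a real value, and the fit
  adopts the exact $\sigma = 0$ collapsed likelihood when that is higher,
  which keeps nested-model log-likelihoods monotone to within $10^{-6}$.
* Optimisation is multi-start Nelder-Mead over a deterministic start grid
  (a moment start plus fixed perturbations), followed by a restart at the
  incumbent; no random numbers are consumed, so fits are byte-reproducible.
* The quadrature needs profiles no narrower than the node spacing: with
  very sharp profiles (curvature far exceeding $1/\sigma^2$) the
  random-effect integral is under-resolved. For the sample sizes this
  package targets (40-50 plants, 13-15 loci) profile width and
  among-population spread are comparable and the regime is benign.

The back-transformed group means reported as "mean selfing rate" are the
medians of the logit-normal; with $\sigma = 0$ (the regime selected by
the data in the motivating design) median and mean coincide.

## Progeny arrays: correlated mixed mating

For family-structured seed data the package fits the correlated
mixed-mating model: each family shares one Bernoulli outcrossing draw
with probability $r_t$ (else progeny draw independently with outcrossing
rate $t_m$), and the outcrossed members of a sibship share a single
father with probability $r_p$ (else fathers are independent draws from
the pollen pool, whose genotypes carry inbreeding $F_p$). Loci multiply
within a latent configuration (linkage equilibrium), and an unknown
maternal genotype is marginalised per locus over ovule genotype
frequencies at inbreeding $F_m$.

`family_loglik()` computes this likelihood exactly, enumerating the
latent classes, every selfed/outcrossed configuration, and per-locus
father (and mother) genotypes. The configuration sum is $O(2^k)$ in
family size $k$: with per-progeny selfing indicators and a father shared
across progeny, no factorisation over loci is possible (the indicators
couple loci while the father couples progeny). The exact function is
therefore a validation tool for small families.

`fit_mating()` maximises the sum of family log-likelihoods using a
decomposition in which every latent-class term is exact except one. The
all-selfed, all-outcrossed (with or without a shared father) and fully
independent configurations factorise — in particular, when *all*
progeny share the father the product factorises over loci and the
father marginal is an exact per-locus sum. Only the mixed term
(independent selfing draws combined with a shared father) couples
progeny and loci; it is integrated by importance sampling of the shared
father, drawn per locus from a proposal proportional to the
mixed-configuration integrand at a reference outcrossing rate. The 600
draws per family are fixed under the fit's seed, so the objective is a
smooth, deterministic function of the parameters and the whole analysis
stays byte-reproducible; against the exact enumeration on small
families the approximation agrees to a few hundredths of a log-unit.
This "full" method requires maternal genotypes (a per-locus
maximum-likelihood assignment fills gaps). When mothers must be
marginalised, `fit_mating(method = "composite")` — the automatic
fallback — maximises a pairwise composite likelihood over within-family
sib pairs instead: exact at the pair level, where the correlation
parameters are defined, with each (pair, locus) contribution reduced to
twelve precomputed coefficients (the likelihood is linear in $F_m$ and
bilinear in $(F_m, F_p)$). The composite surface overweights large
sibships (every pair counts), so its curvature in $r_t$ is exaggerated
relative to the full likelihood; it is retained for the
marginalised-mother case and as a cross-check, not as the default.

Bootstrap resampling of whole families (default 1000 replicates,
percentile intervals) only reweights precomputed family contributions,
which keeps a full bootstrap at the 20-family x 15-progeny design in
the minutes range. Resampled fits restart from the neutral default
start rather than the incumbent estimate: boundary estimates (e.g.
$\hat r_t = 0$) sit in flat likelihood regions where a warm start would
pin every replicate to the boundary and artificially narrow the
intervals. Single-locus outcrossing rates $t_s$ are refit per locus —
exactly, since a single locus admits full father enumeration — with the
correlation parameters held at their multilocus values;
$t_m - \overline{t_s}$ estimates biparental inbreeding (mating among
relatives inflates apparent selfing at single loci only).

Design decisions:

* The maternal prior couples to the current parameter value as
  $F_m = s_m/(2 - s_m)$ with $s_m = 1 - t_m$ (the selfing equilibrium),
  inside the likelihood, rather than through an outer one-step
  iteration; the fit stays smooth and self-consistent. A per-locus
  maximum-likelihood maternal assignment is available
  (`infer_mother = "ml"`).
* The paternal inbreeding coefficient is attached to the *shared* father
  (correlated paternity); an independently drawn father transmits a
  gamete whose allele frequencies are the pollen-pool frequencies
  regardless of his inbreeding, so $F_p$ is only identified through
  father sharing.
* Pollen and ovule pools share the sample allele frequencies by default
  (the parsimonious model); externally supplied frequencies are smoothed
  by one gene copy for observed alleles they lack, so sampling noise
  cannot generate impossible genotypes.
* Optimisation is on the logit scale with five starts; boundary
  estimates (e.g. certain outcrossing, $t_m \to 1$) are flagged.

## Population structure

All fixation indexes use the Weir-Cockerham (1984) variance-components
estimators, with multilocus values combined as ratios of summed
components. The three-level decomposition (ecotype / population within
ecotype / individual within population) generalises the same ANOVA to a
four-level unbalanced nested design on gene copies; expected
sums-of-squares coefficients are computed exactly from the design
(traces of the averaging quadratic forms), and the two-level collapse
reproduces the pairwise Weir-Cockerham $\theta$ estimator. Confidence
intervals bootstrap loci (default 1000 draws); between-ecotype
comparisons of $H_{obs}$, $H_{exp}$, $F_{IS}$ and $F_{ST}$ permute whole
populations between groups (default 5000 permutations, two-sided, +1
correction).

Ancillary analyses follow the conventional workflow: a linkage screen
that removes a locus pair only when a permutation G-test is significant
*and* the composite genotypic correlation exceeds 0.5 in more than two
populations; haversine distances on a 6371-km sphere; simple Mantel
tests (one-sided for positive association; the identity permutation is
represented by the +1 term rather than sampled); the linearised
isolation-by-distance regression of $F_{ST}/(1-F_{ST})$ on log distance
with a Mantel-style permutation p-value (pairs are not independent, so
the parametric p-value is not primary); and a centred, unscaled PCA on
0/1/2 allele dosages with mean imputation of missing dosages.

Two closed forms from mating-system arithmetic are exposed directly:
`ne_reduction_from_selfing()` (the relative effective-size reduction
$1 - (1+F(s_1))/(1+F(s_2))$ implied by two selfing rates) and
`required_inbreeding_depression()` (the survival inbreeding depression
$\delta$ solving $s_{adult} = s(1-\delta)/(1-s\delta)$ that would
reconcile a primary selfing rate with a lower adult-stage estimate).

## Temporal effective size

Two seasonal samples of one population inform the variance effective
size through the magnitude of allele-frequency change. Per locus, each
allele is collapsed to focal-vs-rest; the likelihood of a candidate
$N_e$ integrates a uniform prior on the initial frequency, binomial
sampling of gene copies in each season, and $g$ generations of
Wright-Fisher drift, assuming a closed population. Contributions are
summed over alleles and loci (a composite likelihood). For
$N_e \le 500$ the drift kernel is the exact $(2N_e+1)$-state binomial
chain with the prior on interior lattice states; above that, a beta
kernel matched to the Wright-Fisher mean and variance integrates against
the sampling binomial in closed form (beta-binomial), with a 64-point
midpoint grid on the initial frequency (doubling the grid moves the
log-likelihood by under $10^{-4}$). The two modes agree to total
variation below 0.01 where they overlap. `fit_ne()` maximises over a
log-spaced grid with golden-section refinement, using a linear blend of
the two kernels over Ne in [400, 600] so that the hand-off cannot leave
a step in the profile (in a flat profile even a 0.1 log-unit step fakes
a mode); the 95% interval is the 1.92-drop profile interval, computed
by root finding on the continuous profile. Estimates or upper bounds at
the search cap (default 50 000, configurable) are flagged, and a
profile that never drops appreciably below its maximum out to the cap
is reported *at* the cap: saturation simply means the samples show no
more frequency change than sampling noise alone. The classical
moment (temporal-F) estimator with sampling correction is provided as a
cross-check (`fk_moment_ne()`).

The interval between two consecutive reproductive seasons is treated as
one generation (`generations = 1` by default): most individuals in the
target system are functionally annual, though a configurable parameter
acknowledges that partial biennial flowering blurs generation length.
Sampling is treated as plan II (individuals sampled before reproduction
and not returned).

## Synthetic data

The generators in `sim_config()` / `sim_*()` produce data with exactly
the statistical structure the estimators assume, and they are the basis
of every calibration claim in the test-suite:

* `sim_population()` draws each individual's selfing-generation count
  geometrically, builds genotypes by Mendelian selfing from an outbred
  Hardy-Weinberg draw, and implements null alleles as allele-specific
  non-amplification: an extra null allele of the configured frequency
  segregates at the locus, carriers appear homozygous for their other
  allele, and null homozygotes are missing.
* `sim_metapopulation()` places population allele frequencies around
  shared base frequencies by the Balding-Nichols model (Dirichlet with
  concentration $(1-\theta)/\theta$) and draws population selfing rates
  logit-normally within ecotype. Defaults encode the study conditions
  the package targets: 5 + 5 populations, 45 plants each, 14 loci with
  6 alleles, ecotype means 0.25 and 0.40 with zero logit-scale spread,
  $\theta_{pop} = 0.25$, no ecotype-level divergence.
* `sim_progeny_arrays()` implements the correlated mixed-mating
  generative model (the same latent-class structure the likelihood
  uses) at the 20-mother x 15-seed design with $t_m = 0.75$,
  $r_t = 0.10$, $r_p = 0.30$, $F_p = 0.10$.
* `sim_temporal()` propagates allele counts through multinomial
  Wright-Fisher generations at the configured $N_e$ (default 100) and
  draws Hardy-Weinberg samples each season.

What the generators do *not* emulate — and what passing tests therefore
do not certify for field data: genotyping error beyond the null-allele
mechanism, linkage between loci, spatial substructure within
populations, overlapping generations and seed banks, immigration during
the temporal interval, and selection. The estimators inherit the
corresponding assumptions (inbreeding equilibrium, closed populations,
linkage equilibrium).

## Problem sizes and reproducibility

Every stochastic function takes a `seed` and restores the caller's RNG
state, so analyses are pure functions of (inputs, configuration, seed)
and pipeline outputs are byte-reproducible. The test-suite's replicated
calibration studies use 100-500 replicates at the study design (50
plants x 14 loci; 20 x 15 progeny arrays with 150 bootstrap draws;
100-individual temporal samples at 20 loci), with the 0.005 profile
grid; one-off fits use the full defaults. The pipeline's default
permutation and bootstrap counts (5000 / 1000) match the motivating
analysis; the bundled end-to-end fixtures scale these down (300 / 150)
to keep a complete run in the minutes range.

## Known limitations

* The composite (pairwise) likelihood in `fit_mating()` is not the full
  family likelihood; it is consistent and exact at the pair level, but
  point estimates can differ slightly from a full-likelihood fit, and
  likelihood *values* are not comparable across nesting structures.
  Single-locus $t_s$ estimates carry the usual small finite-sample
  downward bias of low-information single-locus fits.
* The selfing estimator assumes inbreeding equilibrium; after a recent
  change in mating system it estimates a multi-generation blend.
* The hierarchical model conditions on estimated profiles; extremely
  peaked profiles (huge samples) would need more quadrature nodes.
* Temporal $N_e$ assumes no immigration; gene flow inflates apparent
  drift and biases $N_e$ downward.
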