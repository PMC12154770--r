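---
title: "Models and methods in gardensort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gardensort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardensort)
```

`gardensort` analyses replicated multi-garden evolve-and-resequence
experiments of a highly selfing annual plant. A fixed panel of inbred
founder accessions is sown at near-equal frequency in replicated trays
across gardens with contrasting climates; surviving reproductive plants
are pool-sequenced over successive generations. Because the founders
self, adaptation proceeds mainly by *accession sorting*: whole inbred
genomes rise or fall in frequency according to their fitness in each
garden, with occasional outcrossing creating recombinants. This vignette
documents the models, the estimation choices, and the synthetic data
used to test them.

## The forward simulator

The simulator (`generate_founder_panel`, `sim_params`, `garden_design`,
`simulate_experiment`) is a first-class, tested component: it defines
the study conditions under which every statistical property of the
package is verified.

**Founder panel.** Genotypes are homozygous 0/1 dosages. A latent
ancestry coordinate per accession drives both per-SNP allele
probabilities (through per-SNP logistic clines of random strength) and
the climate of origin, so allele sharing is structured and
climate-associated, as in a real species range. Along each chromosome a
copy process (`ld_decay`, the correlation length in SNP-index units;
copy probability `exp(-1/ld_decay)`) creates linkage blocks;
`ld_decay = 0` gives independent SNPs. The founder seed mix targets
`1/n_accessions` per accession with Dirichlet jitter at concentration
5000, i.e. deviations on the 0.1% scale, matching the precision of a
carefully balanced seed mix.

**Fitness.** Expected fitness of accession $a$ in garden $g$ follows
the Gaussian stabilizing-selection form
$$w_{ag} = W_{\max,a}\, e^{-V_{s,a}^{-1} (z_{\mathrm{origin},a} - z_{\mathrm{garden},g})^2},$$
where $z$ is a chosen climate variable (an annual-mean-temperature
analogue by default), $W_{\max,a}$ the accession's peak fitness and
$V_{s,a}^{-1}$ its rate of fitness decay per squared climate unit
(niche narrowness).

**Life cycle.** Generations are discrete and non-overlapping; sites
with two generations per year are represented simply by more generation
steps, indexing on sequencing events rather than calendar years. Each
of $N$ plants sets seeds in proportion to relative fitness — exactly
proportional under the `uniform` model (largest-remainder rounding of
`fecundity * N * w/sum(w)`), Poisson-distributed around it under
`poisson`. `fecundity` (default 10) sets the seed-pool size
$S = N\,\mathrm{fecundity}$ before regulation; it is a computational
stand-in for the thousands of seeds a real plant sets — what matters
for drift is the ratio $S/N$, and the default already puts the
without-replacement correction factor near its large-$S$ limit.
Density regulation samples $N$ seeds from the pool without replacement
(soft selection: mean fitness is an implicit normalizer). With
probability `outcross_rate` an offspring is an outcrossed recombinant
with exactly one crossover uniformly placed per chromosome — enough to
create recombinant genomes without modelling a genetic map. Recombinant
offspring are assigned mid-parent fitness and are counted in their
maternal accession's lineage for frequency accounting, mirroring how
deconvolution attributes recombinants mostly to their closest founder.

**Observation.** `sample_poolseq` draws flowers multinomially over
individuals, per-SNP depth as Poisson around the mean coverage
(default emulation target: 10X), and alternate reads binomially with a
symmetric ref/alt substitution error (default 0.7%, on the scale of the
reconstruction error achievable from real pooled data).

## Frequency reconstruction

`estimate_allele_freq` is the raw estimator `alt/(ref+alt)` with a
configurable `min_depth` (default 1 — no depth filter beyond
observability, since the linkage step below does the denoising).

`deconvolve_accessions` reconstructs the founder mixture of a pool by
simplex-constrained ridge least squares,
$$\hat f = \arg\min_{f \ge 0,\ \sum f = 1} \lVert G^\top f - p\rVert^2 + \lambda \lVert f\rVert^2,$$
with $G$ the accession-by-SNP dosage matrix and $\lambda = 10^{-4}$ by
default for rank safety when accessions are nearly duplicated. The
solver compresses the normal equations by a Cholesky factor and runs
Lawson–Hanson non-negative least squares on the reduced system, with
the sum-to-one constraint imposed as a weighted row and enforced
exactly by final renormalization. Residual founder heterozygosity is
coded as dosage 0.5; missing founder calls are mean-imputed per SNP for
the solve only.

`smooth_frequencies` is the linkage-based error-reduction step:
frequencies are replaced by their projection through the reconstructed
mixture, $p_{\text{smooth}} = G^\top \hat f$. Every founder genome ties
together all of its sites, so independent per-SNP sampling noise is
shrunk genome-wide. The exact linkage-exploiting algorithm used on real
data of this kind is not uniquely specified in the literature we
emulate; projection through the accession mixture is one admissible
realization and is documented as such. It is idempotent and exact for
monomorphic sites.

## Neutral nulls and divergence

Two neutral references are provided. The analytic Wright–Fisher
variance is $p_0(1-p_0)/2N$ with $N$ defaulting to the number of
individuals sequenced — a deliberately conservative choice. The
accession-sorting null (`simulate_neutral_sorting`) resamples whole
accessions through founding and seed-pool thinning without outcrossing;
for the uniform seed-set model its one-generation variance has the
closed form implemented in `sorting_variance`,
$$\mathrm{Var}(\Delta p) = \frac{p_0(1-p_0)}{N}\Big[1 + \big(1 - \tfrac1N\big)\frac{S-N}{S-1}\Big],$$
obtained by the law of total variance over multinomial founding and
hypergeometric thinning.

`variance_ratio_test` reports the ratio of mean squared observed change
to mean null variance with a bootstrap CI over SNPs, a Mann–Whitney U
comparison of the squared-change distributions, and a per
starting-frequency-decile breakdown (deciles with fewer than 50 SNPs
merged). The bootstrap-over-SNPs CI assumes approximately independent
per-SNP contributions; when all SNPs share a single population's
accession draw the effective degrees of freedom are far fewer than the
SNP count, so calibration checks draw the observed changes
independently per SNP and use the analytic null. Real analyses pool
many samples, which brings them close to this regime.

F\_ST uses the Hudson estimator as a genome-wide ratio of averages
(never averaging per-SNP ratios), with the pool depth as the sample
size in the sampling-correction term. PCA of frequency change runs on
the founder-centred matrix $p_t - p_0$ without re-centering, so the
founder state projects to the origin by construction; a set of samples
identical to the founder therefore has zero variance. Repeatability is
the mean pairwise Spearman correlation of frequency change between
replicates; heritability of frequency change is the one-way
random-effects variance-component ratio estimated by ANOVA method of
moments and truncated into [0, 1] — REML machinery is unnecessary at
this scale.

## LD blocks and the selection scan

`build_ld_blocks` chains SNPs greedily along each chromosome: a SNP
joins the current block if its $r^2$ with any of the last `max_gap`
(default 10) block members reaches `r2_threshold` (default 0.5).
Monomorphic SNPs carry no linkage information and start their own
blocks. The defaults are tuned for sensible synthetic block sizes, not
to reproduce any particular real-panel block count.

The replicate-consistency test `lrt_parallel_selection` is a
one-parameter binomial likelihood-ratio test: under the null all
replicate counts at both timepoints share one frequency; under the
alternative the replicates share the founder frequency at $t_0$ and one
common post-selection frequency at $t_1$. The statistic is referred to
$\chi^2_1$; an empirical null from neutral simulation is recommended
when depths are low. Block summaries use the minimum p with a
within-block Bonferroni factor (the aggregate-vs-min-p choice is
documented here as min-p). The scan reports the genomic inflation
factor $\lambda_{GC}$.

`block_overlap_permutation` preserves each garden's significant-set
size and resamples block ids uniformly; its p-value has the guaranteed
lower bound $1/(n_{\mathrm{perm}}+1)$ and, being built on a discrete
overlap count, is slightly conservative — near-uniformity under the
null is only reached when the block universe is large enough for the
overlap count to be effectively continuous.

## Stabilizing-selection fits

Because $p_{t+1}/p_t = w/\bar w$ for a selfing mixture, log frequency
ratios are fitness proxies. `fit_global_stabilizing` regresses
$\log(p_{t+1}/p_t)$ on the negative squared climate distance with
garden fixed offsets; $\bar w$ is never estimated from census data —
the per-garden offset absorbs it (soft selection), with the first
garden anchored at zero for identifiability. `fit_per_accession`
estimates accession-specific intercepts ($\log W_{\max}$) and slopes
($V_s^{-1}$) **jointly** with the shared garden offsets in one linear
model: estimating offsets first under a single shared slope and then
fitting accessions one at a time biases the offsets whenever niche
widths vary, so the joint fit is used and recovers noiseless model data
exactly. Negative fitted $V_s^{-1}$ is truncated to zero and flagged
rather than dropped. The pseudo-frequency `epsilon = 1e-4` (about half
a flower in a 5,000-seed pool) keeps boundary frequencies finite;
records with $p_t < 10^{-5}$ are flagged and excluded from fits.

`realized_optimum` weights garden climates by either $p_1/p_0$
(default) or $p_1$; both are offered because the weighting used in
comparable field studies is not uniquely determined, and the two agree
in direction on simulated data. The specialist–generalist trade-off is
the Spearman correlation between fitted $\log W_{\max}$ and
$V_s^{-1}$.

## Experimental genome–environment association

The default response is the per-garden mean logit frequency change,
averaged over replicates (raw $\Delta p$ available). Three per-SNP
frameworks are provided: Kendall's $\tau$ (exact p for small garden
numbers), a quasi-binomial GLM of alt/depth on climate with depth
weights (overdispersion by Pearson $\chi^2/\mathrm{df}$; complete
separation triggers a flagged ridge-penalized IRLS refit), and a
latent-factor-corrected linear model in which the top $k$ principal
factors of the response matrix are regressed out of both response and
climate. The latter is a deliberately light-weight stand-in for a full
latent factor mixed model: PC-residualization captures the dominant
shared structure at a fraction of the machinery, at the cost of not
modelling factor uncertainty.

WZA pooling converts per-SNP p-values to $z = \Phi^{-1}(1-p)$ and
combines them within blocks as $\sum w_i z_i / \sqrt{\sum w_i^2}$ with
founder-heterozygosity weights $p(1-p)$ (uniform weights available for
sensitivity). Block scores are inflation-corrected by a median-based
$\lambda$ on $z^2$ before one-sided p-values and BH FDR. One climate
variable is scanned at a time; a 19-variable sweep is a loop with
per-variable FDR. Note that under strongly polygenic selection the
inflation correction absorbs genome-wide signal, so the block-level
discovery fraction measures *excess over the polygenic background*,
not the presence of selection per se.

## Forecasting

`fit_logistic_trajectory` regresses logit frequencies (clipped to
$[10^{-4}, 1-10^{-4}]$) on time or climate; block-level rates are
averages of member-SNP slopes. `estimate_selection_coefficient` uses
the haploid-lineage competition model in which carrier odds multiply by
$(1+s)$ per generation, so $\hat s = e^{\text{logit slope}} - 1$; with
exactly two timepoints the estimate is exact and the CI undefined (no
residual degrees of freedom). Diploid fitness parameterizations are out
of scope.

`fit_genomic_offset` fits per-SNP logistic clines of evolved frequency
against training-garden climate (linear regression on the logit scale —
exact on noiseless logistic data); `go_score` is the mean absolute
mismatch $\frac1n \sum_i |p_{\mathrm{adapt},i}(z) - X_{a,i}|$ between
predicted adaptive frequencies and an accession's dosages, in [0, 1],
lower meaning better predicted fit. The SNP subset defaults to blocks
significant in a training-gardens-only eGEA (no leakage into the
held-out garden), falling back to all SNPs when nothing is significant
at the simulated scale. For inbred 0/1 genotypes the offset is least
informative where a cline crosses 0.5 — at gardens near the species'
niche centre every genotype mismatches by about 0.5 there — so offset
predictability is intrinsically strongest toward climate extremes;
simulated checks therefore evaluate the *average* leave-one-out rank
correlation across the gradient.

`loo_predictability` trains on all gardens but one and correlates
(Spearman, per replicate) the predicted accession ranking with the
observed $\log(p_1/p_0)$. The `go_plus_stabsel` scorer combines the
z-scored $-\mathrm{GO}$ with the z-scored stabilizing-selection
predicted log fitness
($\log W_{\max,a} - V_{s,a}^{-1} d_{ag}^2$ from training-garden fits);
z-scoring puts the two heterogeneous scales on an equal footing before
summing, the simplest combination that needs no tuned weight.

`survival_model` is a logistic regression of replicate survival on
predictability ($r^2$), garden temperature and their interaction
(per-replicate $r^2$ enters the model; per-garden means are an offered
alternative); degenerate outcomes or separation trigger a flagged
ridge refit. Isolines solve the fitted model for the $r^2$ needed to
reach a given survival probability at each temperature.
`census_trajectory` fits a quadratic of census size on generation
pooled over replicates; a rebound (evolutionary-rescue-like U shape)
requires a positive quadratic coefficient with an interior minimum and
either a significant coefficient (p < 0.05) or an exactly saturated
3-point fit, which has no residual degrees of freedom but determines
the parabola completely.

## Numerical choices and test design

Simplexes are validated to sum to one within `1e-9` (inputs) and
`1e-6` (deconvolution outputs). Logit transforms clip at `1e-4`
(frequencies) and the WZA clips zero p-values at the smallest positive
double with a warning. All simulations accept seeds and are
bit-reproducible; `simulate_experiment` derives independent per
garden-replicate streams from one base seed.

The test suite verifies each operation against an independent oracle —
closed forms (Wright–Fisher and sorting variances, Hudson F\_ST by
hand, the BH step-up, the exact three-point parabola), brute-force
computation (grid-maximized binomial likelihoods for the LRT,
exhaustive 6! permutation enumeration for Kendall's exact p, a
re-implemented greedy chaining for LD blocks), and Monte-Carlo
self-null calibrations. Study-scale checks use 50-accession panels
with 2,000–5,000 SNPs, 10 gardens with 6 replicates at carrying
capacity 400–800, 200-run coverage simulations for the global
stabilizing fit (231 accessions by 30 gardens, noise SD 0.5) and the
selection-coefficient estimator, and 2,000-block calibrations for WZA —
sizes chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well below the tested margins. eGEA
calibration and power runs generate per-garden responses with
independent noise on the logit scale (the regime where depth sampling
dominates), which isolates the calibration property from LD-induced
correlation; power is driven by a causal block shifting
$\log(1+s)$ per standardized climate unit.

What passing these tests shows — and what it does not. The synthetic
generator reproduces the structural features the methods rely on
(inbred founders, near-equal mixes, LD blocks, climate-linked ancestry,
drift under seed-pool regulation, pool-seq noise), so the tests
demonstrate internal consistency, calibration and parameter recovery
under the stated models. Real data add unmodelled features — germination
and dormancy phenology, seed banks, weather time series, spatially
correlated microenvironments, dispersal between trays, reference bias
in sequencing — and results on real data depend on those; the package
deliberately starts at allele counts and one climate value per garden.

## Known limitations

* The deconvolution is a generic simplex-constrained ridge solver; it
  does not exploit haplotype mosaics of recombinant individuals, which
  are attributed mostly to their nearest founders.
* The latent-factor eGEA is PC-residualization, not a full LFMM;
  factor-number choice is the user's.
* The permutation overlap p is conservative for small block universes.
* Genomic offset scores saturate near the niche centre for inbred
  genotypes (see above).
* Selection coefficients assume clonal (selfing) lineage competition;
  outcrossing dilutes the interpretation of $s$ at linked sites.
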