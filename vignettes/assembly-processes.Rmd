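---
title: "Partitioning community assembly processes: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community assembly processes: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method leaves room.

## 1. The process-partition model

Community assembly is read off two complementary null models computed for
every unordered pair of samples.

**Phylogenetic turnover (βMNTD / βNTI).** βMNTD is the abundance-weighted
mean, over the taxa of one community, of the patristic distance to the
nearest relative in the other community, symmetrised between directions. Its
ecological premise is *phylogenetic niche conservatism at the tips*: close
relatives have similar environmental requirements, so environmental
filtering concentrates communities into clades, and turnover between
differently filtered communities exceeds what random taxon placement
produces. The null shuffles taxon labels across the tips of the regional
pool — taxa present in at least one sample — independently per replicate
(999 by default); one shuffle per replicate serves all pairs, so results do
not depend on pair evaluation order. βNTI is the z-score of the observed
βMNTD in that null.

Interpretation follows the standard effect-size convention: βNTI ≥ +2 means
*more* phylogenetic turnover than expected (heterogeneous, or variable,
selection — divergent environments), βNTI ≤ −2 *less* than expected
(homogeneous selection — a shared filter). Pairs with |βNTI| < 2 are
adjudicated taxonomically: RC_bray ≥ 0.95 is drift under dispersal
limitation, RC_bray ≤ −0.95 homogenizing dispersal, anything else
undominated. The βNTI test takes precedence; RC is not consulted when
selection is significant.

**Taxonomic turnover (RC_bray).** The Raup–Crick null preserves what a pair
of samples trivially owes to its richness and sequencing depth: null
communities keep each sample's observed richness and total abundance, draw
taxon identities without replacement with probability proportional to
regional occupancy, then allocate individuals multinomially by regional
relative abundance. RC = 2[(#null < obs) + ½(#null = obs)]/reps − 1.

Two degenerate behaviours are worth knowing. On a star phylogeny the
tip-shuffle null cannot change any distance; such pairs get βNTI = 0 and an
explicit flag rather than NaN. More subtly, a taxon *shared* by two
communities is its own nearest relative at distance zero under every
shuffle, so fully identical communities have βMNTD = 0 in the observed data
*and in every null replicate* — the pair is flagged, not scored strongly
negative. Phylogenetic clustering is only detectable for communities that
are clade-confined yet compositionally distinct, against a pool that is
wider than the clade. This also means homogeneous selection is structurally
invisible when *every* sample in a study is filtered toward the same
optimum: the observed pool then collapses to the filtered clade and the
null has nothing wider to compare against (section 4).

## 2. Networks, Zi–Pi and keystones

Per group, taxa present in at least half of the group's samples (the same
presence rule used for group-level presence/absence) enter a Pearson
correlation matrix of relative abundances. The threshold is not chosen by
hand: scanning candidate cutoffs (0.30–0.99 by 0.01), entries below the
candidate are zeroed and the eigenvalue spectrum of the resulting matrix is
unfolded with a smoothing spline fitted to the empirical cumulative spectral
density (degenerate repeated eigenvalues excluded); the nearest-neighbour
spacing distribution is tested by chi-square (⌈√k⌉ equal-probability bins)
against the Poisson law P(d) = e^(−d). The chosen threshold is the lowest
candidate whose spacings are Poisson-consistent (p > 0.05) and remain so for
two further steps — the point where surviving correlations behave as
system-specific signal rather than random-matrix noise. Matrices under 20
nodes have no usable spectral statistics; a configured fallback threshold is
used and flagged.

Edges keep both correlation signs (|r| ≥ threshold). Modules come from
CNM-style greedy modularity maximisation; the merge dendrogram is cut at
the level whose recomputed modularity is highest, with ties to the coarser
partition (the library's own cut can miss the final merges on degenerate
graphs such as cliques). Zi is the within-module degree z-score (modules
with zero within-degree variance give Zi = 0, flagged); Pi = 1 − Σ_t
(k_it/k_i)². Roles: Zi > 2.5 module hub, Pi > 0.62 connector, both —
network hub; the three classes together are the keystone taxa. Both
thresholds are configuration values.

## 3. Driver attribution

Environmental factors and keystone relative abundances are min–max scaled
per variable — the scaling the rest of the analysis uses, making the two
variable families commensurate — and combined by PCA (covariance of the
column-centred scaled data). Each axis is sign-fixed so its
largest-magnitude loading is negative; attribution uses absolute loadings,
so this is purely a reproducibility convention.

The PCA axes are fitted to the βNTI and RC_bray matrices by distance-based
RDA. Neither matrix is a metric distance; when negative entries are present
the matrix is shifted by its off-diagonal minimum (already non-negative
responses are left untouched — shifting a genuine distance only distorts its
geometry), and the shifted dissimilarity is embedded with a Lingoes
correction inside `vegan::capscale`. A configuration switch substitutes
|βNTI| for the shifted values.

Forward selection is a double-stopping procedure:

1. **Gatekeeper**: a permutation test of the full model; if it is not
   significant at α = 0.05 nothing is selected. Without this, choosing the
   best of ~10–30 candidate axes makes per-step entry tests strongly
   anti-conservative.
2. **Entry**: the candidate with the largest adjusted-R² (Ezekiel) gain
   enters if its permutation p ≤ α.
3. **Stops**: no candidate improves adjusted R²; or the model's adjusted R²
   would exceed the full model's by more than a slack of 0.01. The slack
   exists because when one axis carries essentially all explainable
   structure, its adjusted R² equals the full model's *in expectation* and
   fluctuates around it — a strict bound would halt the selection on a coin
   flip. When the full model is saturated (as many axes as residual degrees
   of freedom, e.g. 31 axes on 32 samples) its adjusted R² is undefined and
   this bound is inapplicable; the gatekeeper and entry tests then carry the
   control alone. An exact zero-residual fit has an undefined permutation F
   and is treated as maximally significant.

The variable with the maximum |loading| on an axis retained against βNTI is
selection-related; on an axis retained against RC_bray but not βNTI,
dispersal-related. Environmental variables and taxa are also ranked
separately per axis, since a keystone taxon frequently out-loads every
abiotic factor.

The three-set RDA comparison (`rda_explained`) reports constrained over
total inertia; community abundances are Hellinger-transformed by default
(identity available). The 99-random-subcommunity control draws subsets with
as many taxa as the keystone set and locates the keystone set's explained
variance in that null with add-one empirical p-values, upper, lower and
two-sided.

## 4. What the simulator emulates — and what it does not

`simulate_communities` emulates the study design the package was built
around: 4 groups × 8 replicates, a 200-taxon metacommunity (the
1195-taxon study scale is a documented large preset via `n_taxa`), 5000
individuals per sample, and six named sediment covariates (pH, ORP,
Moisture, NH4, TN, TOC) responding linearly, with factor-specific noise, to
a latent per-sample niche environment.

The generative chain: a unit-rate Yule tree; Brownian niche optima along it
(the phylogenetic conservatism βNTI needs); a lognormal metacommunity
(sdlog = 2, a strongly uneven abundance distribution typical of sediment
16S surveys). Under *selection*, sampling weights are the metacommunity
times a Gaussian filter exp(−(trait − env)²/2σ_w²) with σ_w expressed in
tip-trait standard deviations (default 0.15, strong filtering); group
optima sit at trait quantiles, by default alternating two environmental
levels (0.1 and 0.9) across the four groups — a two-level,
strong-filtering design. Under *neutral* assembly, weights mix the
metacommunity with a group-local pool drifted from it by lognormal
perturbation (sd 2): m = 1 is homogenizing dispersal, m = 0.02 dispersal
limitation. Samples are multinomial draws of `depth` individuals, so drift
enters implicitly through finite sampling. All randomness fans out from one
master seed; the same spec reproduces byte-identical tables.

Two deliberate design notes. First, the selection regime supports a
mass-effect immigration fraction, but its default is zero: βMNTD is a
minimum-distance statistic, and even trace immigrants seed every clade with
close relatives, erasing the between-level phylogenetic signal. Second, the
shared-optimum ("homogeneous selection") preset is faithful to its
ecological definition but *not recoverable by the method itself*: with all
samples filtered identically, the observed regional pool is the filtered
clade, and a pool-referenced null cannot detect clustering against it. Its
dominant inferred process is undominated. This is a documented property of
pool-referenced null models, not a defect of the classifier — and it mirrors
the empirical situation in single-habitat surveys, where homogeneous
selection rarely dominates any pair. Regime-recovery checks therefore
expect 3 of the 4 presets to map onto their nominal processes.

What the simulator does not emulate: sequencing error, chimeras and
copy-number variation; compositionality artefacts of relative-abundance
data; temporal dynamics; spatially explicit dispersal kernels; and any
correlation structure among the six covariates beyond their shared latent
axis. Passing recovery tests on these simulations therefore shows the
*inference machinery* is sound under its own assumptions, not that those
assumptions hold in any particular sediment survey.

## 5. Numerical choices and problem sizes

- Rarefaction defaults to the minimum sample total, sampling without
  replacement, seed recorded; counts stay integer until relative abundances
  are requested.
- Shannon diversity is reported in nats (log2 switch available); Chao1 uses
  F1²/(2F2) with the bias-corrected F1(F1−1)/2 branch when no doubletons
  exist.
- ANOSIM uses mid-ranks for ties and the add-one permutation convention
  (999 permutations by default), so p is never zero.
- βNTI with a null standard deviation that is zero up to floating point
  (relative tolerance 1e-6 — the running-sum variance loses about half the
  mantissa to cancellation, while real null standard deviations are orders
  of magnitude larger) yields 0 with a flag.
- Raup–Crick pair streams are seeded from the master seed and the sorted
  pair of sample ids, making the matrix invariant to row order and
  evaluation order; ties with the observed value count half.
- Contribution percentages are printed to one decimal, rounding half up.
- The default problem sizes (200 taxa, 32 samples, depth 5000, 999 null
  replicates; 999 permutations for ANOSIM and selection) keep a full
  pipeline run in the low minutes on a single core; they are the package's
  chosen working scale, with the study-sized 1195-taxon preset available
  through `n_taxa`.

## 6. Known limitations

- The tip-shuffle null is the only βNTI null shipped as default;
  per-pair-pool shuffling is exposed but non-default, and other
  randomisations (e.g. abundance-preserving swap nulls) are out of scope.
- Quantitative process strength (continuous stochasticity ratios) is not
  estimated; the five-way classification is the unit of reporting.
- Drift is not separable from dispersal limitation beyond the RC_bray rule.
- The RMT threshold needs a reasonably large correlation matrix; below 20
  nodes the fallback threshold governs, and with 8 samples per group the
  correlation estimates themselves are noisy — keystone sets from such
  groups should be read as hypotheses, which is also how the random
  subcommunity control treats them.
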