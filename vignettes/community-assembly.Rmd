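---
title: "Community assembly and biogeography of marine microbial metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly and biogeography of marine microbial metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceancomm)
```

## What this package does

`oceancomm` analyses amplicon surveys of marine microbial communities — an
ASV count table, a rooted phylogeny and per-sample metadata — through four
connected lenses:

1. **Diversity**: rarefaction to even depth, Shannon-Wiener, Gini-Simpson,
   Pielou evenness, rooted Faith phylogenetic diversity and Good's coverage;
   Hellinger transformation, Bray-Curtis dissimilarity, PCoA, and Wilcoxon
   comparisons of diversity between depth layers.
2. **Co-occurrence**: order-level Spearman correlation networks with the
   standard joint gate (|rho| > 0.4 and p < 0.05) after removing orders with
   mean relative abundance below 1%.
3. **Assembly processes**: the three-step phylogenetic null-model framework.
   Between-community phylogenetic turnover is measured by the abundance-
   weighted beta mean nearest taxon distance (bMNTD); its standardised
   effect size against a tip-shuffle null is the beta nearest taxon index
   (bNTI). Pairs with bNTI > +2 are assigned to heterogeneous selection and
   bNTI < -2 to homogeneous selection. Remaining pairs are split by the
   Bray-Curtis-based Raup-Crick metric (RC-bray): > +0.95 dispersal
   limitation, < -0.95 homogenizing dispersal, otherwise drift. Per-stratum
   averages of these labels estimate the relative importance of the five
   processes.
4. **Spatial vs environmental drivers**: great-circle distance matrices,
   distance-decay of similarity, Mantel tests, one-factor PERMANOVA over
   depths, stations and sections, PCNM spatial eigenfunctions, RDA, and
   variation partitioning of community variance into pure environmental,
   shared, pure spatial and unexplained fractions.

A synthetic metacommunity generator with **known assembly regimes** ties the
stages together: every statistic the package computes can be checked against
ground truth it was designed to recover.

## The null models, precisely

**bMNTD.** For samples u and v, each taxon present in u contributes its
minimum cophenetic distance to any taxon present in v; the directional mean
is weighted by relative abundance in the source sample (an unweighted flag
is available; it averages each direction over its own taxa and halves the
sum, which differs from some implementations that pool both directions over
the summed richness). bMNTD is half the sum of the two directional means.
The inner loop is a small C++ kernel because the null model re-evaluates it
hundreds of times per sample pair.

**bNTI null.** Taxon labels are shuffled across the tips of the *regional
tree* and bMNTD recomputed; bNTI is the z-score of the observed value. The
regional pool is every tip of the phylogeny handed to `bnti()`. For real
surveys the tree is built from the dataset's ASVs, so this equals the usual
"all taxa in the analysed samples" pool. For simulations the distinction
matters: taxa that exist regionally but are excluded everywhere by the same
environmental filter are precisely what makes homogeneous selection
detectable, so the simulated metacommunity tree must be supplied whole. A
pair whose two samples contain identical taxon sets has a degenerate null
(every shuffle gives the same bMNTD, because shared taxa contribute zero in
both the observed and the shuffled state); such pairs are flagged NA,
excluded from fractions and counted in the run manifest.

**RC-bray null.** Each iteration assembles one null community per sample:
the observed richness is drawn without replacement with probability
proportional to occupancy across the metacommunity, then the observed read
total is allocated multinomially with probability proportional to regional
relative abundance. Because the null community for a sample does not depend
on which partner it is compared with, one draw per sample per iteration
serves all pairs; the two members of a pair remain independent. Ties
between null and observed Bray-Curtis count half, keeping RC symmetric in
[-1, 1]. Equality is judged at 1e-12 to absorb floating-point noise in
rational Bray-Curtis values.

**Thresholds.** The quoted inequalities are strict: bNTI of exactly +/-2
falls through to the stochastic step, RC-bray of exactly +/-0.95 is drift.

## The synthetic metacommunity generator

The generator emulates a tropical western Pacific water-column survey design: 8 stations on two
latitude rows (two "sections", about 1,100 km east-west) by six depth
layers (5 m, 75 m, DCM, 200 m, 500 m, 3,000 m). Temperature decreases and
inorganic nutrients increase strictly with depth at every station;
chlorophyll a peaks at the DCM and is zero below 200 m. Station-level
jitter is bounded at 40% of the smallest adjacent-layer gap, so the
monotone gradients hold in every realisation. It is an observational-design
emulator, not an ocean model: there is no advection, no trophic coupling,
and one latent niche axis (interpretable as the temperature-depth axis)
drives all selection.

**Phylogeny.** A pure-birth backbone scaled to unit height, with one
rate-shifted terminal radiation: the internal node heights of a clade
holding ~30% of the tips are compressed by a factor 0.02. This mimics the
dense recent radiations (genus-like clusters) of real microbial
phylogenies. The radiation is not cosmetic. On a homogeneous Yule tree the
expected pendant edge is long enough that sister taxa differ in a Brownian
trait by ~0.4 trait-SD — wider than any niche breadth that still yields
realistic sample richness — so habitat filtering never produces
nearest-taxon clustering and bNTI cannot resolve homogeneous selection at
a 200-taxon pool. A pure coalescent tree fails in the opposite direction:
its clumps are so dense that shuffled taxa also land next to close
relatives and the null collapses. The single tight radiation embedded in a
Yule backbone restores the contrast the statistic needs, at the scale real
16S/18S trees actually exhibit.

**Niche traits** evolve by Brownian motion from a root value of 0
(`sigma_bm = 1` per unit tree height), so a tip's trait variance equals its
root-to-tip depth and the radiation's tips share nearly identical optima.

**Regimes.** All regimes end with a single multinomial draw of `reads` per
sample (default 16,704, matching the default rarefaction depth; the validation
scenarios use 2,000).

- *Heterogeneous selection*: per-sample expected abundance is a lognormal
  regional base (sdlog 0.3) times a Gaussian niche kernel
  `exp(-(trait - env)^2 / (2 sigma_niche^2))` with `sigma_niche = 0.13`;
  optima run linearly from the 5th to the 95th trait percentile along the
  depth ranking. Lognormal microscale noise (sdlog 0.4) and a recruitment
  lottery (each taxon independently fails to colonise a sample with
  probability 0.15) create the membership turnover real communities show.
- *Homogeneous selection*: the same machinery with one shared optimum at
  the trait-density mode — the regionally dominant ecotype, which coincides
  with the radiation — `sigma_niche = 0.15`, lottery dropout 0.5. The
  heavier lottery matters: the standardised effect size of clustering
  scales with the effective number of unshared taxa between two samples,
  so turnover among near-equivalent clade members is what pushes bNTI
  below -2.
- *Drift*: every sample descends from one realised common pool (a single
  multinomial draw of `5 * n_taxa` founders from a uniform expectation,
  which leaves the rare tail flickering in and out of samples) followed by
  5 rounds of multinomial resampling at census size 1e5 — weak sampling
  drift in a large population, so between-sample divergence stays
  commensurate with the read-sampling noise the Raup-Crick null reproduces.
- *Dispersal limitation / homogenizing dispersal*: strong independent local
  drift (100 rounds at census size = reads) makes local pools diverge far
  beyond the null; a mixing operator then couples them at rate `m` with an
  exponential kernel on station great-circle distance (d0 = the smallest
  inter-station spacing). Dispersal limitation uses m = 0.2 applied once —
  divergence survives, with mild spatial autocorrelation. Homogenizing
  dispersal uses m = 0.95 applied 10 times; iterated kernel mixing is a
  diffusion that drives all pools toward the regional mean, which is what
  "mass effects" mean mechanically.

Scenario defaults were fixed by design analysis on seeds disjoint from the
test seeds and are not adjusted per run. The regime-validation scenarios
use 200 taxa, 16 samples (4 stations by 4 generic layers) and 2,000 reads,
with 199 randomisations and 20 replicates per regime; the depth-structure
checks use the full 8 x 6 design at 100-150 taxa and 1,000-2,000 reads.
These sizes resolve the classification thresholds comfortably while keeping
a full validation run in the minutes range.

**What passing these checks does and does not show.** The generator
reproduces the statistical structure the framework assumes —
phylogenetically conserved niches, depth-structured environments, regimes
with known signatures. Real data differ in ways the generator does not
attempt: thousands of taxa, compositional sequencing artefacts, multiple
interacting environmental axes, temporal turnover, and genuinely mixed
regimes within one survey. Recovery here validates the implementation and
the framework's internal logic at survey scale, not the ecological
inferences drawn from any particular dataset.

## Statistical choices worth knowing

- **Shannon uses the natural log**, so Pielou's J is exactly H / ln S.
  Simpson is reported in the Gini-Simpson form 1 - sum(p^2).
- **Rarefaction** is a single uniform draw without replacement per sample;
  samples below the target depth are dropped with a logged warning.
- **Faith PD is rooted** (the stem to the root is included).
- **Beta diversity** is computed on rarefied counts after Hellinger
  transformation, in that order.
- **Spearman p-values** in the network stage come from the t transform of
  rho; against exhaustive permutation enumeration at n = 8 the two-sided
  values agree to within about 0.02 (the t approximation is slightly
  liberal in the tails at such small n). No multiple-testing correction is
  applied to edge p-values — the conventional gate is a raw p < 0.05 — and
  correlations are computed on relative abundances, which carries the
  usual compositional caveat.
- **Exact Wilcoxon with ties**: for combined n <= 12 the rank-sum
  distribution is enumerated over all splits with average-rank ties (the
  standard exact path refuses ties); two-sided p is twice the smaller tail,
  capped at 1.
- **Mantel tests** default to Spearman with 999 permutations, one-sided
  (greater), since decay and environmental effects are directional
  hypotheses here. An exhaustive mode enumerates all permutations for
  small n.
- **PERMANOVA** is one-factor; depth, station and section are tested
  separately. An optional `blocks` argument
  restricts permutations within the levels of a conditioning factor: when
  a balanced second factor (depth) dominates the distances, the free-label
  test of the first factor (station) is strongly conservative — every
  observed station group is depth-balanced while permuted ones are not —
  and only the within-depth restricted permutation is exact. The package's
  own calibration checks test stations this way.
- **PCNM** truncates at the longest minimum-spanning-tree edge with the
  canonical 4t replacement; the first five eigenfunctions are carried into
  the driver analyses by default.
- **Variation partitioning** uses transformation-based RDA on the
  Hellinger-transformed table with Ezekiel-adjusted R2; environmental
  variables are standardised first. Small negative adjusted fractions are
  reported as computed, flagged, never clipped. Note that this package
  labels the shared fraction [b] and pure-spatial [c]; vegan's `varpart`
  prints the pure fractions as [a] and [b] and the shared one as [c].
- **Reproducibility**: every randomised operation takes an explicit seed;
  the pipeline derives per-stage seeds from the master seed by the fixed
  rule `master * 31 + stage index (mod 2^31 - 1)`.

## Degenerate inputs

Zero-total samples are rejected at validation; all-zero sample pairs make
Bray-Curtis undefined and raise an error. Identical-membership pairs yield
NA bNTI (degenerate null) and are excluded from process fractions with a
warning. Zero-variance orders never produce network edges. Collinear
predictors are dropped from RDA with a warning, and the Ezekiel adjustment
is refused (NA) when n <= p + 1. Taxa absent from the phylogeny abort the
pipeline with a count of the offenders rather than being silently dropped.

## A short worked example

```{r example, eval = FALSE}
library(oceancomm)

cfg <- scenario_config("heterogeneous_selection", n_taxa = 150,
                       n_stations = 8, reads = 2000, seed = 1)
sim <- simulate_metacommunity(cfg)

asm <- assembly_analysis(sim$counts, sim$tree, n_null = 199, seed = 2,
                         strata = depth_strata(sim$frame))
asm$fractions

bc <- bray_curtis(hellinger(sim$counts))
permanova(bc, setNames(as.character(sim$frame$depth_layer),
                       sim$frame$sample), n_perm = 999, seed = 3)
```

## Known limitations

The generator's five regimes are pure; real surveys mix them. The
selection axis is scalar. The dispersal kernel ignores currents and
vertical structure (within-station samples mix at distance zero). RC-bray
inherits the usual sensitivity to the regional-pool definition, and at
small pool sizes (hundreds of taxa) bNTI's power for homogeneous selection
depends on fine-scale tree structure — the radiation discussion above — in
a way that disappears at real-survey pool sizes of thousands of ASVs.
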