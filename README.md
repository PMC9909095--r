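# oceancomm

Community assembly and biogeography of marine microbial metacommunities.

`oceancomm` is an R package for the analysis pattern used in open-ocean
microbial survey studies: given an ASV count table (taxa × samples, TSV), a
rooted phylogeny (Newick) and per-sample metadata (station, depth layer,
coordinates, environmental variables), it quantifies

- **α- and β-diversity** — rarefaction to even depth, Shannon–Wiener,
  Gini–Simpson, Pielou evenness, rooted Faith PD, Good's coverage,
  Hellinger transformation, Bray–Curtis dissimilarity, PCoA, and Wilcoxon
  comparisons between depth layers;
- **co-occurrence structure** — order-level Spearman networks with the
  standard joint gate (|ρ| > 0.4 and p < 0.05) after removing orders whose
  mean relative abundance is below 1%;
- **assembly processes** — the three-step phylogenetic null-model
  framework: the abundance-weighted β mean nearest taxon distance (βMNTD),
  its standardised effect size against 999 tip-shuffle randomizations
  (βNTI), and the Bray–Curtis-based Raup–Crick metric (RC_bray) for the
  pairs with |βNTI| < 2. Pairs are classified as

  | rule | process |
  |---|---|
  | βNTI > +2 | heterogeneous selection |
  | βNTI < −2 | homogeneous selection |
  | RC_bray > +0.95 | dispersal limitation |
  | RC_bray < −0.95 | homogenizing dispersal |
  | otherwise | drift |

  and per-stratum fractions of the five labels estimate the relative
  importance of each process;
- **spatial vs environmental drivers** — great-circle distances,
  distance-decay of similarity with Mantel permutation inference,
  one-factor PERMANOVA across depths / stations / sections, PCNM spatial
  eigenfunctions, RDA, and variation partitioning into pure environmental
  [a], shared [b], pure spatial [c] and unexplained [d] adjusted-R²
  fractions.

A synthetic metacommunity generator reproduces the survey design these
methods assume — 8 stations on two latitude rows × 6 depth layers (5 m,
75 m, DCM, 200 m, 500 m, 3,000 m), monotone temperature and nutrient
gradients, phylogenetically conserved niche traits on a rate-shifted
pure-birth tree — under five *known* assembly regimes, so the whole
pipeline can be validated by parameter recovery. See the methods vignette
(`vignettes/community-assembly.Rmd`) for the models, parameter defaults
and their rationale.

## Worked example

```r
library(oceancomm)

# a depth-stratified survey under heterogeneous (depth-driven) selection
cfg <- scenario_config("heterogeneous_selection", n_taxa = 150,
                       n_stations = 8, reads = 2000, seed = 1)
sim <- simulate_metacommunity(cfg)

# assembly processes, stratified into photic (5-200 m) vs deep (>500 m)
asm <- assembly_analysis(sim$counts, sim$tree, n_null = 199, seed = 8,
                         strata = depth_strata(sim$frame))
subset(asm$fractions, stratum == "all",
       select = c(heterogeneous_selection, drift, n_pairs))
#>   heterogeneous_selection      drift n_pairs
#> 1               0.6524823 0.05939716    1128

# does depth structure the communities? do stations?
bc <- bray_curtis(hellinger(sim$counts))
permanova(bc, setNames(as.character(sim$frame$depth_layer),
                       sim$frame$sample), n_perm = 999, seed = 9)$r2
#> [1] 0.9144753
```

Under depth-driven selection about 65% of sample pairs exceed βNTI = +2
(heterogeneous selection is the modal process), depth explains ~91% of the
Bray–Curtis variance, and stations explain essentially nothing — the
qualitative pattern expected for a water column whose communities track
the temperature–nutrient depth gradient.

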