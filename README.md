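# hzg — genealogical analysis of replicate hybrid zones

`hzg` is an R package for asking, with genealogies rather than allele
frequencies alone, which parts of a genome resist gene flow when two
differentiated varieties meet repeatedly in independent hybrid zones. It is
aimed at population geneticists working with four-population sampling
designs of the form *two zones × two varieties* (e.g. two valleys, each
holding a contact between a magenta- and a yellow-flowered snapdragon
variety), with phased SNPs and marginal genealogies exported from ARG
inference tools as newick tree sequences.

## What it computes

**Topology weighting.** For four populations (PlaP, PlaS, AveP, AveS) there
are three unrooted group-level quartet topologies:

- T_geo = ((AveS, AveP), (PlaS, PlaP)) — samples cluster by zone,
- T_var = ((AveS, PlaS), (AveP, PlaP)) — samples cluster by variety,
- T_alt = ((AveP, PlaS), (AveS, PlaP)) — the remaining pairing.

The weight of a topology in one marginal genealogy is the proportion of
one-haplotype-per-population quartets whose induced subtree matches it,
computed either by exact enumeration over all n₁n₂n₃n₄ combinations or by
fixed subsampling (default 10,000 quartets). For a bifurcating tree
w_geo + w_var + w_alt = 1; polytomies leave an explicit unclassified
residual u.

**Ternary asymmetry.** Each tree's weight triple is a point in the
2-simplex. Under neutral sorting of ancestral variation the two discordant
topologies are exchangeable, so the ternary density is mirror-symmetric
about the T_geo axis. The statistic D_lr = (n_right − n_left) /
(n_right + n_left), with per-bin binomial tests on a simplex lattice
(default granularity 0.02), quantifies excess weight towards T_var — the
tree-based analogue of Patterson's D.

**Genome scans.** Per-site Weir–Cockerham F_ST (haploid variance
components), windowed Hudson F_ST = 1 − π_within/d_xy as a ratio of window
sums (10-kbp windows by default), π and d_xy per callable bp, 95th/99th
percentile outlier calls, fixed T_var thresholds (strictly > 0.55,
≥ 0.60), bp-span tricube loess smoothing (span 50 kbp) and Spearman
landscape correlations.

**TMRCA contrasts.** Median pairwise TMRCA within each variety and between
varieties for every genealogy, locus-versus-flank contrasts, and
seeded-permutation Spearman correlations between T_var weight and median
TMRCA. A recent sweep predicts shallower within-variety coalescence at the
locus; a barrier predicts deeper between-variety coalescence.

**Built-in simulator.** A structured-coalescent generator of the
secondary-contact history (variety split at `T_split_var`, within-variety
zone colonisation at `T_col`, migration between varieties within each zone
since `T_sc` with asymmetric backwards rates `m12`/`m21`, locus-specific
barriers scaling migration by 1 − b, bottleneck-style sweeps,
infinite-sites mutation at μ = 5.7e-9/bp/generation) produces tree
sequences, phased VCFs, population maps and a per-window truth table, so
the entire pipeline is testable and calibratable without external data.

## Worked example

Simulate one 1-Mbp replicate with a complete barrier (b = 1) and a recent
sweep in variety *striatum* at a central 200-kbp locus, then run the
genealogical analysis:

```r
library(hzg)
cfg <- demography_config(
  n_haplotypes_per_deme = 6, N_anc = 5000, N1 = 5000, N2 = 5000,
  N_deme = 5000, T_split_var = 20000, T_col = 4000, T_sc = 2000,
  m12 = 5e-4, m21 = 5e-4, chrom_length = 1e6, window_bp = 1e4,
  barrier_loci = data.frame(start = 4e5, end = 6e5, b = 1),
  sweep_loci = data.frame(start = 4e5, end = 6e5, variety = "striatum",
                          T_sweep = 500, bottleneck_factor = 0.01),
  seed = 42)
sim <- simulate_hybrid_zones(cfg)
w   <- weight_sequence(sim$trees, sim$popmap, method = "exact")
asymmetry(w)
tm  <- tmrca_summary(sim$trees, sim$popmap, weights = w)
locus_flank_contrast(tm, 4e5, 6e5)
weight_tmrca_correlation(tm, "within_S", alternative = "less", seed = 1)
```

This prints:

```
asymmetry: n_right=61 n_left=37 (n_axis=2)
  D_lr = +0.2449 (binomial p = 0.0197)
locus_contrast: 20 locus trees vs 80 flank trees
      tmrca_within_P tmrca_within_S tmrca_between
locus          10170           4063         25440
flank          21140          20930         21850
rho(w_var, within-S TMRCA) = -0.523, permutation p = 0.0001
```

Reading the numbers: the ternary distribution leans right (D_lr > 0),
i.e. towards the variety topology, because the barrier locus keeps variety
ancestry intact while migration elsewhere erodes it. Inside the locus the
median within-*striatum* TMRCA collapses (4,063 vs 20,930 generations in
the flanks — the sweep) while the between-variety TMRCA rises (25,440 vs
21,850 — the barrier), and trees with higher T_var weights have shallower
within-*striatum* coalescence (ρ = −0.52). `run_pipeline(cfg, "out/demo")`
performs the same steps in one call and writes every table (trees, VCF,
popmap, truth, weights, scans, TMRCA, summary) as plain text.

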