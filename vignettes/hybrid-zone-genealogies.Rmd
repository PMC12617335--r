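---
title: "Genealogical analysis of replicate hybrid zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogical analysis of replicate hybrid zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzg)
```

This vignette is the package's own account of the science it implements:
the generative model behind the simulator, the statistics computed
downstream, the parameters that matter and their defaults, the numerical
conventions, and the limits of what the built-in calibration can show
about real data.

## The study design

The package targets a four-population sampling design: two *zones*
(independent geographic contacts, here labelled Pla and Ave) crossed with
two *varieties* (the differentiated taxa meeting in each zone, labelled
pseudomajus and striatum after the magenta- and yellow-flowered snapdragon
varieties that motivate the layout). Each of PlaP, PlaS, AveP, AveS
contributes a set of phased haplotypes. Two histories compete to explain
any shared variation: common ancestry along the population tree, and gene
flow since secondary contact. Barrier loci — regions where selection
reduces effective migration — and selective sweeps leave distinct,
locally restricted genealogical signatures, which is what the package is
built to detect.

## The secondary-contact generative model

`demography_config()` + `simulate_tree_sequence()` implement a
structured-coalescent model, backwards in time:

1. **Present to `T_sc`** — four demes of diploid size `N_deme`.
   Within each zone the two varieties exchange migrants: a lineage
   currently in a pseudomajus deme moves to its zone's striatum deme at
   backwards rate `m12` per generation, and vice versa at `m21`
   (asymmetric migration is allowed). Optional exponential growth
   (`growth1`, `growth2`, per-generation forward rates) makes deme size
   at backwards time t equal `N_deme * exp(-growth * t)`.
2. **`T_sc` to `T_col`** — the isolation phase: no migration.
3. **`T_col` to `T_split_var`** — the two zones of each variety merge
   into ancestral variety demes of sizes `N1` (pseudomajus) and `N2`
   (striatum): colonisation of the zones, viewed backwards.
4. **Beyond `T_split_var`** — the varieties merge into a single ancestor
   of size `N_anc`.

Within a deme of size N, each pair of lineages coalesces at rate 1/(2N)
per generation; all times are in generations. **Barrier loci** multiply
the migration rates of overlapping windows by (1 − b), b ∈ [0, 1].
**Sweeps** are approximated by a bottleneck epoch: from `T_sweep`
backwards, the affected variety's deme sizes are multiplied by
`bottleneck_factor` until its lineages have fully coalesced (or the
variety split is reached). This produces the two qualitative signatures
of interest — drastically shallower within-variety coalescence at the
locus, without modelling an explicit allele-frequency trajectory.

Mutations are dropped afterwards (`drop_mutations()`) under infinite
sites: each genealogy receives a Poisson number of mutations with mean
μ × window length × total branch length, placed on branches
proportionally to length and at unique uniform positions, each yielding
one biallelic site whose derived allele is carried by the branch's
descendants.

### Design choices in the simulator

- **Independent windows.** One marginal genealogy is drawn per window,
  with no ancestral-recombination linkage between adjacent windows. All
  downstream statistics here are per-tree; linkage between trees affects
  only the smoothness of the landscape, not the per-window
  distributions, and independence keeps the simulator exact and fast.
  This is a documented limitation: simulated landscapes lack the
  autocorrelation of real tree sequences.
- **Seeding.** A single root seed spawns one child seed per window, so
  any window's genealogy is reproducible regardless of how many windows
  are simulated or in what order.
- **Growth by exact inversion.** With exponential size change the
  coalescence waiting time is sampled by inverting the integrated rate in
  closed form, not by discretising time.
- **Degenerate epochs are legal.** `T_sc = T_col = T_split_var = 0`
  gives the panmictic limit used by the null-calibration tests;
  `T_col = T_split_var` gives a simultaneous four-way split.

### Default parameter values

Sample sizes default to 36/36/38/38 haplotypes per deme — the 18/18/19/19
diploid individuals of the motivating study design. The mutation rate
defaults to μ = 5.7 × 10⁻⁹ per bp per generation. Population sizes
default to N ≈ 395,000 diploids, the value implied by genome-wide
diversity π ≈ 0.009 via π = 4Nμ at that mutation rate; the split and
contact times (750,000 / 75,000 / 25,000 generations) and migration
rates (10⁻⁵, i.e. 4Nm ≈ 16) were fixed once at plausible coalescent
scale for a long-diverged pair of varieties with strong post-contact
flow. The fitted demographic values of any particular data set should
replace these when known; every test and example in the package passes
its own explicit, smaller configuration (e.g. N = 5,000, 10–40
haplotypes per deme, 100–2,000 windows) chosen to give clear signal at
desk scale, and those sizes are stated in the tests themselves.

One modelling question was left open by the design and decided here:
genome-fraction-wide Hill–Robertson effects are *not* emulated by
locally rescaling deme sizes; barriers act on migration only. A locus
with both reduced effective size and reduced migration can be composed
explicitly by combining a `barrier_loci` entry with a `sweep_loci`
bottleneck.

## Topology weighting

For four groups there are exactly three unrooted quartet topologies,
written here as T_geo (clustering by zone), T_var (clustering by
variety) and T_alt. The weight of a topology in a genealogy is the
fraction of one-leaf-per-population quartets whose induced subtree
matches it — `weight_tree_exact()` enumerates all n₁n₂n₃n₄
combinations, `weight_tree_sampled()` draws a fixed number (default
10,000) uniformly with replacement. Sampling *with* replacement was
chosen because it makes the estimator exactly binomial, with
SE = sqrt(w(1 − w)/n), which the calibration tests rely on; exact mode
is used by default whenever the enumeration is at most 10⁷ quartets.

Classification is unrooted and purely topological: among the six leaf
pairs of a quartet, the pair whose MRCA lies topologically deepest forms
the resolved cherry. Three or more pairs tying at the deepest level can
only arise from a polytomy and map to an UNRESOLVED outcome, kept as a
separate residual u (never redistributed), so that
w_geo + w_var + w_alt + u = 1 always and u = 0 for bifurcating trees.
Because only ancestry relations enter, the result is invariant to
re-rooting and to branch-length scale, which the property tests verify
by permutation and re-rooting.

## Ternary representation and asymmetry

Each tree's classified weights (renormalised over classified mass when
u > 0) map to the unit equilateral triangle with T_geo at the apex,
T_var bottom-right, T_alt bottom-left. `build_grid()` bins points on a
simplex lattice; the default granularity 0.02 (50 bins per edge, 2,500
subtriangles) is fine enough to resolve the corner tails analysed by the
outlier thresholds while keeping occupancy workable — the published
analyses use a comparably fine lattice, and the value is configurable.
Points falling exactly on a lattice vertex are assigned by decrementing
their largest coordinate (ties broken in geo, var, alt order); the rule
is deterministic and affects only measure-zero inputs.

Left–right asymmetry is the genealogical analogue of Patterson's D:
under neutral sorting the discordant topologies are exchangeable and the
ternary density is mirror-symmetric about the vertical axis.
`asymmetry()` reports D_lr = (n_right − n_left)/(n_right + n_left)
(points with w_var = w_alt carry no signal and are excluded), a global
exact binomial test, and per-mirrored-bin binomial tests corrected with
Benjamini–Hochberg across bin pairs — chosen as the standard FDR control
when no particular per-bin procedure is prescribed.

An important subtlety governs what "neutral" means here. Under the
secondary-contact history the deme-level population tree is itself the
*variety* topology whenever `T_col < T_split_var`, so w_var exceeds
w_alt even with perfectly symmetric migration — that asymmetry is real
signal of the split structure, not an artefact. The two discordant
topologies are exchangeable (and D_lr is a calibrated null statistic)
in the simultaneous-split case `T_col = T_split_var` and in the
panmictic limit, which is what the symmetric-null property tests use.
Conversely, within-zone migration inflates T_geo specifically, which is
why a strong barrier locus — where migration is suppressed — stands out
to the *right* of the ternary plot.

## Genome scans

- **Per-site Weir–Cockerham F_ST** uses the two-level (population /
  haplotype) variance components: phased haplotypes are haploid samples,
  so no within-individual heterozygosity term exists. With sample sizes
  n₁, n₂ and frequencies p₁, p₂: MSP = Σnᵢ(pᵢ − p̄)²,
  MSG = Σnᵢpᵢ(1 − pᵢ)/(n₁ + n₂ − 2), n_c = n − Σnᵢ²/n, and
  θ = (MSP − MSG)/(MSP + (n_c − 1)MSG). Sites monomorphic across both
  samples are undefined and are excluded (and counted) from window
  means rather than zero-filled; negative estimates are reported, not
  clamped. This haploid treatment is a deliberate, documented divergence
  from diploid genotype-based implementations.
- **π and d_xy** are mean pairwise differences per bp of callable window
  length (not per polymorphic site). Reported π carries the unbiased
  n/(n − 1) mean-pairwise correction.
- **Hudson window F_ST** is 1 − π_within/d_xy as a *ratio of window
  sums* (never an average of per-site ratios), with the *plug-in*
  within-population heterozygosity 2p(1 − p) inside the ratio so that
  the estimator's anchor points are exact: fixed differences give 1 and
  identical allele frequencies give exactly 0 for any sample size. The
  plug-in form carries a small positive O(1/n) finite-sample bias at
  panmixia, which the null tests account for by using 40 haplotypes per
  sample. Windows with fewer than `min_sites` SNPs (default 10 per
  10-kbp window) are masked.
- **Smoothing** is local linear regression with tricube weights over a
  fixed ±25-kbp genomic neighbourhood (span 50 kbp), evaluated at every
  input position with truncated neighbourhoods at the ends; a
  neighbourhood with fewer than two distinct positions degrades to a
  weighted mean. A bp-denominated span is used rather than a
  nearest-neighbour fraction because marginal trees and windows are
  irregularly spaced along the genome.
- **Outliers**: percentile calls use linear-interpolation quantiles and
  strict exceedance; the fixed variety-topology thresholds follow their
  printed semantics exactly — strictly greater than 0.55, and
  greater-or-equal at 0.60.

## TMRCA summaries

`pairwise_tmrca()` defines TMRCA(i, j) as the age of the MRCA node, with
leaf age 0 and internal ages accumulated rootward (for non-ultrametric
inputs the age of a node is its longest path to a descendant leaf).
Group medians pool all haplotypes of a variety across both zones; each
unordered pair is counted once, and even pair counts use the midpoint
convention. Summaries default to the haplotype level, since inputs are
phased haplotypes; `level = "individual"` first averages each diploid's
2 × 2 haplotype block, for comparison with individual-based pipelines.
Both conventions are explicit toggles because neither is canonical.

Locus-versus-flank contrasts assign each tree by its interval midpoint —
a tree straddling the boundary belongs to the side holding its midpoint.
The weight–TMRCA correlation uses Spearman's ρ (Pearson on mid-ranks)
with a seeded permutation p-value (default 10,000 shuffles, vectorised
over permutations), one-sided where a direction is predicted: a sweep in
variety S predicts ρ(w_var, within-S TMRCA) < 0, a barrier predicts
ρ(w_var, between TMRCA) > 0.

## Window NJ trees

The simplest genealogy-inference route is included for completeness and
comparison: non-overlapping windows of exactly 50 SNPs (trailing
remainder dropped; windows where any individual has fewer than 15
genotyped sites are flagged and skipped), raw Hamming distances between
haplotypes, and Saitou–Nei neighbour joining with negative branch
lengths clamped to zero (counted and reported). Raw mismatch counts are
used as distances because a constant per-site scaling cannot change the
NJ topology; NJ is exact on additive distances, which the tests exploit
as an oracle. Midpoint rooting is applied only for storage — downstream
quartet classification is unrooted, so the rooting is immaterial.

## Numerical and degenerate-input conventions

- Intervals are 0-based half-open throughout; VCF positions are
  converted at the boundary. SNP-to-tree assignment is by half-open
  containment, so boundary SNPs belong to the right-hand tree and totals
  are conserved exactly.
- Weight tables, tree sequences, popmaps, truth tables and configs are
  all plain TSV/key-value text and round-trip bit-exactly through the
  package readers; VCF output is v4.2 with phased diploid `a|b`
  genotypes pairing consecutive haplotypes.
- Zero-variation NJ windows, populations absent from a tree, all-axis
  ternary inputs, all-missing scans and empty locus/flank sides each
  raise informative errors (or skip-with-warning where a sequence-level
  operation should be robust to one bad window).
- Exact weighting refuses silently enormous enumerations: beyond 10⁷
  quartet combinations it falls back to sampling with a warning.

## What the built-in calibration does and does not show

The simulator emulates the features that drive the statistics: deme
structure with asymmetric post-contact migration, locus-specific
barriers, bottleneck sweeps, recombination as a sequence of independent
local trees, and infinite-sites mutation. It does not emulate linked
selection, recombination-rate heterogeneity, gene conversion,
sequencing/imputation error, phasing switch errors, or the inference
error of ARG reconstruction — real tree sequences arrive with all of
these. Passing calibration therefore shows that the statistics are
correct and well-calibrated *given* genealogies and genotypes of the
assumed form, not that any particular empirical landscape will be as
clean. The locus/flank and correlation tests run at desk scale
(hundreds of windows, ≤ 6 haplotypes per deme for enumeration speed);
power at other scales follows the usual binomial/rank-test arithmetic,
not anything specific to this implementation.
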