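Package: hzg
Title: Genealogical Analysis of Replicate Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genealogical analysis of replicate secondary-contact
    hybrid zones sampled as two population pairs (two zones crossed with two
    varieties). Implements topology weighting of marginal genealogies over
    four population groups (exact enumeration and fixed-size subsampling),
    ternary representation of the joint weight distribution with left-right
    asymmetry tests, genome scans of Weir-Cockerham and Hudson F_ST,
    nucleotide diversity and absolute divergence, neighbour-joining trees in
    fixed-SNP windows, and pairwise-TMRCA summaries contrasting candidate
    loci against their flanks. A built-in structured-coalescent simulator of
    the secondary-contact history (asymmetric migration, locus-specific
    barriers to effective migration, bottleneck-style sweeps, infinite-sites
    mutation) generates tree sequences, phased genotypes and population maps
    so every stage of the pipeline can be exercised and calibrated without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
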