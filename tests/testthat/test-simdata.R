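test_that("config validation enforces the model's invariants", {
  expect_error(quick_cfg(T_sc = 5000), "T_sc <= T_col")
  expect_error(quick_cfg(N_deme = 0), "sizes")
  expect_error(quick_cfg(m12 = -1), "migration")
  expect_error(quick_cfg(chrom_length = 95000), "tile")
  expect_error(quick_cfg(barrier_loci = data.frame(start = 0, end = 1e4,
                                                   b = 1.5)),
               "\\[0, 1\\]")
  expect_error(quick_cfg(sweep_loci = data.frame(
    start = 0, end = 1e4, variety = "striatum", T_sweep = 1e5,
    bottleneck_factor = 0.1)), "T_sweep")
})

test_that("simulation is bit-identical given the seed", {
  cfg <- quick_cfg(seed = 77L)
  s1 <- simulate_hybrid_zones(cfg)
  s2 <- simulate_hybrid_zones(cfg)
  expect_identical(lapply(s1$trees$tree, write_newick),
                   lapply(s2$trees$tree, write_newick))
  expect_identical(s1$variants$sites$pos, s2$variants$sites$pos)
  expect_identical(s1$variants$geno, s2$variants$geno)
  s3 <- simulate_hybrid_zones(quick_cfg(seed = 78L))
  expect_false(identical(lapply(s1$trees$tree, write_newick),
                         lapply(s3$trees$tree, write_newick)))
})

test_that("panmictic limit recovers the Kingman expectation E[TMRCA2]=2N", {
  ## all epoch times 0: every lineage coalesces in the single ancestor
  N <- 2000
  cfg <- quick_cfg(n_haplotypes_per_deme = 2L, N_anc = N,
                   T_split_var = 0, T_col = 0, T_sc = 0, m12 = 0, m21 = 0,
                   chrom_length = 4e6, window_bp = 1e4, seed = 5L)
  sim <- simulate_tree_sequence(cfg)
  ## mean pairwise TMRCA over independent windows vs analytic 2N
  tm <- vapply(sim$trees$tree, function(tr) {
    m <- pairwise_tmrca(tr)
    mean(m[upper.tri(m)])
  }, numeric(1))
  nwin <- length(tm)
  se <- stats::sd(tm) / sqrt(nwin)
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("with zero migration no cross-variety pair coalesces before the
           variety split", {
  cfg <- quick_cfg(m12 = 0, m21 = 0, seed = 21L)
  sim <- simulate_tree_sequence(cfg)
  pm <- sim$popmap
  P <- pm$haplotype[pm$variety == "pseudomajus"]
  S <- pm$haplotype[pm$variety == "striatum"]
  for (tr in sim$trees$tree) {
    tmat <- pairwise_tmrca(tr)
    expect_true(all(tmat[P, S] >= cfg$T_split_var - 1e-9))
  }
  ## likewise cross-zone pairs within a variety predate colonisation
  for (tr in sim$trees$tree[1:3]) {
    tmat <- pairwise_tmrca(tr)
    expect_true(all(tmat[c("PlaP_01_A", "PlaP_01_B"),
                         c("AveP_01_A", "AveP_01_B")] >=
                      cfg$T_col - 1e-9))
  }
})

test_that("mutation counts follow the Poisson branch-length expectation", {
  cfg <- quick_cfg(seed = 14L, chrom_length = 1e6, mu = 1e-6)
  sim <- simulate_tree_sequence(cfg)
  total_len <- sum(vapply(sim$trees$tree, function(tr)
    sum(tr$edge.length), numeric(1)))
  lambda <- cfg$mu * cfg$window_bp * total_len
  v <- drop_mutations(sim$trees, cfg$mu, seed = 2L, popmap = sim$popmap)
  ## observed total within 3 SE of the Poisson mean
  expect_lt(abs(nrow(v$geno) - lambda), 3 * sqrt(lambda))
  ## infinite sites: strictly increasing unique positions
  expect_true(!is.unsorted(v$sites$pos, strictly = TRUE))
  ## every site polymorphic among the sample
  counts <- rowSums(v$geno)
  expect_true(all(counts >= 1 & counts < ncol(v$geno)))
  ## determinism and the zero-length edge case
  v2 <- drop_mutations(sim$trees, cfg$mu, seed = 2L, popmap = sim$popmap)
  expect_identical(v$geno, v2$geno)
  zero <- sim$trees
  zero$tree <- lapply(zero$tree, function(tr) {
    tr$edge.length[] <- 0; tr
  })
  expect_equal(nrow(drop_mutations(zero, cfg$mu, seed = 1L)$geno), 0L)
})

test_that("derived carriers match the tree clade under each mutation", {
  cfg <- quick_cfg(seed = 31L, chrom_length = 2e4, mu = 1e-6)
  sim <- simulate_hybrid_zones(cfg)
  ## every biallelic site's carrier set must be a clade of its window tree
  for (w in 1:2) {
    tr <- sim$trees$tree[[w]]
    rows <- which(sim$variants$sites$pos >= sim$trees$start[w] &
                    sim$variants$sites$pos < sim$trees$end[w])
    clades <- c(ape::prop.part(tr))
    clade_keys <- vapply(clades, function(cl)
      paste(sort(tr$tip.label[cl]), collapse = "|"), character(1))
    tip_keys <- tr$tip.label
    for (r in rows) {
      carriers <- colnames(sim$variants$geno)[sim$variants$geno[r, ] == 1L]
      key <- paste(sort(carriers), collapse = "|")
      expect_true(key %in% c(clade_keys, tip_keys))
    }
  }
})

test_that("stronger barriers monotonically raise the variety weight", {
  means <- vapply(c(0, 0.5, 1), function(b) {
    cfg <- quick_cfg(n_haplotypes_per_deme = 4L, T_split_var = 20000,
                     T_col = 4000, T_sc = 3000, m12 = 1e-3, m21 = 1e-3,
                     chrom_length = 5e6, window_bp = 1e4,
                     barrier_loci = data.frame(start = 0, end = 5e6, b = b),
                     seed = 400L + round(10 * b))
    sim <- simulate_tree_sequence(cfg)
    w <- weight_sequence(sim$trees, sim$popmap, method = "exact")
    mean(w$w_var)
  }, numeric(1))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("a sweep epoch shortens within-variety coalescence at the locus", {
  cfg <- quick_cfg(
    n_haplotypes_per_deme = 6L, chrom_length = 1e7, window_bp = 1e4,
    T_split_var = 20000, T_col = 4000, T_sc = 2000, m12 = 2e-4, m21 = 2e-4,
    sweep_loci = data.frame(start = 0, end = 5e6, variety = "striatum",
                            T_sweep = 500, bottleneck_factor = 0.01),
    seed = 71L)
  sim <- simulate_tree_sequence(cfg)
  tm <- tmrca_summary(sim$trees, sim$popmap)
  swept <- sim$truth$sweep
  expect_equal(sum(swept), 500L)
  mw <- stats::wilcox.test(tm$tmrca_within_S[swept],
                           tm$tmrca_within_S[!swept],
                           alternative = "less")
  expect_lt(mw$p.value, 0.01)
})

test_that("under exchangeable discordance the variety and alternative
           weights are symmetric", {
  ## simultaneous four-way split with symmetric within-zone migration:
  ## VAR and ALT are mirror topologies, so their mean weights agree
  cfg <- quick_cfg(n_haplotypes_per_deme = 4L, T_split_var = 10000,
                   T_col = 10000, T_sc = 2000, m12 = 2e-4, m21 = 2e-4,
                   chrom_length = 2e7, window_bp = 1e4, seed = 57L)
  sim <- simulate_tree_sequence(cfg)
  w <- weight_sequence(sim$trees, sim$popmap, method = "exact")
  d <- w$w_var - w$w_alt
  expect_gte(length(d), 2000L)
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("simulator outputs round-trip through the readers", {
  cfg <- quick_cfg(seed = 19L)
  sim <- simulate_hybrid_zones(cfg)
  prefix <- file.path(tempdir(), "simrt")
  paths <- write_outputs(sim, prefix)
  ts <- read_tree_sequence(paths[["trees"]])
  expect_equal(vapply(ts$tree, write_newick, character(1)),
               vapply(sim$trees$tree, write_newick, character(1)))
  pm <- read_popmap(paths[["popmap"]])
  expect_equal(pm$haplotype, sim$popmap$haplotype)
  v <- read_vcf(paths[["vcf"]])
  expect_equal(unname(v$geno), unname(sim$variants$geno))
  truth <- read.table(paths[["truth"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(sim$trees))
})
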