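test_that("pairwise TMRCA matches hand computation and the path oracle", {
  tr <- parse_newick("((a:1,b:1):2,(c:2,d:2):1);")
  tm <- pairwise_tmrca(tr)
  expect_equal(tm["a", "b"], 1)
  expect_equal(tm["c", "d"], 2)
  expect_equal(tm["a", "c"], 3)
  expect_equal(max(tm), max(node_ages(tr)))  # deepest pair = root age
  expect_equal(tm, t(tm))
  expect_equal(unname(diag(tm)), rep(0, 4))
  ## random dated trees vs the ancestor-path oracle
  set.seed(14)
  for (i in 1:5) {
    rtr <- ape::rcoal(8)
    rtm <- pairwise_tmrca(rtr)
    for (pair in list(c("t1", "t2"), c("t3", "t8"), c("t5", "t6"))) {
      expect_equal(rtm[pair[1], pair[2]],
                   oracle_tmrca(rtr, pair[1], pair[2]), tolerance = 1e-9)
    }
  }
})

test_that("group medians follow the defined pair sets", {
  pm <- toy_pop_map(1L)
  ## two varieties as clades splitting at time 3
  tr <- parse_newick(paste0("((PlaP_1:1,AveP_1:1):2,",
                            "(PlaS_1:2,AveS_1:2):1);"))
  expect_equal(group_median_tmrca(tr, pm, "within_P"), 1)
  expect_equal(group_median_tmrca(tr, pm, "within_S"), 2)
  expect_equal(group_median_tmrca(tr, pm, "between"), 3)
  ## brute-force pair enumeration on a random labelled tree
  pm2 <- toy_pop_map(3L)
  set.seed(8)
  rtr <- random_pop_tree(pm2)
  tm <- pairwise_tmrca(rtr)
  P <- pm2$haplotype[pm2$variety == "pseudomajus"]
  S <- pm2$haplotype[pm2$variety == "striatum"]
  pairs_within <- utils::combn(P, 2)
  vals <- vapply(seq_len(ncol(pairs_within)), function(k)
    tm[pairs_within[1, k], pairs_within[2, k]], numeric(1))
  expect_equal(group_median_tmrca(rtr, pm2, "within_P"),
               stats::median(vals))
  cross <- as.vector(tm[P, S])
  expect_equal(group_median_tmrca(rtr, pm2, "between"),
               stats::median(cross))
  ## median convention: even pair counts use the midpoint
  expect_equal(stats::median(c(1, 3)), 2)
  ## a variety represented by a single diploid individual cannot yield an
  ## individual-level within median
  pm1 <- pop_map(c("X_A", "X_B", "PlaS_1", "AveS_1"),
                 c("PlaP", "AveP", "PlaS", "AveS"))
  tr1 <- parse_newick("((X_A:1,X_B:1):2,(PlaS_1:2,AveS_1:2):1);")
  expect_error(group_median_tmrca(tr1, pm1, "within_P",
                                  level = "individual"), "2 samples")
})

test_that("medians are invariant to haplotype order and root-edge
           rerooting on ultrametric trees", {
  pm <- toy_pop_map(3L)
  set.seed(77)
  tr <- random_pop_tree(pm)
  base <- group_median_tmrca(tr, pm, "between")
  tr2 <- ape::rotate(tr, ape::Ntip(tr) + 1L)
  expect_equal(group_median_tmrca(tr2, pm, "between"), base,
               tolerance = 1e-9)
  pm_shuffled <- pm[sample(nrow(pm)), ]
  class(pm_shuffled) <- class(pm)
  expect_equal(group_median_tmrca(tr, pm_shuffled, "between"), base)
})

test_that("reciprocally monophyletic varieties put between-median above
           within-medians", {
  cfg <- quick_cfg(m12 = 0, m21 = 0, seed = 55L)
  sim <- simulate_tree_sequence(cfg)
  tm <- tmrca_summary(sim$trees, sim$popmap)
  ## the ordering is guaranteed only for trees where the varieties are in
  ## fact reciprocally monophyletic (lineages surviving to the split can
  ## interleave in the ancestor even without migration)
  P <- sim$popmap$haplotype[sim$popmap$variety == "pseudomajus"]
  S <- sim$popmap$haplotype[sim$popmap$variety == "striatum"]
  mono <- vapply(sim$trees$tree, function(tr)
    ape::is.monophyletic(tr, P) && ape::is.monophyletic(tr, S),
    logical(1))
  expect_gt(sum(mono), 0L)
  expect_true(all(tm$tmrca_between[mono] >=
                    pmax(tm$tmrca_within_P,
                         tm$tmrca_within_S)[mono] - 1e-9))
  ## zero migration: between-variety median at least the split time, and
  ## the mean excess approximates the ancestral coalescent waiting time
  expect_true(all(tm$tmrca_between >= cfg$T_split_var))
  excess <- tm$tmrca_between - cfg$T_split_var
  ## crude envelope: expected excess is of order 2 * N_anc
  expect_lt(abs(mean(excess)) / (2 * cfg$N_anc), 3)
})

test_that("locus/flank contrast assigns trees by midpoint", {
  df <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                   end = seq(100, 1000, 100),
                   tmrca_within_P = rep(5, 10),
                   tmrca_within_S = c(rep(10, 4), rep(2, 3), rep(10, 3)),
                   tmrca_between = 1:10)
  class(df) <- c("tmrca_summary", "data.frame")
  ct <- locus_flank_contrast(df, 400, 700)
  expect_equal(nrow(ct$locus), 3L)
  expect_equal(ct$medians["locus", "tmrca_within_S"], 2)
  expect_equal(ct$medians["flank", "tmrca_within_S"], 10)
  ## all-equal input: locus equals flank
  expect_equal(ct$medians["locus", "tmrca_within_P"],
               ct$medians["flank", "tmrca_within_P"])
  ## straddling tree goes to the side holding its midpoint
  ct2 <- locus_flank_contrast(df, 350, 450)
  expect_equal(ct2$locus$start, 300)
  expect_error(locus_flank_contrast(df, 2000, 3000), "inside the locus")
})

test_that("weight-TMRCA correlation recovers signed relationships", {
  df <- data.frame(chrom = "chr1", start = seq(0, 190, 10) * 100,
                   end = seq(10, 200, 10) * 100)
  set.seed(3)
  df$w_var <- runif(20)
  df$tmrca_within_S <- 100 - 50 * df$w_var          # perfectly negative
  df$tmrca_between <- 10 + 5 * df$w_var             # perfectly positive
  df$tmrca_within_P <- runif(20)
  class(df) <- c("tmrca_summary", "data.frame")
  r1 <- weight_tmrca_correlation(df, "within_S", n_perm = 2000L,
                                 alternative = "less", seed = 4L)
  expect_equal(r1$rho, -1)
  expect_lt(r1$p_value, 0.01)
  r2 <- weight_tmrca_correlation(df, "between", n_perm = 2000L,
                                 alternative = "greater", seed = 4L)
  expect_equal(r2$rho, 1)
  expect_lt(r2$p_value, 0.01)
  ## independent inputs: p roughly uniform, rho near zero
  set.seed(10)
  ps <- replicate(30, {
    df$tmrca_within_P <- stats::rnorm(20)
    weight_tmrca_correlation(df, "within_P", n_perm = 400L,
                             seed = 6L)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_error(weight_tmrca_correlation(df[1:5, ], "between"), ">= 10")
})
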