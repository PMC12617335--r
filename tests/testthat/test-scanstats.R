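test_that("per-site Weir-Cockerham F_ST matches the variance-component
           oracle", {
  ## fixed difference
  expect_equal(wc_fst_site(rep(1L, 20), rep(0L, 20)), 1)
  ## identical intermediate frequencies: estimator is biased negative
  expect_lte(wc_fst_site(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10)), 0)
  ## arbitrary tables against the explicit ANOVA computation
  cases <- list(
    list(a1 = c(rep(1L, 2), rep(0L, 8)), a2 = c(rep(1L, 8), rep(0L, 2))),
    list(a1 = c(rep(1L, 5), rep(0L, 15)), a2 = c(rep(1L, 9), rep(0L, 3))),
    list(a1 = c(1L, 0L, 0L), a2 = rep(1L, 12)))
  for (cs in cases)
    expect_equal(wc_fst_site(cs$a1, cs$a2), oracle_wc(cs$a1, cs$a2),
                 tolerance = 1e-12)
  set.seed(88)
  for (i in 1:50) {
    a1 <- stats::rbinom(sample(4:30, 1), 1L, runif(1, 0.05, 0.95))
    a2 <- stats::rbinom(sample(4:30, 1), 1L, runif(1, 0.05, 0.95))
    if (sum(a1) + sum(a2) == 0 || all(c(a1, a2) == 1L)) next
    expect_equal(wc_fst_site(a1, a2), oracle_wc(a1, a2), tolerance = 1e-12)
  }
  ## monomorphic across both samples is undefined
  expect_true(is.na(wc_fst_site(rep(0L, 10), rep(0L, 10))))
})

test_that("window pi, dxy and Hudson F_ST behave on constructed tables", {
  pm <- toy_pop_map(2L)
  ## two populations fixed for opposite alleles at every site
  g <- cbind(matrix(0L, 5, 2), matrix(1L, 5, 2),
             matrix(0L, 5, 2), matrix(1L, 5, 2))
  colnames(g) <- pm$haplotype
  v <- variant_table("chr1", seq(0, 40, 10), g)
  L <- 50
  expect_equal(pi_window(v, pm, "PlaP", L), 0)
  expect_equal(pi_window(v, pm, "PlaS", L), 0)
  expect_equal(dxy_window(v, pm, "PlaP", "PlaS", L), 5 / L)
  expect_equal(hudson_fst_window(v, pm, "PlaP", "PlaS", L), 1)
  ## identical 50/50 frequencies in both populations: Hudson exactly 0
  g2 <- g
  g2[, ] <- 0L
  g2[, c("PlaP_1", "PlaS_1")] <- 1L   # p = 0.5 in both populations
  v2 <- variant_table("chr1", seq(0, 40, 10), g2)
  expect_equal(hudson_fst_window(v2, pm, "PlaP", "PlaS", L), 0)
  ## algebraic identity 1 - piw/dxy for the implementation's own values
  set.seed(2)
  g3 <- matrix(stats::rbinom(5 * 8, 1, 0.4), 5, 8,
               dimnames = list(NULL, pm$haplotype))
  v3 <- variant_table("chr1", seq(0, 40, 10), g3)
  piw <- (pi_window(v3, pm, "PlaP", L, unbiased = FALSE) +
            pi_window(v3, pm, "PlaS", L, unbiased = FALSE)) / 2
  dxy <- dxy_window(v3, pm, "PlaP", "PlaS", L)
  expect_equal(hudson_fst_window(v3, pm, "PlaP", "PlaS", L), 1 - piw / dxy,
               tolerance = 1e-12)
  ## the unbiased mean-pairwise pi exceeds the plug-in heterozygosity
  expect_gt(pi_window(v3, pm, "PlaP", L),
            pi_window(v3, pm, "PlaP", L, unbiased = FALSE))
})

test_that("ratio-of-averages Hudson F_ST differs from average of ratios on
           heterogeneous windows", {
  pm <- toy_pop_map(2L)
  ## one strongly differentiated site + one undifferentiated site
  g <- rbind(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
             c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L))
  colnames(g) <- pm$haplotype
  v <- variant_table("chr1", c(0, 5), g)
  L <- 10
  roa <- hudson_fst_window(v, pm, "PlaP", "PlaS", L)
  aor <- mean(c(hudson_fst_window(v, pm, "PlaP", "PlaS", L, sites = 1L),
                hudson_fst_window(v, pm, "PlaP", "PlaS", L, sites = 2L)))
  expect_false(isTRUE(all.equal(roa, aor)))
  expect_gt(roa, aor)   # the chosen convention upweights informative sites
})

test_that("panmictic simulated windows give F_ST near zero", {
  cfg <- quick_cfg(n_haplotypes_per_deme = 40L, N_anc = 10000,
                   T_split_var = 0, T_col = 0, T_sc = 0, m12 = 0, m21 = 0,
                   chrom_length = 1e6, window_bp = 1e4, mu = 5e-7,
                   seed = 12L)
  sim <- simulate_hybrid_zones(cfg)
  s <- window_scan(sim$variants, sim$popmap, "PlaP", "PlaS",
                   chrom_length = cfg$chrom_length)
  fst <- s$fst_hudson[!s$masked]
  expect_gt(length(fst), 50)
  expect_lt(abs(mean(fst, na.rm = TRUE)), 0.05)
})

test_that("window masking and undefined-site accounting", {
  pm <- toy_pop_map(2L)
  set.seed(6)
  g <- matrix(stats::rbinom(30 * 8, 1, 0.3), 30, 8,
              dimnames = list(NULL, pm$haplotype))
  v <- variant_table("chr1", sort(sample.int(20000, 30)) - 1, g)
  s <- window_scan(v, pm, "PlaP", "PlaS", window_bp = 1e4,
                   chrom_length = 3e4, min_sites = 10)
  expect_equal(nrow(s), 3L)
  expect_true(s$masked[3])          # no sites beyond 20 kb
  expect_true(all(is.na(s$fst_hudson[s$masked])))
  expect_equal(sum(s$n_sites), 30L)
})

test_that("bp-span tricube smoothing is exact on lines and matches a
           weighted-lm oracle", {
  x <- sort(sample.int(2e5, 300)) - 1
  ## constant and exactly linear series reproduced
  expect_equal(loess_smooth(x, rep(3.2, 300)), rep(3.2, 300),
               tolerance = 1e-9)
  lin <- 0.5 + 2e-4 * x
  expect_equal(loess_smooth(x, lin), lin, tolerance = 1e-9)
  ## noisy step function vs per-point weighted regression with lm()
  set.seed(10)
  y <- ifelse(x > 1e5, 1, 0) + stats::rnorm(300, 0, 0.1)
  sm <- loess_smooth(x, y, span_bp = 5e4)
  h <- 2.5e4
  ref <- vapply(seq_along(x), function(i) {
    keep <- abs(x - x[i]) <= h
    df <- data.frame(xk = x[keep], yk = y[keep])
    wt <- (1 - pmin(abs(df$xk - x[i]) / h, 1)^3)^3
    fit <- stats::lm(yk ~ xk, data = df, weights = wt)
    unname(stats::predict(fit, data.frame(xk = x[i])))
  }, numeric(1))
  expect_equal(sm, ref, tolerance = 1e-6)
})

test_that("percentile and fixed T_var outlier semantics are exact", {
  p <- percentile_outliers(1:100, 95)
  expect_equal(p$threshold, 95.05)
  expect_identical(which(p$flag), 96:100)
  w <- c(0.54, 0.55, 0.56, 0.61)
  tv <- tvar_outliers(w)
  expect_identical(w[tv$over_0.55], c(0.56, 0.61))
  expect_identical(w[tv$ge_0.60], 0.61)
  expect_true(tvar_outliers(0.60)$ge_0.60)     # >= at 0.60
  expect_false(tvar_outliers(0.55)$over_0.55)  # strict > at 0.55
  expect_error(percentile_outliers(c(NA_real_, NA_real_)), "missing")
})

test_that("spearman_rho equals the brute-force mid-rank formula", {
  expect_equal(spearman_rho(1:10, (1:10)^2), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  x <- c(1, 2, 2, 2, 3, 5, 5, 8)
  y <- c(3, 3, 1, 4, 4, 4, 2, 9)
  rx <- rank(x); ry <- rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), brute, tolerance = 1e-12)
})
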