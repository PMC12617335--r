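## Shared fixtures: small demographies, labelled random trees, and
## independent oracles kept deliberately naive (path-walking, prune-and-
## inspect, explicit ANOVA sums) so they exercise none of the package's own
## code paths.

quick_cfg <- function(...) {
  args <- list(n_haplotypes_per_deme = 4L, N_anc = 5000, N1 = 5000,
               N2 = 5000, N_deme = 5000, T_split_var = 20000, T_col = 4000,
               T_sc = 2000, m12 = 2e-4, m21 = 2e-4, chrom_length = 1e5,
               window_bp = 1e4, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(demography_config, args)
}

## pop map with n haplotypes per population, generic labels
toy_pop_map <- function(n = 2L) {
  pops <- rep(c("PlaP", "PlaS", "AveP", "AveS"), each = n)
  pop_map(paste0(pops, "_", rep(seq_len(n), times = 4L)), pops)
}

## random dated (coalescent) tree whose tips follow a pop_map
random_pop_tree <- function(pm) {
  n <- nrow(pm)
  ape::rcoal(n, tip.label = sample(pm$haplotype))
}

## --- oracle: quartet topology by pruning and clade inspection ------------
## Keeps the four leaves, then looks for a non-root clade of exactly two of
## them; the unrooted quartet is resolved iff such a cherry exists.
oracle_quartet <- function(tree, leaves) {
  tr <- ape::keep.tip(tree, leaves)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  ## any rooted 4-tip tree that is resolved as an unrooted quartet contains
  ## a clade of exactly two tips (the cherry); a star contains none
  for (cl in parts)
    if (length(cl) == 2L)
      return(pair_class(sort(match(labs[cl], leaves))))
  "UNRESOLVED"
}

## class of a population pair given indices into (PlaP, PlaS, AveP, AveS)
pair_class <- function(pair) {
  key <- paste(pair, collapse = "-")
  switch(key,
         "1-2" = "GEO", "3-4" = "GEO",
         "1-3" = "VAR", "2-4" = "VAR",
         "1-4" = "ALT", "2-3" = "ALT",
         stop("bad pair"))
}

## brute-force exact weights: prune-and-inspect every combination
oracle_weights <- function(tree, pm) {
  pops <- c("PlaP", "PlaS", "AveP", "AveS")
  leaves <- lapply(pops, function(p) pm$haplotype[pm$population == p])
  combos <- expand.grid(leaves, stringsAsFactors = FALSE)
  cls <- apply(combos, 1L, function(r) oracle_quartet(tree, unname(r)))
  c(w_geo = mean(cls == "GEO"), w_var = mean(cls == "VAR"),
    w_alt = mean(cls == "ALT"), u = mean(cls == "UNRESOLVED"))
}

## --- oracle: pairwise TMRCA by root-path intersection ---------------------
oracle_tmrca <- function(tree, a, b) {
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    out <- node
    repeat {
      r <- which(tree$edge[, 2L] == node)
      if (!length(r)) break
      node <- tree$edge[r, 1L]
      out <- c(out, node)
    }
    out
  }
  common <- intersect(path_to_root(a), path_to_root(b))
  mrca <- common[1L]   # paths are ordered tipwards -> rootwards
  ## age = longest path from mrca to any descendant leaf
  depth_below <- function(node) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (!length(kids)) return(0)
    lens <- tree$edge.length[match(kids, tree$edge[, 2L])]
    max(lens + vapply(kids, depth_below, numeric(1)))
  }
  depth_below(mrca)
}

## --- oracle: Weir-Cockerham theta from explicit ANOVA sums ---------------
oracle_wc <- function(a1, a2) {
  x <- c(a1, a2)
  g <- rep(1:2, c(length(a1), length(a2)))
  n <- tapply(x, g, length)
  p <- tapply(x, g, mean)
  pbar <- mean(x)
  r <- 2
  SSP <- sum(n * (p - pbar)^2)
  SSG <- sum(x^2) - sum(n * p^2)       # within-group sum of squares, 0/1 data
  MSP <- SSP / (r - 1)
  MSG <- SSG / (sum(n) - r)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  (MSP - MSG) / (MSP + (nc - 1) * MSG)
}
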