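## Pairwise TMRCA summaries from dated genealogies.
##
## TMRCA(i, j) is the age of the MRCA node of haplotypes i and j under the
## node-age convention of node_ages() (leaves at 0; exact node times for
## ultrametric coalescent trees). Summaries are taken at the haplotype
## level by default - inputs are phased haplotypes - with an option to
## average each diploid individual's two haplotypes before taking medians.
## Medians use the midpoint convention for even pair counts.

#' Pairwise TMRCA matrix of a dated genealogy
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix (tips x tips, dimnames = tip labels) of MRCA
#'   ages; zero diagonal.
#' @export
pairwise_tmrca <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ages <- node_ages(tree)
  m <- ape::mrca(tree)
  out <- matrix(ages[m], nrow(m), ncol(m),
                dimnames = list(tree$tip.label, tree$tip.label))
  diag(out) <- 0
  out
}

.group_haps <- function(popmap, grouping) {
  P <- popmap$haplotype[popmap$variety == "pseudomajus"]
  S <- popmap$haplotype[popmap$variety == "striatum"]
  switch(grouping,
         within_P = list(P),
         within_S = list(S),
         between = list(P, S),
         stop("grouping must be 'within_P', 'within_S' or 'between'"))
}

## collapse a haplotype TMRCA matrix to individuals (mean of the 2x2
## haplotype block), pairing consecutive haplotypes that share an id stem
.collapse_individuals <- function(tm) {
  stem <- sub("_[AB]$", "", rownames(tm))
  u <- unique(stem)
  out <- matrix(0, length(u), length(u), dimnames = list(u, u))
  idx <- split(seq_along(stem), factor(stem, levels = u))
  for (i in seq_along(u)) for (j in seq_len(i)) {
    v <- mean(tm[idx[[i]], idx[[j]], drop = FALSE])
    out[i, j] <- out[j, i] <- v
  }
  diag(out) <- 0
  out
}

#' Median pairwise TMRCA within or between varieties
#'
#' `within_P` pools all pseudomajus haplotypes from both zones (each
#' unordered pair once, no self-pairs); `within_S` likewise for striatum;
#' `between` uses all cross-variety pairs.
#'
#' @param tree a dated `phylo`.
#' @param popmap a [pop_map()].
#' @param grouping one of "within_P", "within_S", "between".
#' @param level "haplotype" (default) or "individual" (haplotype pairs
#'   averaged before the median).
#' @return median TMRCA (same time unit as the tree).
#' @export
group_median_tmrca <- function(tree, popmap,
                               grouping = c("within_P", "within_S",
                                            "between"),
                               level = c("haplotype", "individual")) {
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  tm <- pairwise_tmrca(tree)
  if (level == "individual") tm <- .collapse_individuals(tm)
  groups <- .group_haps(popmap, grouping)
  groups <- lapply(groups, function(h) {
    h <- if (level == "individual") unique(sub("_[AB]$", "", h)) else h
    i <- match(h, rownames(tm)); i[!is.na(i)]
  })
  if (length(groups) == 1L) {
    i <- groups[[1L]]
    if (length(i) < 2L) stop("within-group median needs >= 2 samples")
    stats::median(tm[i, i][upper.tri(tm[i, i])])
  } else {
    if (!length(groups[[1L]]) || !length(groups[[2L]]))
      stop("between-group median needs both groups non-empty")
    stats::median(tm[groups[[1L]], groups[[2L]]])
  }
}

#' Per-tree TMRCA summary along a tree sequence
#'
#' Computes, for every marginal genealogy, the median pairwise TMRCA
#' within variety pseudomajus, within variety striatum and between the
#' varieties, and attaches the tree's variety-topology weight when a
#' weight table is supplied.
#'
#' @param ts a [tree_sequence()] of dated trees.
#' @param popmap a [pop_map()].
#' @param weights optional `topology_weights` aligned with `ts` rows.
#' @param level see [group_median_tmrca()].
#' @return a `tmrca_summary` data.frame: chrom, start, end, tmrca_within_P,
#'   tmrca_within_S, tmrca_between and (optionally) w_var.
#' @export
tmrca_summary <- function(ts, popmap, weights = NULL,
                          level = c("haplotype", "individual")) {
  stopifnot(inherits(ts, "tree_sequence"))
  level <- match.arg(level)
  f <- function(tr, g) group_median_tmrca(tr, popmap, g, level)
  out <- data.frame(chrom = ts$chrom, start = ts$start, end = ts$end,
                    tmrca_within_P = vapply(ts$tree, f, numeric(1),
                                            g = "within_P"),
                    tmrca_within_S = vapply(ts$tree, f, numeric(1),
                                            g = "within_S"),
                    tmrca_between = vapply(ts$tree, f, numeric(1),
                                           g = "between"),
                    stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    if (nrow(weights) != nrow(out))
      stop("weights must have one row per tree")
    out$w_var <- weights$w_var
  }
  class(out) <- c("tmrca_summary", "data.frame")
  out
}

#' Locus versus flank TMRCA contrast
#'
#' Splits a region's trees into those inside a focal locus and those in
#' the flanks (region minus locus) and returns the per-grouping TMRCA
#' distributions and their medians-of-medians. Trees are assigned by
#' interval midpoint, so a tree straddling the locus boundary goes to the
#' side containing its midpoint.
#'
#' @param summaries a [tmrca_summary()].
#' @param locus_start,locus_end locus interval (0-based half-open, bp).
#' @param region_start,region_end optional region bounds; default spans
#'   all summarised trees.
#' @return a `locus_contrast` list with elements `locus` and `flank` (the
#'   subset data.frames) and `medians` (2 x 3 matrix of
#'   median-of-medians per side and grouping).
#' @export
locus_flank_contrast <- function(summaries, locus_start, locus_end,
                                 region_start = -Inf, region_end = Inf) {
  stopifnot(inherits(summaries, "tmrca_summary"))
  if (locus_start >= locus_end) stop("locus must satisfy start < end")
  mid <- (summaries$start + summaries$end) / 2
  in_region <- mid >= region_start & mid < region_end
  in_locus <- in_region & mid >= locus_start & mid < locus_end
  in_flank <- in_region & !in_locus
  if (!any(in_locus)) stop("no trees inside the locus")
  if (!any(in_flank)) stop("no trees in the flanks")
  cols <- c("tmrca_within_P", "tmrca_within_S", "tmrca_between")
  med <- rbind(locus = vapply(summaries[in_locus, cols], stats::median,
                              numeric(1), na.rm = TRUE),
               flank = vapply(summaries[in_flank, cols], stats::median,
                              numeric(1), na.rm = TRUE))
  out <- list(locus = summaries[in_locus, , drop = FALSE],
              flank = summaries[in_flank, , drop = FALSE],
              medians = med)
  class(out) <- "locus_contrast"
  out
}

#' @export
print.locus_contrast <- function(x, ...) {
  cat(sprintf("locus_contrast: %d locus trees vs %d flank trees\n",
              nrow(x$locus), nrow(x$flank)))
  print(signif(x$medians, 4))
  invisible(x)
}

#' Correlation between topology weight and median TMRCA
#'
#' Spearman rank correlation between each tree's variety-topology weight
#' and its median TMRCA for the chosen grouping, with a permutation
#' p-value (label shuffles of the TMRCA vector, seeded).
#'
#' @param summaries a [tmrca_summary()] carrying a `w_var` column.
#' @param grouping "within_P", "within_S" or "between".
#' @param n_perm number of permutations (default 10,000).
#' @param alternative "two.sided", "less" (rho < 0) or "greater".
#' @param seed integer seed for the permutations.
#' @return list with rho, p_value, n, alternative.
#' @export
weight_tmrca_correlation <- function(summaries,
                                     grouping = c("within_P", "within_S",
                                                  "between"),
                                     n_perm = 10000L,
                                     alternative = c("two.sided", "less",
                                                     "greater"),
                                     seed = 1L) {
  grouping <- match.arg(grouping)
  alternative <- match.arg(alternative)
  if (is.null(summaries$w_var))
    stop("summaries must carry a w_var column (pass weights to",
         " tmrca_summary)")
  col <- paste0("tmrca_", grouping)
  x <- summaries$w_var; y <- summaries[[col]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need >= 10 trees for the correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  set.seed(seed)
  ## correlation of mid-ranks under permutation, vectorised:
  ## rho_perm = (sum(rx * perm(ry)) - n * mx * my) / ((n - 1) sx sy)
  mx <- mean(rx); my <- mean(ry)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  perm <- replicate(n_perm, sum(rx * ry[sample.int(n)]))
  rho_perm <- (perm - n * mx * my) / ((n - 1) * sx * sy)
  p <- switch(alternative,
              less = (sum(rho_perm <= rho) + 1) / (n_perm + 1),
              greater = (sum(rho_perm >= rho) + 1) / (n_perm + 1),
              two.sided = (sum(abs(rho_perm) >= abs(rho)) + 1) /
                (n_perm + 1))
  list(rho = rho, p_value = p, n = n, alternative = alternative)
}
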