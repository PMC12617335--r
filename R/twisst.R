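## Topology weighting for four population groups.
##
## For four populations there are exactly three unrooted group-level quartet
## topologies. With the zone x variety layout these are:
##   GEO  ((AveS, AveP), (PlaS, PlaP))  - samples cluster by hybrid zone
##   VAR  ((AveS, PlaS), (AveP, PlaP))  - samples cluster by variety
##   ALT  ((AveP, PlaS), (AveS, PlaP))  - the remaining pairing
## The weight of a topology for one genealogy is the proportion of
## one-leaf-per-population subsampled quartets whose induced topology
## matches it. Polytomous induced quartets contribute to an unclassified
## residual u rather than being redistributed.
##
## Classification uses the deepest-pairwise-MRCA rule: among the six leaf
## pairs of a quartet, the pair whose MRCA is topologically deepest (most
## edges from the root) forms the resolved cherry; if three or more pairs
## tie at the deepest level the induced quartet is a star (UNRESOLVED).
## Exactly two tied pairs are necessarily the two cherries of one pairing.
## Depth ties between overlapping pairs force a shared MRCA node and drag in
## the third pair of the triple, so the two-tie case is always consistent.
## Because the rule only compares ancestry, it is invariant to re-rooting
## along the root edge and to branch lengths.

## pair order: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4) over populations
## 1=PlaP 2=PlaS 3=AveP 4=AveS
.PAIR_I <- c(1L, 1L, 1L, 2L, 2L, 3L)
.PAIR_J <- c(2L, 3L, 4L, 3L, 4L, 4L)
.PAIR_CLASS <- c("GEO", "VAR", "ALT", "ALT", "VAR", "GEO")

.group_leaves <- function(tree, popmap) {
  pops <- c("PlaP", "PlaS", "AveP", "AveS")
  idx <- lapply(pops, function(p) {
    h <- popmap$haplotype[popmap$population == p]
    i <- match(h, tree$tip.label)
    i[!is.na(i)]
  })
  names(idx) <- pops
  if (any(lengths(idx) == 0L))
    stop("population(s) with no leaf in tree: ",
         paste(pops[lengths(idx) == 0L], collapse = ", "))
  idx
}

## vectorised classification of quartet combinations.
## combos: n x 4 matrix of tip indices (one per population, columns in
## population order). Returns factor-like character vector.
.classify_combos <- function(mrca_mat, depth, combos) {
  n <- nrow(combos)
  D <- matrix(0L, n, 6L)
  for (k in 1:6) {
    ij <- cbind(combos[, .PAIR_I[k]], combos[, .PAIR_J[k]])
    D[, k] <- depth[mrca_mat[ij]]
  }
  maxd <- do.call(pmax, lapply(1:6, function(k) D[, k]))
  E <- D == maxd
  ties <- rowSums(E)
  cls <- .PAIR_CLASS[max.col(E, ties.method = "first")]
  cls[ties >= 3L] <- "UNRESOLVED"
  cls
}

#' Classify the induced quartet of four haplotypes
#'
#' Restricts the genealogy to one haplotype from each of the four
#' populations and reports which group-level topology the induced quartet
#' matches: `GEO` (clustering by zone), `VAR` (clustering by variety),
#' `ALT` (the remaining pairing), or `UNRESOLVED` when the induced quartet
#' is a star (possible only when the tree has polytomies). Classification
#' is on the unrooted quartet, so re-rooting the input does not change the
#' result.
#'
#' @param tree a `phylo`.
#' @param leaves character vector of 4 tip labels, in population order
#'   PlaP, PlaS, AveP, AveS.
#' @return one of "GEO", "VAR", "ALT", "UNRESOLVED".
#' @export
classify_quartet <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) == 4L)
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx))
    stop("leaf not in tree: ", paste(leaves[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("the four leaves must be distinct")
  .classify_combos(ape::mrca(tree), node_depths(tree),
                   matrix(idx, nrow = 1L))
}

.weights_from_classes <- function(cls, n, interval = c(NA, NA),
                                  method = "exact") {
  data.frame(chrom = NA_character_, start = interval[1], end = interval[2],
             w_geo = sum(cls == "GEO") / n,
             w_var = sum(cls == "VAR") / n,
             w_alt = sum(cls == "ALT") / n,
             u = sum(cls == "UNRESOLVED") / n,
             n_evaluated = n, method = method,
             stringsAsFactors = FALSE)
}

#' Exact topology weights of one genealogy
#'
#' Enumerates all `n1*n2*n3*n4` one-leaf-per-population quartets and counts
#' the frequency of each group topology. For a fully bifurcating tree the
#' three weights sum to exactly 1; polytomies can leave an unclassified
#' residual `u` with `w_geo + w_var + w_alt + u = 1`.
#'
#' @param tree a `phylo` containing at least one leaf of each population.
#' @param popmap a [pop_map()].
#' @param max_combinations enumeration cap; above it the function falls
#'   back to [weight_tree_sampled()] with a warning.
#' @param ... passed to [weight_tree_sampled()] on fallback.
#' @return one-row data.frame: w_geo, w_var, w_alt, u, n_evaluated, method.
#' @export
weight_tree_exact <- function(tree, popmap, max_combinations = 1e7, ...) {
  idx <- .group_leaves(tree, popmap)
  ncomb <- prod(lengths(idx))
  if (ncomb > max_combinations) {
    warning("more than ", format(max_combinations, scientific = FALSE),
            " quartet combinations; using sampled weights")
    return(weight_tree_sampled(tree, popmap, ...))
  }
  combos <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  cls <- .classify_combos(ape::mrca(tree), node_depths(tree), combos)
  .weights_from_classes(cls, ncomb, method = "exact")
}

#' Sampled topology weights of one genealogy
#'
#' Draws `n_subtrees` quartets uniformly with replacement (one leaf per
#' population, uniform within population) and reports topology frequencies.
#' The standard error of a weight w is approximately
#' `sqrt(w * (1 - w) / n_subtrees)`. Reproducible given `seed`.
#'
#' @inheritParams weight_tree_exact
#' @param n_subtrees number of subsampled quartets (default 10,000).
#' @param seed integer seed.
#' @return one-row data.frame as in [weight_tree_exact()].
#' @export
weight_tree_sampled <- function(tree, popmap, n_subtrees = 10000L,
                                seed = 1L) {
  if (n_subtrees <= 0L) stop("n_subtrees must be > 0")
  idx <- .group_leaves(tree, popmap)
  set.seed(seed)
  combos <- vapply(idx, function(v)
    v[sample.int(length(v), n_subtrees, replace = TRUE)],
    integer(n_subtrees))
  if (n_subtrees == 1L) combos <- matrix(combos, nrow = 1L)
  cls <- .classify_combos(ape::mrca(tree), node_depths(tree), combos)
  .weights_from_classes(cls, n_subtrees, method = "sampled")
}

#' Topology weights along a tree sequence
#'
#' Applies exact or fixed-subsampling weighting to every marginal tree.
#' Trees that fail (e.g., a population absent from a tree) are skipped with
#' a warning and returned as NA rows.
#'
#' @param ts a [tree_sequence()].
#' @param popmap a [pop_map()].
#' @param method "exact" or "sampled".
#' @param n_subtrees,seed sampling parameters for `method = "sampled"`
#'   (each tree uses an independent child seed derived from `seed`).
#' @param max_combinations cap for exact enumeration per tree.
#' @param strict error (naming the offenders) when popmap haplotypes occur
#'   in none of the trees; set FALSE to weight trees carrying subsets of
#'   the sample.
#' @return a `topology_weights` data.frame, one row per tree: chrom, start,
#'   end, w_geo, w_var, w_alt, u, n_evaluated, method.
#' @export
weight_sequence <- function(ts, popmap, method = c("exact", "sampled"),
                            n_subtrees = 10000L, seed = 1L,
                            max_combinations = 1e7, strict = TRUE) {
  stopifnot(inherits(ts, "tree_sequence"))
  method <- match.arg(method)
  nwin <- nrow(ts)
  if (strict && nwin > 0L) {
    tips <- unique(unlist(lapply(ts$tree, `[[`, "tip.label")))
    missing <- setdiff(popmap$haplotype, tips)
    if (length(missing))
      stop("haplotype(s) in popmap absent from trees: ",
           paste(missing, collapse = ", "))
  }
  out <- vector("list", nwin)
  if (nwin == 0L) {
    res <- .weights_from_classes(character(0), 0L)[0L, ]
    class(res) <- c("topology_weights", "data.frame")
    return(res)
  }
  set.seed(seed)
  tree_seeds <- sample.int(2147483646L, nwin)
  for (w in seq_len(nwin)) {
    row <- tryCatch({
      if (method == "exact")
        weight_tree_exact(ts$tree[[w]], popmap,
                          max_combinations = max_combinations,
                          n_subtrees = n_subtrees, seed = tree_seeds[w])
      else
        weight_tree_sampled(ts$tree[[w]], popmap, n_subtrees = n_subtrees,
                            seed = tree_seeds[w])
    }, error = function(e) {
      warning("window ", w, " skipped: ", conditionMessage(e))
      r <- .weights_from_classes("UNRESOLVED", 1L)
      r[, c("w_geo", "w_var", "w_alt", "u", "n_evaluated")] <- NA
      r
    })
    row$chrom <- ts$chrom[w]; row$start <- ts$start[w]; row$end <- ts$end[w]
    out[[w]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("topology_weights", "data.frame")
  res
}

#' Read / write topology-weight tables
#'
#' Tab-separated, columns `chrom start end w_geo w_var w_alt u n method`.
#' @param w a `topology_weights` data.frame.
#' @param path file path.
#' @export
write_weights <- function(w, path) {
  df <- as.data.frame(w)
  names(df)[names(df) == "n_evaluated"] <- "n"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "n"] <- "n_evaluated"
  class(df) <- c("topology_weights", "data.frame")
  df
}
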