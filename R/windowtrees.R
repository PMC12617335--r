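## Neighbour-joining trees in fixed-SNP windows.
##
## The simplest of the genealogy-inference routes: cut the SNP table into
## consecutive non-overlapping blocks of the same number of SNPs, build a
## pairwise Hamming distance matrix over the window's haplotypes, and run
## classic Saitou-Nei neighbour joining. Raw Hamming counts are used (a
## constant per-site scaling would not change the NJ topology). The trees
## are unrooted by construction and midpoint-rooted for storage so they
## share the rooted-newick plumbing of the rest of the package.

#' Fixed-SNP windows over a variant table
#'
#' Consecutive non-overlapping blocks of exactly `snps_per_window` SNPs;
#' the trailing remainder is dropped. The window interval is
#' `[first SNP position, last SNP position + 1)`. Windows in which any
#' individual (pair of haplotype columns sharing an id stem) has fewer
#' than `min_per_ind` fully genotyped sites are flagged; with fully
#' imputed input the flag never triggers.
#'
#' @param v a [variant_table()] (single chromosome).
#' @param snps_per_window SNPs per window (default 50).
#' @param min_per_ind minimum genotyped sites per individual (default 15).
#' @return data.frame with chrom, start, end, flagged, and a list column
#'   `sites` of row indices into `v`.
#' @export
snp_windows <- function(v, snps_per_window = 50L, min_per_ind = 15L) {
  stopifnot(inherits(v, "variant_table"))
  ns <- nrow(v$geno)
  if (ns < snps_per_window)
    stop("fewer than ", snps_per_window, " sites in the variant table")
  if (length(unique(v$sites$chrom)) != 1L)
    stop("snp_windows expects a single chromosome")
  nwin <- ns %/% snps_per_window
  idx <- lapply(seq_len(nwin), function(k)
    ((k - 1L) * snps_per_window + 1L):(k * snps_per_window))
  stem <- sub("_[AB]$", "", colnames(v$geno))
  ind <- split(seq_len(ncol(v$geno)), factor(stem, levels = unique(stem)))
  flagged <- vapply(idx, function(rows) {
    g <- v$geno[rows, , drop = FALSE]
    any(vapply(ind, function(cols)
      sum(stats::complete.cases(g[, cols, drop = FALSE])), numeric(1)) <
        min_per_ind)
  }, logical(1))
  out <- data.frame(chrom = v$sites$chrom[1L],
                    start = vapply(idx, function(r) v$sites$pos[r[1L]],
                                   numeric(1)),
                    end = vapply(idx, function(r)
                      v$sites$pos[r[length(r)]] + 1, numeric(1)),
                    flagged = flagged, stringsAsFactors = FALSE)
  out$sites <- idx
  out
}

#' Hamming distance matrix over a window's haplotypes
#'
#' @param v a [variant_table()].
#' @param sites integer row indices of the window's SNPs.
#' @return symmetric matrix of pairwise allele mismatch counts.
#' @export
hamming_distance <- function(v, sites = seq_len(nrow(v$geno))) {
  g <- v$geno[sites, , drop = FALSE]
  as.matrix(stats::dist(t(g), method = "manhattan"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei NJ (via \pkg{ape}), midpoint-rooted for storage.
#' Negative branch lengths - a known artefact of NJ on noisy distances -
#' are clamped to zero; the number clamped is recorded in the
#' `n_clamped` attribute. NJ is exact on additive distances, so the true
#' topology (and branch lengths) are recovered whenever the input metric
#' is additive.
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @return a rooted `phylo` with attribute `n_clamped`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("NJ needs at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite values in distance matrix")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  tr <- ape::nj(stats::as.dist(d))
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  ## midpoint() can leave tiny negative lengths on rerooted edges
  neg <- neg + sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "n_clamped") <- neg
  tr
}

#' Neighbour-joining tree sequence from phased genotypes
#'
#' Composition of [snp_windows()], [hamming_distance()] and [nj_tree()].
#' Flagged windows and windows with no variation among the haplotypes are
#' skipped with a warning. The result is a [tree_sequence()] directly
#' consumable by [weight_sequence()].
#'
#' @param v a [variant_table()].
#' @param popmap optional [pop_map()]; if given, haplotypes are restricted
#'   and ordered to its entries.
#' @param snps_per_window,min_per_ind see [snp_windows()].
#' @return a [tree_sequence()] with attribute `n_clamped` (total clamped
#'   negative branch lengths).
#' @export
window_nj_sequence <- function(v, popmap = NULL, snps_per_window = 50L,
                               min_per_ind = 15L) {
  if (!is.null(popmap)) {
    i <- match(popmap$haplotype, colnames(v$geno))
    if (anyNA(i))
      stop("popmap haplotype(s) missing from genotypes: ",
           paste(popmap$haplotype[is.na(i)], collapse = ", "))
    v <- variant_table(v$sites$chrom, v$sites$pos,
                       v$geno[, i, drop = FALSE],
                       ref = v$sites$ref, alt = v$sites$alt)
  }
  wins <- snp_windows(v, snps_per_window, min_per_ind)
  keep <- logical(nrow(wins))
  trees <- vector("list", nrow(wins))
  clamped <- 0L
  for (k in seq_len(nrow(wins))) {
    if (wins$flagged[k]) {
      warning("window ", k, " skipped: individual below min_per_ind")
      next
    }
    d <- hamming_distance(v, wins$sites[[k]])
    if (all(d == 0)) {
      warning("window ", k, " skipped: no variation among haplotypes")
      next
    }
    tr <- nj_tree(d)
    clamped <- clamped + attr(tr, "n_clamped")
    trees[[k]] <- tr
    keep[k] <- TRUE
  }
  if (!any(keep)) stop("no usable windows")
  out <- tree_sequence(wins$chrom[keep], wins$start[keep], wins$end[keep],
                       trees[keep])
  attr(out, "n_clamped") <- clamped
  out
}
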