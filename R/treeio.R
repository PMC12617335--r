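## Tree-sequence, population-map and VCF input/output.
##
## Internal coordinate convention: 0-based half-open intervals [start, end)
## in bp (BED-like). VCF positions are converted at the boundary (1-based).

#' Population map for four hybrid-zone populations
#'
#' Builds the haplotype-to-population assignment used throughout the package.
#' The four populations are interpreted on two crossed axes: zone (e.g., two
#' valleys holding independent hybrid zones) and variety (the two taxa that
#' meet in each zone). Topology weighting, the simulator and the TMRCA
#' summaries all require exactly these four groups.
#'
#' @param haplotype character vector of haplotype identifiers.
#' @param population character vector, same length, each one of the four
#'   population names.
#' @param pop_info data.frame with columns `population`, `zone`, `variety`
#'   (one row per population). Defaults to the PlaP/PlaS/AveP/AveS layout:
#'   zones `Pla`/`Ave`, varieties `pseudomajus` (P) / `striatum` (S).
#' @return A `pop_map` data.frame with columns haplotype, population, zone,
#'   variety.
#' @export
pop_map <- function(haplotype, population, pop_info = default_pop_info()) {
  haplotype <- as.character(haplotype)
  population <- as.character(population)
  if (length(haplotype) != length(population))
    stop("haplotype and population must have the same length")
  if (anyDuplicated(haplotype))
    stop("duplicated haplotype ids: ",
         paste(unique(haplotype[duplicated(haplotype)]), collapse = ", "))
  bad <- setdiff(population, pop_info$population)
  if (length(bad))
    stop("unknown population(s): ", paste(bad, collapse = ", "))
  if (nrow(pop_info) != 4L)
    stop("exactly four populations are required")
  if (!all(pop_info$population %in% population))
    stop("every population must be non-empty; missing: ",
         paste(setdiff(pop_info$population, population), collapse = ", "))
  i <- match(population, pop_info$population)
  out <- data.frame(haplotype = haplotype,
                    population = population,
                    zone = pop_info$zone[i],
                    variety = pop_info$variety[i],
                    stringsAsFactors = FALSE)
  class(out) <- c("pop_map", "data.frame")
  out
}

#' @rdname pop_map
#' @export
default_pop_info <- function() {
  data.frame(population = c("PlaP", "PlaS", "AveP", "AveS"),
             zone = c("Pla", "Pla", "Ave", "Ave"),
             variety = c("pseudomajus", "striatum",
                         "pseudomajus", "striatum"),
             stringsAsFactors = FALSE)
}

#' @rdname pop_map
#' @param path file path of a tab-separated table with columns
#'   `haplotype  population  zone  variety`.
#' @export
read_popmap <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("haplotype", "population", "zone", "variety")
  if (!all(need %in% names(x)))
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  info <- unique(x[, c("population", "zone", "variety")])
  pop_map(x$haplotype, x$population, pop_info = info)
}

#' @rdname pop_map
#' @param pm a `pop_map`.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(as.data.frame(pm)[, c("haplotype", "population",
                                           "zone", "variety")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- newick --

#' Parse and serialise newick trees
#'
#' Thin wrappers around \pkg{ape} that add the validation this package
#' relies on: unique leaf labels, well-formed text, and (for
#' `parse_newick`) rejection of unparseable input with a clear error.
#' Polytomies are permitted. Unlabelled internal nodes are accepted and
#' internal labels are ignored.
#'
#' @param text a single newick string (terminating `;` optional).
#' @return `parse_newick`: an object of class `phylo`; `write_newick`: a
#'   newick string.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  ## cheap structural check: ape can silently mis-parse unbalanced input
  op <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  cl <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (op != cl) stop("unbalanced parentheses in newick string")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in newick string: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

## ------------------------------------------------------------- node ages --

#' Node ages and root-distance depths of a tree
#'
#' `node_ages` returns the age of every node (tips and internal), defining
#' leaf age as 0 and the age of an internal node as the maximum path length
#' to any descendant leaf. For ultrametric (dated) trees this is the usual
#' node time; non-ultrametric trees are accepted and pairwise TMRCA then
#' uses the MRCA node's age under this convention. `node_depths` returns the
#' topological depth (edge count from the root), used for quartet
#' classification where branch lengths are irrelevant.
#'
#' @param tree a `phylo` with branch lengths (for `node_ages`).
#' @return numeric vector indexed by ape node number (1..Ntip tips, then
#'   internal nodes).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; node ages undefined")
  n <- ape::Ntip(tree)
  ages <- numeric(n + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge
  len <- ord$edge.length
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    a <- ages[ch] + len[k]
    if (a > ages[p]) ages[p] <- a
  }
  ages
}

#' @rdname node_ages
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  depth <- integer(n + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")
  e <- ord$edge
  for (k in seq_len(nrow(e)))
    depth[e[k, 2L]] <- depth[e[k, 1L]] + 1L
  depth
}

## ---------------------------------------------------------- tree sequence --

#' Tree sequence: ordered genealogies tiling a chromosome
#'
#' A tree sequence is a set of marginal genealogies, each valid over a
#' half-open genomic interval, sorted and non-overlapping. Gaps between
#' consecutive intervals are permitted (flagged in the `gap_before` column).
#'
#' @param chrom chromosome id (recycled).
#' @param start,end integer vectors, 0-based half-open intervals in bp.
#' @param trees list of `phylo` objects, one per interval.
#' @return a `tree_sequence`: data.frame with columns chrom, start, end,
#'   gap_before and a list column `tree`.
#' @export
tree_sequence <- function(chrom, start, end, trees) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (length(end) != n || length(trees) != n)
    stop("start, end and trees must have equal length")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  chrom <- rep_len(as.character(chrom), n)
  o <- order(chrom, start)
  start <- start[o]; end <- end[o]; trees <- trees[o]; chrom <- chrom[o]
  same <- which(chrom[-1] == chrom[-n])
  if (n > 1L && any(start[same + 1L] < end[same]))
    stop("overlapping intervals in tree sequence")
  gap <- c(FALSE, chrom[-1] == chrom[-n] & start[-1] > end[-n])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    gap_before = gap, stringsAsFactors = FALSE)
  out$tree <- trees
  class(out) <- c("tree_sequence", "data.frame")
  out
}

#' Read / write a tree-sequence table
#'
#' Plain-text format, one marginal tree per line:
#' `chrom <TAB> start <TAB> end <TAB> newick`, with 0-based half-open
#' intervals. This is the exchange format for trees exported from ARG
#' inference tools (after conversion to newick) as well as for the
#' package's own simulator and NJ-window inference.
#'
#' @param path file path.
#' @return `read_tree_sequence`: a [tree_sequence()].
#' @export
read_tree_sequence <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character"))
  need <- c("chrom", "start", "end", "newick")
  if (!all(need %in% names(x)))
    stop("tree-sequence table must have columns: ",
         paste(need, collapse = ", "))
  trees <- lapply(x$newick, parse_newick)
  tree_sequence(x$chrom, x$start, x$end, trees)
}

#' @rdname read_tree_sequence
#' @param ts a `tree_sequence`.
#' @export
write_tree_sequence <- function(ts, path) {
  stopifnot(inherits(ts, "tree_sequence"))
  df <- data.frame(chrom = ts$chrom, start = ts$start, end = ts$end,
                   newick = vapply(ts$tree, write_newick, character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- variants --

#' Variant table: phased biallelic genotypes
#'
#' Holds per-site metadata and the haplotype allele matrix (0 = ancestral /
#' reference, 1 = derived / alternate). Positions are stored 0-based.
#'
#' @param chrom chromosome id (recycled).
#' @param pos numeric vector of 0-based positions, strictly increasing.
#' @param geno integer matrix, sites x haplotypes, entries in {0, 1} (NA
#'   allowed for missing genotypes); column names are haplotype ids.
#' @param ref,alt ancestral and derived allele (recycled single bases).
#' @return a `variant_table` (list with elements `sites` and `geno`).
#' @export
variant_table <- function(chrom, pos, geno, ref = "A", alt = "T") {
  pos <- as.numeric(pos)
  geno <- as.matrix(geno)
  if (length(pos) != nrow(geno))
    stop("length(pos) must equal nrow(geno)")
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be strictly increasing and unique")
  if (is.null(colnames(geno)))
    stop("geno must have haplotype ids as column names")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("genotypes must be 0/1 (biallelic)")
  sites <- data.frame(chrom = rep_len(as.character(chrom), length(pos)),
                      pos = pos,
                      ref = rep_len(as.character(ref), length(pos)),
                      alt = rep_len(as.character(alt), length(pos)),
                      stringsAsFactors = FALSE)
  out <- list(sites = sites, geno = geno)
  class(out) <- "variant_table"
  out
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d haplotypes\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

n_sites <- function(v) nrow(v$geno)

#' Write phased genotypes as VCF v4.2
#'
#' Haplotypes are paired consecutively into diploid sample columns with
#' phased `a|b` genotypes. When two consecutive haplotype ids share a common
#' stem and differ only by a trailing `_A`/`_B`, that stem becomes the
#' sample name (so the reader recovers the original haplotype ids exactly).
#'
#' @param v a [variant_table()] with an even number of haplotype columns.
#' @param path output file path (plain text).
#' @param contig_length optional contig length for the header.
#' @export
write_vcf <- function(v, path, contig_length = NULL) {
  stopifnot(inherits(v, "variant_table"))
  nh <- ncol(v$geno)
  if (nh %% 2L != 0L)
    stop("write_vcf needs an even number of haplotypes (diploid pairing)")
  haps <- colnames(v$geno)
  i1 <- seq(1L, nh, by = 2L); i2 <- i1 + 1L
  stem1 <- sub("_A$", "", haps[i1]); stem2 <- sub("_B$", "", haps[i2])
  samples <- ifelse(stem1 == stem2 & stem1 != haps[i1], stem1,
                    paste0("ind", seq_along(i1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=hzg", con)
  chrom <- unique(v$sites$chrom)
  for (ch in chrom) {
    len <- if (is.null(contig_length))
      max(v$sites$pos[v$sites$chrom == ch]) + 1 else contig_length
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)),
               con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  g <- v$geno
  gt <- matrix(paste(g[, i1, drop = FALSE], g[, i2, drop = FALSE],
                     sep = "|"),
               nrow = nrow(g))
  gt[is.na(g[, i1, drop = FALSE]) | is.na(g[, i2, drop = FALSE])] <- ".|."
  lines <- paste(v$sites$chrom, format(v$sites$pos + 1, scientific = FALSE,
                                       trim = TRUE),
                 ".", v$sites$ref, v$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF of phased biallelic genotypes
#'
#' Parses with \pkg{vcfR} and splits each phased diploid genotype into two
#' haplotype columns named `<sample>_A` and `<sample>_B`. Positions are
#' converted to the package's 0-based convention. Multiallelic or unphased
#' records are rejected.
#'
#' @param path VCF file path.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multiallelic sites are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("unphased genotypes ('/') are not supported; phase the VCF first")
  samples <- colnames(gt)
  nsite <- nrow(gt)
  a <- sub("\\|.*$", "", gt)
  b <- sub("^.*\\|", "", gt)
  conv <- function(m) {
    m[m == "."] <- NA_character_
    storage.mode(m) <- "integer"
    m
  }
  geno <- matrix(NA_integer_, nrow = nsite, ncol = 2L * length(samples))
  geno[, seq(1L, ncol(geno), by = 2L)] <- conv(a)
  geno[, seq(2L, ncol(geno), by = 2L)] <- conv(b)
  colnames(geno) <- as.vector(rbind(paste0(samples, "_A"),
                                    paste0(samples, "_B")))
  variant_table(chrom = fix[, "CHROM"],
                pos = as.numeric(fix[, "POS"]) - 1,
                geno = geno, ref = fix[, "REF"], alt = fix[, "ALT"])
}

## ----------------------------------------------------------------- summary --

#' Tree-sequence summary statistics
#'
#' Summarises a tree sequence the way method-comparison tables report them:
#' number of marginal trees, mean and SD of tree span in bp, mean and SD of
#' the number of SNPs falling in each tree's interval, and the fraction of
#' trees with no SNP. Each SNP is assigned to the unique tree whose
#' half-open interval contains its position; SNPs outside every interval are
#' counted in `n_unassigned` so that totals are conserved exactly.
#'
#' @param ts a [tree_sequence()].
#' @param variants optional [variant_table()] on the same chromosome(s).
#' @return list with n_trees, mean_span_bp, sd_span_bp, mean_snps_per_tree,
#'   sd_snps_per_tree, fraction_trees_without_snps, n_unassigned, and the
#'   per-tree count vector `snps_per_tree`.
#' @export
tree_sequence_summary <- function(ts, variants = NULL) {
  stopifnot(inherits(ts, "tree_sequence"))
  span <- ts$end - ts$start
  counts <- integer(nrow(ts))
  unassigned <- 0L
  if (!is.null(variants) && n_sites(variants) > 0L) {
    for (ch in unique(variants$sites$chrom)) {
      sel <- ts$chrom == ch
      pos <- variants$sites$pos[variants$sites$chrom == ch]
      if (!any(sel)) { unassigned <- unassigned + length(pos); next }
      st <- ts$start[sel]; en <- ts$end[sel]
      idx <- findInterval(pos, st)
      ok <- idx >= 1L & pos < en[pmax(idx, 1L)]
      unassigned <- unassigned + sum(!ok)
      tab <- tabulate(idx[ok], nbins = sum(sel))
      counts[sel] <- counts[sel] + tab
    }
  }
  list(n_trees = nrow(ts),
       mean_span_bp = mean(span),
       sd_span_bp = stats::sd(span),
       mean_snps_per_tree = mean(counts),
       sd_snps_per_tree = stats::sd(counts),
       fraction_trees_without_snps = mean(counts == 0L),
       n_unassigned = unassigned,
       snps_per_tree = counts)
}
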