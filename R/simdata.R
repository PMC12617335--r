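## Structured-coalescent simulator of replicate secondary-contact hybrid
## zones.
##
## Four demes (PlaP, PlaS, AveP, AveS) are related by a variety split at
## T_split_var generations ago, within-variety zone colonisation at T_col,
## and secondary contact since T_sc during which the two varieties exchange
## migrants within each zone at (possibly asymmetric) backwards rates m12
## (pseudomajus -> striatum) and m21. Locus-specific barriers scale those
## rates by (1 - b); sweeps are approximated by a bottleneck epoch in the
## affected variety. One independent marginal genealogy is drawn per genomic
## window; time is in generations and the pairwise coalescence rate within a
## deme of diploid size N is 1/(2N).

#' Demographic configuration for the hybrid-zone simulator
#'
#' All parameters of the secondary-contact (SC) generative model. Time flows
#' backwards from the present: migration between varieties within each zone
#' operates during `[0, T_sc)`; the two zones of each variety merge into a
#' single ancestral variety deme at `T_col` (sizes `N1` for pseudomajus,
#' `N2` for striatum); the varieties merge into the ancestor of size
#' `N_anc` at `T_split_var`.
#'
#' Defaults mirror the sampled study design (36/36/38/38 haplotypes per
#' deme, i.e. 18/18/19/19 diploids) and a mutation rate of 5.7e-9 per bp per
#' generation. The population size default is derived from genome-wide
#' diversity pi = 0.009 via pi = 4*N*mu; split and contact times default to
#' plausible coalescent scale relative to that size (see the methods
#' vignette). Tests and examples typically pass much smaller, explicit
#' configurations.
#'
#' @param n_haplotypes_per_deme scalar or length-4 vector (order PlaP, PlaS,
#'   AveP, AveS) of haplotype counts per deme.
#' @param N_anc,N1,N2,N_deme diploid effective sizes: ancestor, ancestral
#'   pseudomajus, ancestral striatum, and each present-day deme.
#' @param T_split_var,T_col,T_sc epoch boundaries in generations,
#'   `0 <= T_sc <= T_col <= T_split_var` (equalities give degenerate
#'   histories, e.g. all zero is the panmictic limit).
#' @param m12,m21 backwards per-lineage per-generation migration
#'   probabilities within a zone: pseudomajus -> striatum (`m12`) and
#'   striatum -> pseudomajus (`m21`).
#' @param growth1,growth2 exponential growth rates (per generation, forward
#'   in time) of the pseudomajus and striatum demes since `T_sc`; deme size
#'   at time `t < T_sc` in the past is `N_deme * exp(-growth * t)`.
#' @param barrier_loci data.frame with columns `start`, `end`, `b`;
#'   migration in windows overlapping `[start, end)` is multiplied by
#'   `(1 - b)`, `b` in `[0, 1]`.
#' @param sweep_loci data.frame with columns `start`, `end`, `variety`
#'   ("pseudomajus" or "striatum"), `T_sweep`, `bottleneck_factor`; in
#'   overlapping windows the affected variety's deme sizes are multiplied by
#'   `bottleneck_factor` from `T_sweep` backwards until its lineages have
#'   fully coalesced or `T_split_var` is reached.
#' @param chrom_length,window_bp chromosome length and marginal-tree window
#'   size in bp; windows must tile `[0, chrom_length)` exactly.
#' @param mu per-bp per-generation mutation rate (infinite sites).
#' @param chrom chromosome id used in all outputs.
#' @param seed integer root seed; each window gets an independent child
#'   seed so per-window results do not depend on window order.
#' @return a validated `demography_config` list.
#' @export
demography_config <- function(n_haplotypes_per_deme = c(36L, 36L, 38L, 38L),
                              N_anc = 395000, N1 = 395000, N2 = 395000,
                              N_deme = 395000,
                              T_split_var = 750000, T_col = 75000,
                              T_sc = 25000,
                              m12 = 1e-5, m21 = 1e-5,
                              growth1 = 0, growth2 = 0,
                              barrier_loci = NULL, sweep_loci = NULL,
                              chrom_length = 1e6, window_bp = 1e4,
                              mu = 5.7e-9, chrom = "chr1", seed = 1L) {
  n <- as.integer(rep_len(n_haplotypes_per_deme, 4L))
  if (any(n < 1L)) stop("each deme needs at least one haplotype")
  if (any(c(N_anc, N1, N2, N_deme) <= 0)) stop("population sizes must be > 0")
  if (!(T_sc >= 0 && T_sc <= T_col && T_col <= T_split_var))
    stop("epoch times must satisfy 0 <= T_sc <= T_col <= T_split_var")
  if (m12 < 0 || m21 < 0) stop("migration rates must be >= 0")
  if (mu < 0) stop("mu must be >= 0")
  if (chrom_length <= 0 || window_bp <= 0 ||
      chrom_length %% window_bp != 0)
    stop("windows of window_bp must tile [0, chrom_length) exactly")
  if (!is.null(barrier_loci)) {
    barrier_loci <- as.data.frame(barrier_loci)
    stopifnot(all(c("start", "end", "b") %in% names(barrier_loci)))
    if (any(barrier_loci$b < 0 | barrier_loci$b > 1))
      stop("barrier strength b must lie in [0, 1]")
    if (any(barrier_loci$start >= barrier_loci$end))
      stop("barrier intervals must satisfy start < end")
  }
  if (!is.null(sweep_loci)) {
    sweep_loci <- as.data.frame(sweep_loci)
    stopifnot(all(c("start", "end", "variety", "T_sweep",
                    "bottleneck_factor") %in% names(sweep_loci)))
    if (!all(sweep_loci$variety %in% c("pseudomajus", "striatum")))
      stop("sweep variety must be 'pseudomajus' or 'striatum'")
    if (any(sweep_loci$bottleneck_factor <= 0))
      stop("bottleneck_factor must be > 0")
    if (any(sweep_loci$T_sweep < 0 | sweep_loci$T_sweep >= T_split_var))
      stop("T_sweep must lie in [0, T_split_var)")
  }
  cfg <- list(n_haplotypes_per_deme = n, N_anc = N_anc, N1 = N1, N2 = N2,
              N_deme = N_deme, T_split_var = T_split_var, T_col = T_col,
              T_sc = T_sc, m12 = m12, m21 = m21,
              growth1 = growth1, growth2 = growth2,
              barrier_loci = barrier_loci, sweep_loci = sweep_loci,
              chrom_length = chrom_length, window_bp = window_bp,
              mu = mu, chrom = as.character(chrom), seed = as.integer(seed))
  class(cfg) <- "demography_config"
  cfg
}

## deme layout: 1 PlaP, 2 PlaS, 3 AveP, 4 AveS; merged: 5 P-ancestor,
## 6 S-ancestor, 7 common ancestor
.DEME_POPS <- c("PlaP", "PlaS", "AveP", "AveS")
.DEME_VARIETY <- c("pseudomajus", "striatum", "pseudomajus", "striatum",
                   "pseudomajus", "striatum", NA)

#' @export
print.demography_config <- function(x, ...) {
  cat("demography_config: 4 demes,",
      sprintf("%d windows of %g bp\n",
              as.integer(x$chrom_length / x$window_bp), x$window_bp))
  cat(sprintf("  T_sc=%g  T_col=%g  T_split_var=%g generations\n",
              x$T_sc, x$T_col, x$T_split_var))
  cat(sprintf("  N_deme=%g N1=%g N2=%g N_anc=%g  m12=%g m21=%g  mu=%g\n",
              x$N_deme, x$N1, x$N2, x$N_anc, x$m12, x$m21, x$mu))
  invisible(x)
}

#' Population map implied by a demography configuration
#' @param cfg a [demography_config()].
#' @return a [pop_map()] with haplotype ids `<pop>_<ind>_<A|B>`.
#' @export
sim_pop_map <- function(cfg) {
  haps <- character(0); pops <- character(0)
  for (d in 1:4) {
    n <- cfg$n_haplotypes_per_deme[d]
    ind <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
    ab <- rep(c("A", "B"), length.out = n)
    haps <- c(haps, sprintf("%s_%02d_%s", .DEME_POPS[d], ind, ab))
    pops <- c(pops, rep(.DEME_POPS[d], n))
  }
  pop_map(haps, pops)
}

## waiting time to the next coalescence in a deme whose size follows
## N(t) = N_ref * exp(-g t) on absolute (backwards) time; t0 = current time
.coal_wait <- function(k, N_ref, g, t0) {
  if (k < 2L) return(Inf)
  C <- k * (k - 1) / 2
  E <- stats::rexp(1L)
  if (g == 0) return(E * 2 * N_ref / C)
  arg <- exp(g * t0) + 2 * N_ref * g * E / C
  if (arg <= 0) return(Inf)
  log(arg) / g - t0
}

## simulate one marginal genealogy; returns a dated phylo whose tip labels
## follow popmap order
.sim_window <- function(cfg, popmap, mig_factor = 1, sweeps = NULL) {
  nvec <- cfg$n_haplotypes_per_deme
  ntip <- sum(nvec)
  labels <- popmap$haplotype
  deme_of_tip <- rep(1:4, times = nvec)

  time <- numeric(2L * ntip - 1L)
  parent <- integer(2L * ntip - 1L)
  act <- seq_len(ntip)            # active node ids
  deme <- deme_of_tip             # deme of each active lineage
  nxt <- ntip + 1L                # next internal node id
  t <- 0

  Tsc <- cfg$T_sc; Tcol <- cfg$T_col; Tsplit <- cfg$T_split_var
  gvar <- c(cfg$growth1, cfg$growth2)   # growth by variety index 1=P, 2=S
  has_sweep <- !is.null(sweeps) && nrow(sweeps) > 0L

  ## migration target and rate by source deme (phase A only)
  mig_to <- c(2L, 1L, 4L, 3L)
  mig_rate0 <- c(cfg$m12, cfg$m21, cfg$m12, cfg$m21) * mig_factor

  repeat {
    if (length(act) == 1L) break

    ## apply structural merges for boundaries already reached
    if (t >= Tcol && t < Tsplit) {
      deme[deme == 1L | deme == 3L] <- 5L
      deme[deme == 2L | deme == 4L] <- 6L
    }
    if (t >= Tsplit) deme[] <- 7L

    ## next structural boundary
    bounds <- c(Tsc, Tcol, Tsplit)
    if (has_sweep) bounds <- c(bounds, sweeps$T_sweep)
    bounds <- bounds[bounds > t]
    t_end <- if (length(bounds)) min(bounds) else Inf

    ## per-deme sizes at the current epoch (constant or exponential)
    demes_here <- sort(unique(deme))
    size_ref <- numeric(length(demes_here))
    growth <- numeric(length(demes_here))
    for (j in seq_along(demes_here)) {
      d <- demes_here[j]
      if (d <= 4L) {
        g <- gvar[if (d %in% c(1L, 3L)) 1L else 2L]
        if (t < Tsc) { size_ref[j] <- cfg$N_deme; growth[j] <- g }
        else size_ref[j] <- cfg$N_deme * exp(-g * Tsc)
      } else if (d == 5L) size_ref[j] <- cfg$N1
      else if (d == 6L) size_ref[j] <- cfg$N2
      else size_ref[j] <- cfg$N_anc
    }
    ## active sweeps multiply the affected variety's sizes
    if (has_sweep && t < Tsplit) {
      for (s in seq_len(nrow(sweeps))) {
        if (t < sweeps$T_sweep[s]) next
        v <- if (sweeps$variety[s] == "pseudomajus") 1L else 2L
        vdemes <- if (v == 1L) c(1L, 3L, 5L) else c(2L, 4L, 6L)
        if (sum(deme %in% vdemes) > 1L) {
          j <- which(demes_here %in% vdemes)
          size_ref[j] <- size_ref[j] * sweeps$bottleneck_factor[s]
        }
      }
    }

    ## candidate event times (competing exponentials; coalescence may be
    ## time-inhomogeneous under growth)
    w_best <- Inf; ev <- NULL
    for (j in seq_along(demes_here)) {
      d <- demes_here[j]
      k <- sum(deme == d)
      w <- .coal_wait(k, size_ref[j], growth[j], t)
      if (w < w_best) { w_best <- w; ev <- list(type = "coal", deme = d) }
      if (t < Tsc && d <= 4L && mig_rate0[d] > 0 && k > 0L) {
        wm <- stats::rexp(1L) / (k * mig_rate0[d])
        if (wm < w_best) { w_best <- wm; ev <- list(type = "mig", deme = d) }
      }
    }

    if (t + w_best >= t_end) { t <- t_end; next }
    t <- t + w_best

    members <- which(deme == ev$deme)
    if (ev$type == "coal") {
      pick <- members[sample.int(length(members), 2L)]
      node <- nxt; nxt <- nxt + 1L
      time[node] <- t
      parent[act[pick]] <- node
      act <- c(act[-pick], node)
      deme <- c(deme[-pick], ev$deme)
    } else {
      pick <- members[sample.int(length(members), 1L)]
      deme[pick] <- mig_to[ev$deme]
    }
  }

  ## renumber internal nodes so the root (oldest, created last) is ntip+1
  n_internal <- nxt - 1L - ntip
  remap <- function(v) as.integer(ifelse(v > ntip, ntip + nxt - v, v))
  nodes <- seq_len(nxt - 1L)
  nonroot <- nodes[nodes != nxt - 1L]
  edge <- cbind(remap(parent[nonroot]), remap(nonroot))
  storage.mode(edge) <- "integer"
  edge.length <- time[parent[nonroot]] - time[nonroot]
  tr <- list(edge = edge, edge.length = edge.length,
             tip.label = labels, Nnode = n_internal)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a tree sequence under the secondary-contact model
#'
#' Draws one independent structured-coalescent genealogy per genomic window
#' (no linkage between windows; the downstream statistics are per tree).
#' Windows overlapping a barrier locus have their migration rates multiplied
#' by `(1 - b)`; windows overlapping a sweep locus experience the bottleneck
#' epoch in the affected variety. Deterministic given `cfg$seed`: each
#' window uses its own child seed, so results are reproducible independent
#' of window order.
#'
#' @param cfg a [demography_config()].
#' @return an `hz_sim` list: `trees` (a [tree_sequence()] with node times in
#'   generations), `truth` (per-window data.frame: barrier flag, sweep flag,
#'   realised migration factor), `popmap`, `config`, and `variants` (NULL
#'   until [drop_mutations()] is applied).
#' @export
simulate_tree_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "demography_config"))
  popmap <- sim_pop_map(cfg)
  nwin <- as.integer(cfg$chrom_length / cfg$window_bp)
  starts <- (seq_len(nwin) - 1L) * cfg$window_bp
  ends <- starts + cfg$window_bp

  set.seed(cfg$seed)
  win_seeds <- sample.int(2147483646L, nwin)

  overlaps <- function(tab, ws, we) {
    if (is.null(tab) || nrow(tab) == 0L) return(integer(0))
    which(tab$start < we & tab$end > ws)
  }

  trees <- vector("list", nwin)
  mig_fac <- numeric(nwin); barrier <- logical(nwin); swept <- logical(nwin)
  for (w in seq_len(nwin)) {
    ib <- overlaps(cfg$barrier_loci, starts[w], ends[w])
    f <- if (length(ib)) prod(1 - cfg$barrier_loci$b[ib]) else 1
    is_ <- overlaps(cfg$sweep_loci, starts[w], ends[w])
    sw <- if (length(is_)) cfg$sweep_loci[is_, , drop = FALSE] else NULL
    set.seed(win_seeds[w])
    trees[[w]] <- .sim_window(cfg, popmap, mig_factor = f, sweeps = sw)
    mig_fac[w] <- f; barrier[w] <- f < 1; swept[w] <- length(is_) > 0L
  }

  out <- list(trees = tree_sequence(cfg$chrom, starts, ends, trees),
              truth = data.frame(chrom = cfg$chrom, start = starts,
                                 end = ends, barrier = barrier,
                                 sweep = swept, mig_factor = mig_fac,
                                 stringsAsFactors = FALSE),
              popmap = popmap, config = cfg, variants = NULL)
  class(out) <- "hz_sim"
  out
}

#' @export
print.hz_sim <- function(x, ...) {
  cat(sprintf("hz_sim: %d windows x %d haplotypes%s\n", nrow(x$trees),
              nrow(x$popmap),
              if (is.null(x$variants)) "" else
                sprintf(", %d variant sites", nrow(x$variants$geno))))
  invisible(x)
}

## per-node descendant tip sets as a logical matrix (nodes x tips)
.descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  desc <- matrix(FALSE, nn, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge
  for (k in seq_len(nrow(e)))
    desc[e[k, 1L], ] <- desc[e[k, 1L], ] | desc[e[k, 2L], ]
  desc
}

#' Drop infinite-sites mutations onto a tree sequence
#'
#' Mutation counts per genealogy are Poisson with mean
#' `mu * window_bp * total branch length` (branch lengths in generations);
#' each mutation is placed on a branch with probability proportional to its
#' length, at a uniform unique integer position within the window, and
#' yields one biallelic site whose derived allele is carried by the branch's
#' descendant haplotypes. Ancestral allele is written as REF, derived as
#' ALT.
#'
#' @param trees a [tree_sequence()] (or an `hz_sim`, whose trees are used).
#' @param mu per-bp per-generation mutation rate.
#' @param seed integer seed (one child stream per window).
#' @param popmap optional [pop_map()] fixing haplotype column order.
#' @return a [variant_table()].
#' @export
drop_mutations <- function(trees, mu, seed = 1L, popmap = NULL) {
  if (inherits(trees, "hz_sim")) {
    if (is.null(popmap)) popmap <- trees$popmap
    trees <- trees$trees
  }
  stopifnot(inherits(trees, "tree_sequence"))
  if (mu < 0) stop("mu must be >= 0")
  haps <- if (is.null(popmap)) trees$tree[[1L]]$tip.label else
    popmap$haplotype
  nwin <- nrow(trees)
  set.seed(seed)
  win_seeds <- sample.int(2147483646L, nwin)

  chunks <- vector("list", nwin)
  for (w in seq_len(nwin)) {
    tr <- trees$tree[[w]]
    len <- tr$edge.length
    if (any(len < 0)) stop("negative branch length in window ", w)
    span <- trees$end[w] - trees$start[w]
    set.seed(win_seeds[w])
    nmut <- stats::rpois(1L, mu * span * sum(len))
    if (nmut == 0L) next
    if (nmut > span)
      stop("more mutations than sites in window ", w,
           "; infinite-sites assumption violated")
    branch <- sample.int(nrow(tr$edge), nmut, replace = TRUE, prob = len)
    pos <- sort(sample.int(span, nmut)) - 1L + trees$start[w]
    desc <- .descendant_tips(tr)
    col <- match(haps, tr$tip.label)
    if (anyNA(col)) stop("popmap haplotypes missing from tree in window ", w)
    g <- matrix(0L, nmut, length(haps), dimnames = list(NULL, haps))
    for (i in seq_len(nmut))
      g[i, ] <- as.integer(desc[tr$edge[branch[i], 2L], col])
    chunks[[w]] <- list(pos = pos, g = g, chrom = trees$chrom[w])
  }
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  if (!length(chunks)) {
    return(variant_table(character(0), numeric(0),
                         matrix(integer(0), 0L, length(haps),
                                dimnames = list(NULL, haps))))
  }
  variant_table(chrom = unlist(lapply(chunks, function(x)
                  rep(x$chrom, length(x$pos)))),
                pos = unlist(lapply(chunks, `[[`, "pos")),
                geno = do.call(rbind, lapply(chunks, `[[`, "g")))
}

#' Simulate trees and genotypes in one call
#'
#' Convenience wrapper: [simulate_tree_sequence()] followed by
#' [drop_mutations()] at the configured mutation rate.
#'
#' @param cfg a [demography_config()].
#' @return an `hz_sim` with `variants` filled in.
#' @export
simulate_hybrid_zones <- function(cfg) {
  sim <- simulate_tree_sequence(cfg)
  ## distinct stream from the genealogy seeds
  sim$variants <- drop_mutations(sim$trees, cfg$mu,
                                 seed = (cfg$seed + 1000003L) %% 2147483646L,
                                 popmap = sim$popmap)
  sim
}

#' Write all simulator outputs to disk
#'
#' Emits `<prefix>.vcf` (phased diploid GT), `<prefix>.trees.tsv`
#' (chrom/start/end/newick), `<prefix>.popmap.tsv` and `<prefix>.truth.tsv`.
#' All files round-trip through the package readers.
#'
#' @param sim an `hz_sim` (with variants for the VCF to be written).
#' @param prefix output path prefix.
#' @return named character vector of the files written.
#' @export
write_outputs <- function(sim, prefix) {
  stopifnot(inherits(sim, "hz_sim"))
  paths <- c(trees = paste0(prefix, ".trees.tsv"),
             popmap = paste0(prefix, ".popmap.tsv"),
             truth = paste0(prefix, ".truth.tsv"))
  write_tree_sequence(sim$trees, paths[["trees"]])
  write_popmap(sim$popmap, paths[["popmap"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$variants) && nrow(sim$variants$geno) > 0L) {
    paths <- c(paths, vcf = paste0(prefix, ".vcf"))
    write_vcf(sim$variants, paths[["vcf"]],
              contig_length = sim$config$chrom_length)
  }
  invisible(paths)
}
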