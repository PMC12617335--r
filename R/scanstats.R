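## Site and window population-genetic statistics.
##
## Phased haplotypes are treated as haploid samples throughout: the
## Weir-Cockerham estimator uses the two-level (population / haplotype)
## variance components with no within-individual heterozygosity term, and
## pi / d_xy are mean pairwise differences per bp of callable window length.
## Hudson's window F_ST is the ratio-of-averages form
## 1 - mean(pi_within) / d_xy, i.e. window sums are accumulated before the
## ratio is taken (averaging per-site ratios is biased on heterogeneous
## windows and is deliberately not offered).

.pop_cols <- function(v, popmap, pop) {
  h <- popmap$haplotype[popmap$population %in% pop |
                          popmap$variety %in% pop | popmap$zone %in% pop]
  i <- match(h, colnames(v$geno))
  i <- i[!is.na(i)]
  if (!length(i)) stop("no haplotypes found for group: ",
                       paste(pop, collapse = "+"))
  i
}

#' Per-site Weir-Cockerham F_ST for two populations
#'
#' Two-population Weir-Cockerham theta from variance components, haploid
#' treatment: with sample sizes n1, n2 (alleles) and frequencies p1, p2,
#' the among-population mean square is
#' `MSP = sum(n_i (p_i - pbar)^2) / (r - 1)` and the within-population mean
#' square is `MSG = sum(n_i p_i (1 - p_i)) / sum(n_i - 1)`; then
#' `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)` with
#' `n_c = (n_total - sum(n_i^2) / n_total) / (r - 1)`. Sites monomorphic
#' across both samples (0/0) return NA; negative estimates are reported,
#' not clamped.
#'
#' @param alleles1,alleles2 integer vectors of 0/1 alleles (NA = missing)
#'   for the two populations at one site.
#' @return numeric F_ST estimate, possibly negative, or NA.
#' @export
wc_fst_site <- function(alleles1, alleles2) {
  a1 <- alleles1[!is.na(alleles1)]; a2 <- alleles2[!is.na(alleles2)]
  n1 <- length(a1); n2 <- length(a2)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  p1 <- mean(a1); p2 <- mean(a2)
  nt <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / nt
  if (pbar == 0 || pbar == 1) return(NA_real_)
  MSP <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)        # / (r-1), r=2
  MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt                            # / (r-1)
  denom <- MSP + (nc - 1) * MSG
  if (denom == 0) return(NA_real_)
  (MSP - MSG) / denom
}

## per-site building blocks on an allele matrix (sites x haplotypes)
.site_freq <- function(g) {
  n <- rowSums(!is.na(g))
  list(n = n, p = rowSums(g, na.rm = TRUE) / pmax(n, 1L))
}

#' Window diversity and divergence statistics
#'
#' `pi_window` is the mean pairwise difference per bp within one
#' population over the window (`sum 2 p (1-p) n/(n-1) / L`, i.e. the
#' unbiased mean-pairwise estimator; set `unbiased = FALSE` for the
#' plug-in heterozygosity `sum 2 p (1-p) / L`); `dxy_window` the mean
#' between-population pairwise difference per bp
#' (`sum (p1 (1-p2) + p2 (1-p1)) / L`); `hudson_fst_window` is
#' `1 - mean(pi1, pi2) / d_xy` computed from the window sums, using the
#' plug-in within-population heterozygosity so that identical allele
#' frequencies give exactly 0 and fixed differences exactly 1. `L` is the
#' callable window length in bp (sites absent from the table are treated as
#' monomorphic and contribute 0 to the sums).
#'
#' @param v a [variant_table()] restricted to (or indexed within) one
#'   window.
#' @param popmap a [pop_map()].
#' @param pop,pop1,pop2 population (or zone/variety) labels.
#' @param L callable window length in bp.
#' @param sites optional integer row indices of the window's sites.
#' @param unbiased apply the n/(n-1) mean-pairwise correction (default).
#' @return numeric value (NA when undefined, e.g. d_xy = 0 for Hudson).
#' @export
pi_window <- function(v, popmap, pop, L, sites = NULL, unbiased = TRUE) {
  g <- v$geno[if (is.null(sites)) TRUE else sites,
              .pop_cols(v, popmap, pop), drop = FALSE]
  f <- .site_freq(g)
  ok <- f$n >= 2L
  corr <- if (unbiased) f$n[ok] / (f$n[ok] - 1L) else 1
  sum(2 * f$p[ok] * (1 - f$p[ok]) * corr) / L
}

#' @rdname pi_window
#' @export
dxy_window <- function(v, popmap, pop1, pop2, L, sites = NULL) {
  rows <- if (is.null(sites)) TRUE else sites
  g1 <- v$geno[rows, .pop_cols(v, popmap, pop1), drop = FALSE]
  g2 <- v$geno[rows, .pop_cols(v, popmap, pop2), drop = FALSE]
  f1 <- .site_freq(g1); f2 <- .site_freq(g2)
  ok <- f1$n >= 1L & f2$n >= 1L
  sum(f1$p[ok] * (1 - f2$p[ok]) + f2$p[ok] * (1 - f1$p[ok])) / L
}

#' @rdname pi_window
#' @export
hudson_fst_window <- function(v, popmap, pop1, pop2, L, sites = NULL) {
  piw <- (pi_window(v, popmap, pop1, L, sites, unbiased = FALSE) +
            pi_window(v, popmap, pop2, L, sites, unbiased = FALSE)) / 2
  dxy <- dxy_window(v, popmap, pop1, pop2, L, sites)
  if (is.na(dxy) || dxy == 0) return(NA_real_)
  1 - piw / dxy
}

#' Windowed genome scan of differentiation and diversity
#'
#' Cuts the chromosome into non-overlapping windows and computes, for one
#' population pair: number of SNPs, per-population pi, d_xy, Hudson F_ST
#' and the mean per-site Weir-Cockerham F_ST (undefined sites excluded and
#' counted). Windows with fewer than `min_sites` SNPs are masked (statistics
#' set to NA) but kept in the output.
#'
#' @param v a [variant_table()].
#' @param popmap a [pop_map()].
#' @param pop1,pop2 population (or zone/variety) labels.
#' @param window_bp window size in bp (default 10 kbp).
#' @param chrom_length scan length in bp; defaults to the last SNP's
#'   position rounded up to a whole window.
#' @param min_sites minimum SNPs per window before masking (default 10).
#' @return data.frame, one row per window: chrom, start, end, n_sites,
#'   pi1, pi2, dxy, fst_hudson, fst_wc_mean, n_wc_undefined, masked.
#' @export
window_scan <- function(v, popmap, pop1, pop2, window_bp = 1e4,
                        chrom_length = NULL, min_sites = 10L) {
  stopifnot(inherits(v, "variant_table"))
  chrom <- unique(v$sites$chrom)
  if (length(chrom) != 1L)
    stop("window_scan expects a single chromosome; got ", length(chrom))
  if (is.null(chrom_length))
    chrom_length <- ceiling((max(v$sites$pos) + 1) / window_bp) * window_bp
  nwin <- as.integer(ceiling(chrom_length / window_bp))
  starts <- (seq_len(nwin) - 1) * window_bp
  ends <- pmin(starts + window_bp, chrom_length)
  win_of <- findInterval(v$sites$pos, starts)
  i1 <- .pop_cols(v, popmap, pop1); i2 <- .pop_cols(v, popmap, pop2)

  res <- data.frame(chrom = chrom, start = starts, end = ends,
                    n_sites = tabulate(win_of, nbins = nwin),
                    pi1 = NA_real_, pi2 = NA_real_, dxy = NA_real_,
                    fst_hudson = NA_real_, fst_wc_mean = NA_real_,
                    n_wc_undefined = 0L, masked = FALSE,
                    stringsAsFactors = FALSE)
  for (wi in seq_len(nwin)) {
    rows <- which(win_of == wi)
    if (length(rows) < min_sites) { res$masked[wi] <- TRUE; next }
    L <- ends[wi] - starts[wi]
    res$pi1[wi] <- pi_window(v, popmap, pop1, L, rows)
    res$pi2[wi] <- pi_window(v, popmap, pop2, L, rows)
    res$dxy[wi] <- dxy_window(v, popmap, pop1, pop2, L, rows)
    res$fst_hudson[wi] <- hudson_fst_window(v, popmap, pop1, pop2, L, rows)
    wc <- vapply(rows, function(r)
      wc_fst_site(v$geno[r, i1], v$geno[r, i2]), numeric(1))
    res$n_wc_undefined[wi] <- sum(is.na(wc))
    res$fst_wc_mean[wi] <- if (all(is.na(wc))) NA_real_ else
      mean(wc, na.rm = TRUE)
  }
  res
}

#' Local linear (loess-style) smoothing over a bp span
#'
#' Local linear regression with tricube weights over a fixed +-span_bp/2
#' neighbourhood in genomic coordinates, evaluated at every input position.
#' Endpoints use the truncated neighbourhood with the same half-width.
#' Neighbourhoods with fewer than two distinct positions fall back to the
#' local (weighted) mean. Missing values are dropped from the fit but their
#' positions still receive a smoothed value.
#'
#' @param positions sorted numeric vector of bp positions.
#' @param values numeric vector of the statistic to smooth.
#' @param span_bp full window span in bp (default 50 kbp).
#' @return numeric vector of smoothed values at `positions`.
#' @export
loess_smooth <- function(positions, values, span_bp = 5e4) {
  stopifnot(length(positions) == length(values))
  if (is.unsorted(positions)) stop("positions must be sorted")
  h <- span_bp / 2
  ok <- !is.na(values)
  x <- positions[ok]; y <- values[ok]
  out <- rep(NA_real_, length(positions))
  if (!length(x)) return(out)
  lo <- findInterval(positions - h, x, left.open = TRUE) + 1L
  hi <- findInterval(positions + h, x)
  for (i in seq_along(positions)) {
    if (lo[i] > hi[i]) next
    xi <- x[lo[i]:hi[i]]; yi <- y[lo[i]:hi[i]]
    d <- abs(xi - positions[i]) / h
    wt <- (1 - pmin(d, 1)^3)^3
    sw <- sum(wt)
    if (sw == 0 || length(unique(xi)) < 2L) {
      out[i] <- if (sw > 0) sum(wt * yi) / sw else mean(yi)
      next
    }
    xm <- sum(wt * xi) / sw
    ym <- sum(wt * yi) / sw
    sxx <- sum(wt * (xi - xm)^2)
    if (sxx == 0) { out[i] <- ym; next }
    beta <- sum(wt * (xi - xm) * (yi - ym)) / sxx
    out[i] <- ym + beta * (positions[i] - xm)
  }
  out
}

#' Percentile and fixed-threshold outlier calls
#'
#' `percentile_outliers` flags values strictly above the genome-wide
#' `q`-th percentile (linear-interpolation quantile on the unmasked
#' values). `tvar_outliers` applies the two fixed variety-topology
#' thresholds with their exact semantics: strictly greater than 0.55, and
#' greater-or-equal at 0.60.
#'
#' @param values numeric vector (NAs = masked, never flagged).
#' @param q percentile in (0, 100), typically 95 or 99.
#' @return `percentile_outliers`: list with `threshold` and logical
#'   `flag`; `tvar_outliers`: data.frame with logical columns
#'   `over_0.55` and `ge_0.60`.
#' @export
percentile_outliers <- function(values, q = 95) {
  if (all(is.na(values))) stop("all values missing")
  thr <- stats::quantile(values, q / 100, na.rm = TRUE, names = FALSE,
                         type = 7)
  list(threshold = thr, flag = !is.na(values) & values > thr)
}

#' @rdname percentile_outliers
#' @param w_var numeric vector of variety-topology weights.
#' @export
tvar_outliers <- function(w_var) {
  data.frame(w_var = w_var,
             over_0.55 = !is.na(w_var) & w_var > 0.55,
             ge_0.60 = !is.na(w_var) & w_var >= 0.60)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); pairs with a
#' missing value in either vector are dropped.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  stats::cor(x[ok], y[ok], method = "spearman")
}
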