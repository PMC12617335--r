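## Ternary representation of topology weights and left-right asymmetry.
##
## Each genealogy's weight triple (w_geo, w_var, w_alt) is a point in the
## 2-simplex, drawn in an equilateral triangle with the GEO corner at the
## top, VAR at the bottom right and ALT at the bottom left. Under neutral
## sorting of ancestral variation the two discordant topologies are
## exchangeable, so the distribution is mirror-symmetric about the vertical
## (GEO) axis; an excess of points on the VAR side is the tree-based
## analogue of Patterson's D and indicates biased haplotype sharing within
## varieties.

.TERNARY_EPS <- 1e-9

## renormalise over classified mass; drops fully unresolved trees
.classified_weights <- function(w) {
  df <- as.data.frame(w)
  stopifnot(all(c("w_geo", "w_var", "w_alt") %in% names(df)))
  keep <- stats::complete.cases(df[, c("w_geo", "w_var", "w_alt")])
  df <- df[keep, , drop = FALSE]
  tot <- df$w_geo + df$w_var + df$w_alt
  dropped <- sum(tot <= .TERNARY_EPS)
  df <- df[tot > .TERNARY_EPS, , drop = FALSE]
  tot <- tot[tot > .TERNARY_EPS]
  bad <- abs(df$w_geo + df$w_var + df$w_alt +
               (if ("u" %in% names(df)) df$u else 0) - 1) > 1e-6
  if (any(bad)) stop("weights do not lie in the simplex")
  list(geo = df$w_geo / tot, var = df$w_var / tot, alt = df$w_alt / tot,
       n_dropped = dropped)
}

#' Cartesian coordinates of weights in the unit equilateral triangle
#'
#' Vertices: ALT at (0, 0), VAR at (1, 0), GEO at (1/2, sqrt(3)/2), so
#' `x = w_var + w_geo / 2` and `y = w_geo * sqrt(3) / 2`. Weights of
#' polytomous trees are renormalised over the classified mass first; trees
#' with no classified quartets are dropped (and counted).
#'
#' @param w a `topology_weights` data.frame (or any data.frame with columns
#'   w_geo, w_var, w_alt and optionally u).
#' @return data.frame with columns x, y; attribute `n_dropped`.
#' @export
ternary_coordinates <- function(w) {
  cw <- .classified_weights(w)
  out <- data.frame(x = cw$var + cw$geo / 2,
                    y = cw$geo * sqrt(3) / 2)
  attr(out, "n_dropped") <- cw$n_dropped
  out
}

#' Bin weights on a simplex lattice
#'
#' Divides each triangle edge into `1/g` segments, giving `(1/g)^2`
#' congruent subtriangles ("up" and "down" orientations). Each classified
#' tree is assigned to the subtriangle containing its weight point; counts
#' are conserved. Points exactly on a lattice vertex are assigned
#' deterministically by decrementing their largest coordinate (geo, then
#' var, then alt on ties). Mirror bins under reflection across the vertical
#' axis are the pairs `(a, b, c) <-> (a, c, b)` of the same orientation.
#'
#' @param w a `topology_weights` data.frame.
#' @param g granularity: bin edge width in weight units; `1/g` must be an
#'   integer (default 0.02, i.e. 50 bins per edge).
#' @return a `ternary_grid` data.frame: integer lattice indices a (geo),
#'   b (var), c (alt), orientation ("up"/"down") and count; attributes
#'   `granularity`, `n_points`, `n_dropped`.
#' @export
build_grid <- function(w, g = 0.02) {
  K <- round(1 / g)
  if (abs(K * g - 1) > 1e-9)
    stop("granularity g must divide 1 evenly")
  cw <- .classified_weights(w)
  n <- length(cw$geo)
  snap <- function(v) {
    f <- v * K
    r <- round(f)
    ifelse(abs(f - r) < 1e-7, r, floor(f))
  }
  a <- snap(cw$geo); b <- snap(cw$var); c <- snap(cw$alt)
  a <- pmin(a, K); b <- pmin(b, K); c <- pmin(c, K)
  s <- a + b + c
  if (any(s < K - 2L | s > K))
    stop("point outside the simplex beyond tolerance")
  ## s == K: point on a lattice line/vertex; push into an "up" triangle by
  ## decrementing the largest coordinate (deterministic tie-break)
  fix <- which(s == K)
  if (length(fix)) {
    m <- cbind(a[fix], b[fix], c[fix])
    j <- max.col(m, ties.method = "first")
    m[cbind(seq_along(fix), j)] <- m[cbind(seq_along(fix), j)] - 1L
    a[fix] <- m[, 1L]; b[fix] <- m[, 2L]; c[fix] <- m[, 3L]
    s[fix] <- K - 1L
  }
  orient <- ifelse(s == K - 1L, "up", "down")
  key <- paste(a, b, c, orient, sep = ":")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  out <- data.frame(a = as.integer(parts[, 1L]),
                    b = as.integer(parts[, 2L]),
                    c = as.integer(parts[, 3L]),
                    orientation = parts[, 4L],
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b, out$c, out$orientation), ]
  rownames(out) <- NULL
  attr(out, "granularity") <- g
  attr(out, "n_points") <- n
  attr(out, "n_dropped") <- cw$n_dropped
  class(out) <- c("ternary_grid", "data.frame")
  out
}

#' Left-right asymmetry of the ternary weight distribution
#'
#' Counts classified trees strictly right (`w_var > w_alt`) and strictly
#' left (`w_alt > w_var`) of the vertical axis; ties carry no signal and
#' are excluded. Reports `D_lr = (n_right - n_left) / (n_right + n_left)`
#' with an exact two-sided binomial test of H0: p = 0.5, and, when a grid
#' granularity is supplied, per-mirrored-bin binomial tests with
#' Benjamini-Hochberg adjustment across bin pairs.
#'
#' @param w a `topology_weights` data.frame.
#' @param g optional granularity for the per-bin-pair tests (NULL to skip).
#' @return an `asymmetry_result` list: n_right, n_left, n_axis, D_lr,
#'   p_value (global binomial), and `bins` (data.frame of mirrored-bin
#'   counts, p-values and q-values) when `g` is given.
#' @export
asymmetry <- function(w, g = NULL) {
  cw <- .classified_weights(w)
  if (!length(cw$var)) stop("no classified trees")
  right <- cw$var > cw$alt + .TERNARY_EPS
  left <- cw$alt > cw$var + .TERNARY_EPS
  n_right <- sum(right); n_left <- sum(left)
  if (n_right + n_left == 0L)
    stop("all points lie on the symmetry axis")
  D_lr <- (n_right - n_left) / (n_right + n_left)
  p <- stats::binom.test(n_right, n_right + n_left)$p.value
  out <- list(n_right = n_right, n_left = n_left,
              n_axis = length(cw$var) - n_right - n_left,
              D_lr = D_lr, p_value = p, bins = NULL)
  if (!is.null(g)) {
    grid <- build_grid(w, g)
    off <- grid[grid$b != grid$c, , drop = FALSE]
    if (nrow(off)) {
      key <- paste(off$a, pmax(off$b, off$c), pmin(off$b, off$c),
                   off$orientation, sep = ":")
      rightbin <- off$b > off$c
      cr <- tapply(ifelse(rightbin, off$count, 0L), key, sum)
      cl <- tapply(ifelse(rightbin, 0L, off$count), key, sum)
      parts <- do.call(rbind, strsplit(names(cr), ":", fixed = TRUE))
      bins <- data.frame(a = as.integer(parts[, 1L]),
                         hi = as.integer(parts[, 2L]),
                         lo = as.integer(parts[, 3L]),
                         orientation = parts[, 4L],
                         n_right = as.integer(cr),
                         n_left = as.integer(cl),
                         stringsAsFactors = FALSE)
      bins$p_value <- mapply(function(r, l)
        stats::binom.test(r, r + l)$p.value, bins$n_right, bins$n_left)
      bins$q_value <- stats::p.adjust(bins$p_value, method = "BH")
      out$bins <- bins[order(bins$a, bins$hi, bins$lo), ]
      rownames(out$bins) <- NULL
    }
  }
  class(out) <- "asymmetry_result"
  out
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("asymmetry: n_right=%d n_left=%d (n_axis=%d)\n",
              x$n_right, x$n_left, x$n_axis))
  cat(sprintf("  D_lr = %+0.4f (binomial p = %.3g)\n", x$D_lr, x$p_value))
  if (!is.null(x$bins))
    cat(sprintf("  %d mirrored bin pairs tested; %d with q < 0.05\n",
                nrow(x$bins), sum(x$bins$q_value < 0.05)))
  invisible(x)
}
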