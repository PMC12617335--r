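## One-call orchestration of the analysis on a synthetic replicate:
## simulate -> topology weights -> ternary asymmetry -> window scan ->
## TMRCA locus/flank contrast, with every artifact written as plain text.
## The package functions themselves are the command interface; this wrapper
## exists so a whole replicate is reproducible from one config and seed.

#' Serialise / parse a demography configuration as key-value text
#'
#' One `key = value` pair per line, keys exactly the
#' [demography_config()] fields. `barrier_loci` is encoded as
#' `start:end:b` triplets separated by `;`, `sweep_loci` as
#' `start:end:variety:T_sweep:bottleneck_factor` quintuplets.
#'
#' @param cfg a [demography_config()].
#' @param path file path.
#' @export
write_demography_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "demography_config"))
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE,
                                digits = 15)
  lines <- c(
    paste("n_haplotypes_per_deme =",
          paste(cfg$n_haplotypes_per_deme, collapse = ",")),
    vapply(c("N_anc", "N1", "N2", "N_deme", "T_split_var", "T_col", "T_sc",
             "m12", "m21", "growth1", "growth2", "chrom_length",
             "window_bp", "mu", "seed"),
           function(k) paste(k, "=", format(cfg[[k]], digits = 15)),
           character(1)),
    paste("chrom =", cfg$chrom))
  if (!is.null(cfg$barrier_loci))
    lines <- c(lines, paste("barrier_loci =", paste(
      apply(cfg$barrier_loci[, c("start", "end", "b")], 1L,
            function(r) paste(fmt_num(r), collapse = ":")),
      collapse = ";")))
  if (!is.null(cfg$sweep_loci))
    lines <- c(lines, paste("sweep_loci =", paste(
      apply(cfg$sweep_loci, 1L, function(r)
        paste(fmt_num(r[["start"]]), fmt_num(r[["end"]]), r[["variety"]],
              fmt_num(r[["T_sweep"]]), fmt_num(r[["bottleneck_factor"]]),
              sep = ":")),
      collapse = ";")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_demography_config
#' @export
read_demography_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$",
                                  lines))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  names(vals) <- keys
  args <- list()
  num <- function(k) if (k %in% keys) as.numeric(vals[[k]]) else NULL
  for (k in c("N_anc", "N1", "N2", "N_deme", "T_split_var", "T_col",
              "T_sc", "m12", "m21", "growth1", "growth2", "chrom_length",
              "window_bp", "mu"))
    if (!is.null(num(k))) args[[k]] <- num(k)
  if ("seed" %in% keys) args$seed <- as.integer(vals[["seed"]])
  if ("chrom" %in% keys) args$chrom <- vals[["chrom"]]
  if ("n_haplotypes_per_deme" %in% keys)
    args$n_haplotypes_per_deme <-
      as.integer(strsplit(vals[["n_haplotypes_per_deme"]], ",")[[1L]])
  if ("barrier_loci" %in% keys) {
    p <- strsplit(strsplit(vals[["barrier_loci"]], ";")[[1L]], ":")
    args$barrier_loci <- data.frame(
      start = as.numeric(vapply(p, `[`, character(1), 1L)),
      end = as.numeric(vapply(p, `[`, character(1), 2L)),
      b = as.numeric(vapply(p, `[`, character(1), 3L)))
  }
  if ("sweep_loci" %in% keys) {
    p <- strsplit(strsplit(vals[["sweep_loci"]], ";")[[1L]], ":")
    args$sweep_loci <- data.frame(
      start = as.numeric(vapply(p, `[`, character(1), 1L)),
      end = as.numeric(vapply(p, `[`, character(1), 2L)),
      variety = vapply(p, `[`, character(1), 3L),
      T_sweep = as.numeric(vapply(p, `[`, character(1), 4L)),
      bottleneck_factor = as.numeric(vapply(p, `[`, character(1), 5L)))
  }
  do.call(demography_config, args)
}

#' Run the full analysis on one synthetic replicate
#'
#' Simulates a replicate under `config`, computes topology weights for
#' every marginal tree, the ternary asymmetry, a 10-kbp window scan
#' between the two varieties of each zone, the TMRCA summaries and - when
#' the config defines barrier or sweep loci - the locus-versus-flank
#' contrast at their union. All artifacts are written under
#' `out_prefix` (trees, VCF, popmap, truth, weights, scan, TMRCA tables,
#' config echo and a summary file); identical config and seed reproduce
#' identical artifacts.
#'
#' @param config a [demography_config()] or path to a key-value config
#'   file.
#' @param out_prefix path prefix for artifacts (directories are created).
#' @param weight_method "exact" or "sampled" (see [weight_sequence()]).
#' @param n_subtrees subtree count for sampled weighting.
#' @return (invisibly) a list with the summary block and all in-memory
#'   results (sim, weights, asymmetry, scans, tmrca, contrast).
#' @export
run_pipeline <- function(config = demography_config(), out_prefix,
                         weight_method = c("exact", "sampled"),
                         n_subtrees = 10000L) {
  if (is.character(config)) config <- read_demography_config(config)
  stopifnot(inherits(config, "demography_config"))
  weight_method <- match.arg(weight_method)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_hybrid_zones(config)
  ## fail early, naming the offender, if popmap and trees disagree
  tips <- sim$trees$tree[[1L]]$tip.label
  missing <- setdiff(sim$popmap$haplotype, tips)
  if (length(missing))
    stop("haplotype(s) in popmap absent from trees: ",
         paste(missing, collapse = ", "))
  files <- write_outputs(sim, out_prefix)
  write_demography_config(config, paste0(out_prefix, ".config.txt"))

  w <- weight_sequence(sim$trees, sim$popmap, method = weight_method,
                       n_subtrees = n_subtrees, seed = config$seed)
  write_weights(w, paste0(out_prefix, ".weights.tsv"))
  asym <- asymmetry(w, g = 0.02)

  scans <- list()
  if (!is.null(sim$variants) && nrow(sim$variants$geno) > 0L) {
    for (zone in c("Pla", "Ave")) {
      pops <- paste0(zone, c("P", "S"))
      scans[[zone]] <- window_scan(sim$variants, sim$popmap,
                                   pops[1L], pops[2L],
                                   window_bp = config$window_bp,
                                   chrom_length = config$chrom_length)
      utils::write.table(scans[[zone]],
                         paste0(out_prefix, ".scan_", zone, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  tm <- tmrca_summary(sim$trees, sim$popmap, weights = w)
  utils::write.table(as.data.frame(tm), paste0(out_prefix, ".tmrca.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  loci <- rbind(
    if (!is.null(config$barrier_loci))
      config$barrier_loci[, c("start", "end")],
    if (!is.null(config$sweep_loci))
      config$sweep_loci[, c("start", "end")])
  contrast <- NULL
  if (!is.null(loci) && nrow(loci) > 0L)
    contrast <- tryCatch(
      locus_flank_contrast(tm, min(loci$start), max(loci$end)),
      error = function(e) NULL)

  fst95 <- if (length(scans))
    vapply(scans, function(s)
      percentile_outliers(s$fst_hudson, 95)$threshold, numeric(1))
  summary_block <- list(
    n_windows = nrow(sim$trees),
    n_variants = if (is.null(sim$variants)) 0L else nrow(sim$variants$geno),
    mean_w_geo = mean(w$w_geo, na.rm = TRUE),
    mean_w_var = mean(w$w_var, na.rm = TRUE),
    mean_w_alt = mean(w$w_alt, na.rm = TRUE),
    D_lr = asym$D_lr,
    D_lr_p = asym$p_value,
    n_tvar_over_0.55 = sum(tvar_outliers(w$w_var)$over_0.55),
    n_tvar_ge_0.60 = sum(tvar_outliers(w$w_var)$ge_0.60),
    fst95_threshold = if (length(scans)) fst95 else NULL,
    locus_flank_medians = if (!is.null(contrast)) contrast$medians else
      NULL)
  sm <- vapply(summary_block[!vapply(summary_block, is.null, logical(1))],
               function(x) paste(signif(unlist(x), 6), collapse = " "),
               character(1))
  writeLines(paste(names(sm), "=", sm), paste0(out_prefix, ".summary.txt"))

  invisible(list(summary = summary_block, files = files, sim = sim,
                 weights = w, asymmetry = asym, scans = scans,
                 tmrca = tm, contrast = contrast))
}
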