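#' Analysis configuration
#'
#' Collects the thresholds used throughout the pipeline: the Spearman
#' magnitude filter, the FDR level for edge calling, the genus prevalence
#' filter, the median-correlation sign-flip thresholds, the significance
#' level for univariate q-values, and the permutation count for
#' distance-based tests.
#'
#' @param r_threshold minimum |Spearman rho| for a network edge (default 0.5).
#' @param fdr_alpha Benjamini-Hochberg FDR level for edge calling (0.05).
#' @param prevalence_min minimum fraction of all samples in which a genus
#'   must be present (value > 0) to be retained (0.20).
#' @param median_pos_threshold healthy-cohort median-correlation threshold
#'   for sign-flip selection (0.4).
#' @param median_neg_threshold disease-cohort median-correlation threshold
#'   for sign-flip selection (-0.4).
#' @param q_significance q-value below which univariate contrasts are
#'   flagged significant (0.1).
#' @param n_permutations label permutations for PERMANOVA and the dispersion
#'   test (999).
#' @param clr_pseudocount pseudocount added before the centered log-ratio
#'   transform, in the units of the input matrix (0.5: half of the smallest
#'   possible positive count).
#' @param rng_seed master seed; stage seeds derive from it via [derive_seed()].
#' @param bh_family `"per_cohort"` (default: one BH family per cohort) or
#'   `"global"` (one family across cohorts) for network edge q-values.
#' @param univariate_family `"across_features"` (default: BH across features
#'   within each pairwise contrast) or `"within_feature"` (BH across the
#'   three contrasts of each feature).
#' @param correlation_level `"asv"` (default: correlate at ASV level, then
#'   collapse edges to genus) or `"genus"` (correlate aggregated genera).
#' @param correlation_scale `"counts"` (default) or `"absolute"`: abundance
#'   scale fed to the rank-based association networks. Per-sample qPCR
#'   rescaling is not a monotone transform of a taxon's cross-sample
#'   profile, so the count scale is where rank correlations are exact; the
#'   absolute scale is available for sensitivity analyses.
#' @param invert_enrichment_ratio report expected/observed instead of the
#'   conventional observed/expected enrichment ratio (default `FALSE`).
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(r_threshold = 0.5,
                            fdr_alpha = 0.05,
                            prevalence_min = 0.20,
                            median_pos_threshold = 0.4,
                            median_neg_threshold = -0.4,
                            q_significance = 0.1,
                            n_permutations = 999,
                            clr_pseudocount = 0.5,
                            rng_seed = 1L,
                            bh_family = c("per_cohort", "global"),
                            univariate_family = c("across_features", "within_feature"),
                            correlation_level = c("asv", "genus"),
                            correlation_scale = c("counts", "absolute"),
                            invert_enrichment_ratio = FALSE) {
  cfg <- list(
    r_threshold = r_threshold, fdr_alpha = fdr_alpha,
    prevalence_min = prevalence_min,
    median_pos_threshold = median_pos_threshold,
    median_neg_threshold = median_neg_threshold,
    q_significance = q_significance,
    n_permutations = as.integer(n_permutations),
    clr_pseudocount = clr_pseudocount,
    rng_seed = as.integer(rng_seed),
    bh_family = match.arg(bh_family),
    univariate_family = match.arg(univariate_family),
    correlation_level = match.arg(correlation_level),
    correlation_scale = match.arg(correlation_scale),
    invert_enrichment_ratio = isTRUE(invert_enrichment_ratio))
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  if (!(cfg$fdr_alpha > 0 && cfg$fdr_alpha < 1))
    stop_mm("fdr_alpha must be in (0, 1)")
  if (!(cfg$prevalence_min >= 0 && cfg$prevalence_min <= 1))
    stop_mm("prevalence_min must be in [0, 1]")
  if (!(cfg$r_threshold > 0 && cfg$r_threshold <= 1))
    stop_mm("r_threshold must be in (0, 1]")
  if (cfg$n_permutations < 99) stop_mm("n_permutations must be >= 99")
  if (!(cfg$q_significance > 0 && cfg$q_significance < 1))
    stop_mm("q_significance must be in (0, 1)")
  if (cfg$median_pos_threshold <= 0 || cfg$median_neg_threshold >= 0)
    stop_mm("median thresholds must straddle zero")
  invisible(cfg)
}

#' Read / write configuration as YAML
#'
#' The file may hold an `analysis:` block, a `simulation:` block, or both.
#'
#' @param path YAML file path.
#' @return `read_config()`: a list with elements `analysis`
#'   ([analysis_config()]) and/or `simulation` ([simulation_config()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$analysis))
    out$analysis <- do.call(analysis_config, raw$analysis)
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$planted_edges))
      sim$planted_edges <- as.data.frame(do.call(rbind.data.frame, sim$planted_edges))
    if (!is.null(sim$n_samples)) sim$n_samples <- unlist(sim$n_samples)
    if (!is.null(sim$asvs_per_genus)) sim$asvs_per_genus <- unlist(sim$asvs_per_genus)
    out$simulation <- do.call(simulation_config, sim)
  }
  if (!length(out)) stop_mm("config file has neither 'analysis' nor 'simulation' block")
  out
}

#' @rdname read_config
#' @param config a list as returned by [read_config()], or a single
#'   [analysis_config()] / [simulation_config()].
#' @export
write_config <- function(config, path) {
  if (inherits(config, "analysis_config")) config <- list(analysis = config)
  if (inherits(config, "simulation_config")) config <- list(simulation = config)
  ser <- lapply(config, function(blk) {
    blk <- unclass(blk)
    if (!is.null(blk$planted_edges) && is.data.frame(blk$planted_edges))
      blk$planted_edges <- unname(split(blk$planted_edges, seq_len(nrow(blk$planted_edges)))) |>
        lapply(as.list)
    if (!is.null(blk$n_samples)) blk$n_samples <- as.list(blk$n_samples)
    if (!is.null(blk$asvs_per_genus)) blk$asvs_per_genus <- as.list(blk$asvs_per_genus)
    blk
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
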