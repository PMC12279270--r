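#' Planted-edge recovery study
#'
#' Replicated simulation measuring how often planted taxon-metabolite
#' associations pass the network edge filter (`q <= fdr_alpha`,
#' `|rho| >= r_threshold`) in the correct cohort, at the default group
#' sizes (HC 20, CD 23, UC 37). Each replicate plants `edges_per_cohort`
#' associations of strength `rho` per cohort on distinct (genus,
#' metabolite) pairs and runs the preprocessing + network stages. Also
#' reports the misassignment rate: the fraction of planted (cohort, genus,
#' metabolite) triples that surface in a *different* cohort's network.
#'
#' @param n_replicates number of simulation replicates.
#' @param rho planted Spearman strength.
#' @param edges_per_cohort planted edges per cohort (<= 4 with the default
#'   panel).
#' @param seed master seed; replicate seeds derive from it.
#' @param cfg an [analysis_config()].
#' @return A list with per-cohort recovery rates (`recovery` named vector),
#'   `misassignment`, and the counts that produced them.
#' @export
recovery_study <- function(n_replicates = 100, rho = 0.7,
                           edges_per_cohort = 4, seed = 1L,
                           cfg = analysis_config()) {
  groups <- c("HC", "CD", "UC")
  # distinct (genus, metabolite) pairs per cohort, rotating the panel
  plant <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    data.frame(genus = sprintf("g%02d", seq_len(edges_per_cohort)),
               metabolite = sprintf("met%d", ((seq_len(edges_per_cohort) +
                                                 gi - 2) %% 5) + 1),
               group = groups[gi], rho = rho, stringsAsFactors = FALSE)
  }))
  hits <- stats::setNames(numeric(3), groups)
  totals <- stats::setNames(numeric(3), groups)
  misassigned <- 0; mis_total <- 0
  for (r in seq_len(n_replicates)) {
    scfg <- simulation_config(planted_edges = plant,
                              rng_seed = derive_seed(seed, paste0("recovery", r)))
    bnd <- generate_cohort(scfg)
    nets <- run_network_stage(bnd, cfg)
    edges <- do.call(rbind, lapply(nets$networks, `[[`, "edges"))
    edge_keys <- unique(paste(edges$cohort, edges$genus, edges$metabolite_id))
    for (i in seq_len(nrow(plant))) {
      grp <- plant$group[i]
      totals[grp] <- totals[grp] + 1
      if (paste(grp, plant$genus[i], plant$metabolite[i]) %in% edge_keys)
        hits[grp] <- hits[grp] + 1
      others <- setdiff(groups, grp)
      mis_total <- mis_total + length(others)
      misassigned <- misassigned +
        sum(paste(others, plant$genus[i], plant$metabolite[i]) %in% edge_keys)
    }
  }
  list(recovery = hits / totals, n_edge_tests = totals,
       misassignment = misassigned / mis_total,
       n_replicates = n_replicates, rho = rho, seed = seed)
}

#' Sign-flip recovery study
#'
#' Replicated simulation of the anticorrelation selection rule: pairs are
#' planted at `+rho` in HC and `-rho` in CD on single-ASV genera, and a
#' replicate pair counts as recovered when its median correlations satisfy
#' `HC >= pos_threshold` and `CD <= neg_threshold`. The selection rate of
#' never-planted (pure-null) shared pairs is reported alongside.
#'
#' @param n_replicates number of replicates.
#' @param rho planted magnitude (+rho in HC, -rho in CD).
#' @param seed master seed.
#' @param cfg an [analysis_config()].
#' @return A list with `signflip_recovery`, `null_selection_rate`, and
#'   counts.
#' @export
signflip_study <- function(n_replicates = 100, rho = 0.6, seed = 1L,
                           cfg = analysis_config()) {
  # both single-ASV genera of the default panel carry a flip pair
  plant <- data.frame(
    genus = c("g01", "g01", "g02", "g02"),
    metabolite = c("met1", "met1", "met2", "met2"),
    group = c("HC", "CD", "HC", "CD"),
    rho = c(rho, -rho, rho, -rho), stringsAsFactors = FALSE)
  flip_keys <- c("g01 met1", "g02 met2")
  hit <- 0; tot <- 0; null_sel <- 0; null_tot <- 0
  for (r in seq_len(n_replicates)) {
    scfg <- simulation_config(planted_edges = plant,
                              rng_seed = derive_seed(seed, paste0("signflip", r)))
    bnd <- generate_cohort(scfg)
    nets <- run_network_stage(bnd, cfg)
    med <- median_pair_correlations(nets$results)
    anti <- anticorrelation_clusters(med, cfg$median_pos_threshold,
                                     cfg$median_neg_threshold, "CD")
    sc <- anti$scatter
    keys <- paste(sc$genus, sc$metabolite_id)
    planted <- keys %in% flip_keys
    tot <- tot + length(flip_keys)
    hit <- hit + sum(sc$selected[planted])
    null_tot <- null_tot + sum(!planted)
    null_sel <- null_sel + sum(sc$selected[!planted])
  }
  list(signflip_recovery = hit / tot, n_pair_tests = tot,
       null_selection_rate = null_sel / null_tot, n_null_tests = null_tot,
       n_replicates = n_replicates, rho = rho, seed = seed)
}

#' Null-calibration study
#'
#' All-null replicated simulation (no planted edges, default dimensions)
#' measuring (a) the fraction of per-cohort BH families that yield any
#' strong edge (false-positive families) and (b) the fraction of features
#' (genera and metabolites pooled) with any univariate contrast q below
#' 0.05.
#'
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param cfg an [analysis_config()].
#' @return A list with `family_fp_rate`, `univariate_fp_rate`, counts.
#' @export
null_calibration_study <- function(n_replicates = 200, seed = 1L,
                                   cfg = analysis_config()) {
  fam_fp <- 0; fam_tot <- 0
  feat_fp <- 0; feat_tot <- 0
  for (r in seq_len(n_replicates)) {
    scfg <- simulation_config(planted_edges = NULL,
                              rng_seed = derive_seed(seed, paste0("null", r)))
    bnd <- generate_cohort(scfg)
    pre <- preprocess_stage(bnd, cfg)
    nets <- build_networks(network_taxa_input(bnd, cfg), pre$metabolites,
                           bnd$design, cfg, taxonomy = bnd$taxonomy)
    for (nw in nets$networks) {
      fam_tot <- fam_tot + 1
      if (nrow(nw$edges)) fam_fp <- fam_fp + 1
    }
    for (tbl in list(univariate_table(pre$genus, bnd$design, cfg),
                     univariate_table(pre$metabolites, bnd$design, cfg))) {
      qc <- as.matrix(tbl[, grep("_q$", names(tbl))])
      feat_tot <- feat_tot + nrow(tbl)
      feat_fp <- feat_fp + sum(apply(qc < 0.05, 1, any, na.rm = TRUE))
    }
  }
  list(family_fp_rate = fam_fp / fam_tot, n_families = fam_tot,
       univariate_fp_rate = feat_fp / feat_tot, n_features = feat_tot,
       n_replicates = n_replicates, seed = seed)
}

# shared preprocessing for the studies: absolute abundance, filtered genus
# table, imputed metabolites
preprocess_stage <- function(bnd, cfg) {
  absolute <- to_absolute(bnd$counts, bnd$biomass)
  genus <- aggregate_genus(absolute, bnd$taxonomy)
  pf <- prevalence_filter(genus, cfg$prevalence_min)
  cm <- suppressWarnings(condition_metabolites(bnd$metabolites))
  list(absolute = absolute, genus = pf$table, metabolites = cm$imputed)
}

# taxon matrix entering the association networks, honouring the configured
# level (asv / genus) and scale (counts / absolute)
network_taxa_input <- function(bnd, cfg) {
  base <- if (cfg$correlation_scale == "counts") bnd$counts
          else to_absolute(bnd$counts, bnd$biomass)
  if (cfg$correlation_level == "asv") return(base)
  genus <- aggregate_genus(base, bnd$taxonomy)
  prevalence_filter(genus, cfg$prevalence_min)$table
}

run_network_stage <- function(bnd, cfg) {
  pre <- preprocess_stage(bnd, cfg)
  build_networks(network_taxa_input(bnd, cfg), pre$metabolites, bnd$design,
                 cfg,
                 taxonomy = if (cfg$correlation_level == "asv") bnd$taxonomy)
}
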