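#' Run the full integrative analysis pipeline
#'
#' Orchestrates simulate-or-read, preprocessing (absolute abundance, genus
#' aggregation, prevalence filter, CLR, metabolite conditioning), diversity
#' (alpha panel, Aitchison distance, PCoA, PERMANOVA, dispersion test),
#' univariate comparisons, per-cohort association networks with the
#' cross-cohort set analyses, differential-network analyses (median pair
#' correlations, sign-flip clusters, rewiring), metabolite-set enrichment,
#' and — for simulated runs — recovery evaluation against the truth table.
#' All stage outputs are TSV files under `out_dir`; a JSON manifest records
#' the configuration, per-stage seeds, input checksums, output paths, row
#' counts and warnings. Reruns with the same configuration produce
#' bit-identical outputs.
#'
#' @param out_dir output directory (created).
#' @param config a list with elements `analysis` ([analysis_config()]) and
#'   `simulation` ([simulation_config()]), a path to a YAML file for
#'   [read_config()], or `NULL` for defaults.
#' @param input_dir optional directory of input files (`counts.tsv`,
#'   `taxonomy.tsv`, `biomass.tsv`, `metabolites.tsv`, `design.tsv`,
#'   optional `tree.nwk`, `pathways.gmt`); when `NULL` a cohort is
#'   simulated from `config$simulation`.
#' @param seed optional master seed overriding the configured one.
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(out_dir, config = NULL, input_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- config %||% list()
  acfg <- config$analysis %||% analysis_config()
  scfg <- config$simulation %||% simulation_config()
  if (!is.null(seed)) {
    acfg$rng_seed <- as.integer(seed)
    scfg$rng_seed <- derive_seed(seed, "simulate")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = list(analysis = unclass(acfg),
                                 simulation = if (is.null(input_dir)) unclass(scfg)),
                   seeds = list(master = acfg$rng_seed),
                   inputs = list(), outputs = list(), row_counts = list(),
                   warnings = character())
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  emit <- function(stage, name, df, writer = .write_tsv) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    writer(df, path)
    manifest$outputs[[name]] <<- path
    manifest$row_counts[[name]] <<- if (is.data.frame(df)) nrow(df) else NA
    path
  }
  finish <- function(ok) {
    manifest$complete <- ok
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    manifest
  }
  run <- function() {
    ## ---- inputs ----
    if (is.null(input_dir)) {
      bnd <- generate_cohort(scfg)
      if (is.null(bnd$pathways))
        bnd$pathways <- simulate_pathway_library(
          rownames(bnd$metabolites),
          rng_seed = derive_seed(acfg$rng_seed, "pathways"))
      manifest$seeds$simulate <<- scfg$rng_seed
      in_paths <- write_bundle(bnd, file.path(out_dir, "inputs"))
      manifest$inputs <<- as.list(tools::md5sum(in_paths))
    } else {
      p <- function(f) file.path(input_dir, f)
      opt <- function(f) if (file.exists(p(f))) p(f)
      bnd <- withCallingHandlers(
        read_inputs(p("counts.tsv"), p("taxonomy.tsv"), p("biomass.tsv"),
                    p("metabolites.tsv"), p("design.tsv"),
                    tree = opt("tree.nwk"), pathways = opt("pathways.gmt")),
        message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
      if (file.exists(p("truth.tsv"))) bnd$truth <- .read_tsv(p("truth.tsv"))
      files <- list.files(input_dir, full.names = TRUE)
      manifest$inputs <<- as.list(tools::md5sum(files))
    }
    if (nrow(bnd$dropped))
      note(paste("dropped samples:", paste(unique(bnd$dropped$sample_id), collapse = ", ")))

    ## ---- preprocess ----
    absolute <- to_absolute(bnd$counts, bnd$biomass)
    genus_abs <- aggregate_genus(absolute, bnd$taxonomy)
    pf <- prevalence_filter(genus_abs, acfg$prevalence_min)
    emit("preprocess", "prevalence_report", pf$report)
    clr <- clr_transform(absolute, acfg$clr_pseudocount)
    cm <- withCallingHandlers(condition_metabolites(bnd$metabolites),
                              warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    emit("preprocess", "genus_absolute_abundance",
         data.frame(feature_id = rownames(pf$table), ft_values(pf$table),
                    check.names = FALSE))

    ## ---- diversity ----
    alpha <- alpha_diversity(bnd$counts, tree = bnd$tree)
    emit("diversity", "alpha_diversity", alpha)
    dm <- aitchison_distance(clr)
    emit("diversity", "aitchison_distance", dm, writer = write_distance_matrix)
    ord <- ordinate(dm, "pcoa", k = 2)
    emit("diversity", "pcoa_coordinates",
         data.frame(sample_id = rownames(ord$points), ord$points,
                    check.names = FALSE))
    pseed <- derive_seed(acfg$rng_seed, "permanova")
    manifest$seeds$permanova <<- pseed
    pmv <- permanova(dm, bnd$design$group, acfg$n_permutations, seed = pseed)
    dseed <- derive_seed(acfg$rng_seed, "dispersion")
    manifest$seeds$dispersion <<- dseed
    dsp <- dispersion_test(dm, bnd$design$group, acfg$n_permutations, seed = dseed)
    emit("diversity", "beta_tests",
         data.frame(test = c("permanova", "dispersion"),
                    statistic = c(pmv$statistic, dsp$statistic),
                    p_value = c(pmv$p_value, dsp$p_value),
                    n_permutations = c(pmv$n_permutations, dsp$n_permutations),
                    seed = c(pmv$seed, dsp$seed)))

    ## ---- univariate ----
    emit("univariate", "univariate_genera",
         univariate_table(pf$table, bnd$design, acfg))
    emit("univariate", "univariate_metabolites",
         univariate_table(cm$imputed, bnd$design, acfg))

    ## ---- networks ----
    nets <- withCallingHandlers(
      build_networks(network_taxa_input(bnd, acfg), cm$imputed, bnd$design,
                     acfg,
                     taxonomy = if (acfg$correlation_level == "asv") bnd$taxonomy),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    emit("network", "correlation_results",
         transform(nets$results, rho = sprintf("%.17g", rho),
                   p = sprintf("%.17g", p),
                   q = ifelse(is.na(q), NA, sprintf("%.17g", q))))
    all_edges <- do.call(rbind, lapply(nets$networks, `[[`, "edges"))
    write_network(all_edges, file.path(out_dir, "network_edges.tsv"), "tsv")
    manifest$outputs$network_edges <<- file.path(out_dir, "network_edges.tsv")
    manifest$row_counts$network_edges <<- nrow(all_edges)
    write_network(all_edges, file.path(out_dir, "network.graphml"), "graphml")
    manifest$outputs$network_graphml <<- file.path(out_dir, "network.graphml")
    sp_sets <- lapply(nets$networks, function(nw)
      collapse_to_genus(strong_positive(nw$edges, acfg$r_threshold)))
    venn <- cross_state_sets(sp_sets)
    emit("network", "venn_regions", venn$counts)
    emit("network", "variable_genera", variable_genera(sp_sets))

    ## ---- differential ----
    med <- median_pair_correlations(nets$results)
    emit("differential", "median_pair_correlations", med)
    anti <- anticorrelation_clusters(med, acfg$median_pos_threshold,
                                     acfg$median_neg_threshold, "either")
    emit("differential", "anticorrelation_selected", anti$selected)
    emit("differential", "anticorrelation_scatter", anti$scatter)
    genus_nets <- lapply(nets$networks, function(nw) collapse_to_genus(nw$edges))
    rw <- rewiring_scores(genus_nets)
    emit("differential", "rewiring_scores", rw)

    ## ---- enrichment ----
    if (!is.null(bnd$pathways)) {
      background <- intersect(rownames(cm$imputed),
                              unique(unlist(lapply(bnd$pathways, `[[`, "members"))))
      enr <- NULL
      for (grp in names(nets$networks)) {
        qset <- intersect(unique(strong_positive(nets$networks[[grp]]$edges,
                                                 acfg$r_threshold)$metabolite_id),
                          background)
        res <- withCallingHandlers(
          ora(qset, background, bnd$pathways,
              invert_ratio = acfg$invert_enrichment_ratio),
          message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
        if (nrow(res)) enr <- rbind(enr, cbind(cohort = grp, res))
      }
      emit("enrichment", "enrichment",
           enr %||% data.frame(cohort = character()))
    }

    ## ---- evaluation against truth ----
    if (!is.null(bnd$truth) && nrow(bnd$truth)) {
      ev <- evaluate_recovery(nets, bnd$truth,
                              anticorrelation = anti,
                              cfg = acfg)
      emit("evaluate", "recovery",
           data.frame(metric = names(ev), value = unlist(ev)))
    }
    invisible(NULL)
  }
  ok <- TRUE
  tryCatch(run(), error = function(e) {
    ok <<- FALSE
    note(paste("stage failure:", conditionMessage(e)))
    finish(FALSE)
    stop_mm("pipeline aborted: ", conditionMessage(e))
  })
  invisible(finish(ok))
}

#' Evaluate a run against the planted truth table
#'
#' Recall: fraction of planted edges found (genus-level match) in the
#' correct cohort's filtered network. Precision: fraction of filtered edges
#' (collapsed to genus, cohort-matched) that correspond to a planted edge.
#' Sign-flip recall: fraction of planted sign-flip pairs (positive in HC,
#' negative in a disease cohort) selected by the anticorrelation rule. With
#' an all-null truth, precision is undefined (`NA`) and the false-edge
#' count is reported.
#'
#' @param networks a `correlation_networks` object from [build_networks()].
#' @param truth truth table (`genus`, `metabolite`, `group`,
#'   `target_spearman_rho`).
#' @param anticorrelation optional output of [anticorrelation_clusters()].
#' @param cfg an [analysis_config()].
#' @return Named list: `recall`, `precision`, `n_planted`, `n_edges`,
#'   `false_edges`, and (when applicable) `signflip_recall`.
#' @export
evaluate_recovery <- function(networks, truth, anticorrelation = NULL,
                              cfg = analysis_config()) {
  if (is.null(truth)) stop_mm("truth table required")
  edges <- do.call(rbind, lapply(networks$networks, `[[`, "edges"))
  edge_keys <- unique(paste(edges$cohort, edges$genus, edges$metabolite_id))
  truth_pos <- truth[truth$target_spearman_rho > 0, , drop = FALSE]
  truth_keys <- paste(truth_pos$group, truth_pos$genus, truth_pos$metabolite)
  n_planted <- length(truth_keys)
  recall <- if (n_planted) mean(truth_keys %in% edge_keys) else NA_real_
  precision <- if (length(edge_keys) && nrow(truth)) {
    all_truth <- paste(truth$group, truth$genus, truth$metabolite)
    mean(edge_keys %in% all_truth)
  } else NA_real_
  false_edges <- if (length(edge_keys)) {
    all_truth <- paste(truth$group, truth$genus, truth$metabolite)
    sum(!(edge_keys %in% all_truth))
  } else 0L
  out <- list(recall = recall, precision = precision,
              n_planted = n_planted, n_edges = length(edge_keys),
              false_edges = false_edges)
  if (!is.null(anticorrelation)) {
    flips <- find_planted_signflips(truth)
    if (nrow(flips)) {
      sel <- anticorrelation$selected
      sel_keys <- paste(sel$disease, sel$genus, sel$metabolite_id)
      out$signflip_recall <-
        mean(paste(flips$disease, flips$genus, flips$metabolite) %in% sel_keys)
    }
  }
  out
}

# planted pairs positive in HC and negative in a disease cohort
find_planted_signflips <- function(truth) {
  pos <- truth[truth$group == "HC" & truth$target_spearman_rho > 0, ]
  neg <- truth[truth$group %in% c("CD", "UC") & truth$target_spearman_rho < 0, ]
  m <- merge(pos[, c("genus", "metabolite")],
             neg[, c("genus", "metabolite", "group")],
             by = c("genus", "metabolite"))
  if (!nrow(m)) return(data.frame(genus = character(), metabolite = character(),
                                  disease = character()))
  data.frame(genus = m$genus, metabolite = m$metabolite, disease = m$group,
             stringsAsFactors = FALSE)
}
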