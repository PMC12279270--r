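#' Map a target Spearman correlation to the latent Pearson correlation
#'
#' Under a Gaussian copula with continuous margins the Spearman correlation
#' `rho_s` of the observed pair corresponds to a latent bivariate-normal
#' Pearson correlation of `2 sin(pi rho_s / 6)`. The map is odd and strictly
#' monotone on (-1, 1).
#'
#' @param rho_s target Spearman correlation(s), each with |rho_s| < 1.
#' @return Latent Pearson correlation(s) in (-1, 1).
#' @export
spearman_to_latent_pearson <- function(rho_s) {
  if (!is.numeric(rho_s) || any(!is.finite(rho_s)))
    stop_mm("rho_s must be finite numeric")
  if (any(abs(rho_s) >= 1)) stop_mm("|rho_s| must be < 1")
  2 * sin(pi * rho_s / 6)
}

#' Simulation configuration
#'
#' Defines the synthetic three-cohort study the simulator generates: group
#' sizes (default: 20 healthy controls, 23 Crohn's disease, 37 ulcerative
#' colitis), a compact taxon panel (genera each holding one or more ASVs),
#' a targeted metabolite panel, and a set of planted cohort-specific
#' genus-metabolite Spearman associations that form the ground truth.
#'
#' Each planted association acts on one designated "driver" ASV (the first
#' ASV of the genus); other ASVs of the genus stay independent, so that
#' genus-collapse and median-summary logic can be tested against a known
#' mixture of associated and null strains.
#'
#' @param n_samples named integer vector of group sizes `c(HC=, CD=, UC=)`.
#' @param n_genera number of genera.
#' @param asvs_per_genus integer vector (length `n_genera`) of ASVs per genus.
#' @param n_metabolites number of metabolites.
#' @param planted_edges data frame with columns `genus`, `metabolite`,
#'   `group`, `rho` (target Spearman, |rho| < 1); `NULL` for a null
#'   simulation; defaults to [default_planted_edges()].
#' @param nb_dispersion negative-binomial size (dispersion) parameter of the
#'   ASV count margins.
#' @param asv_log_mean,asv_log_sd lognormal hyper-parameters from which
#'   per-ASV mean counts are drawn (heterogeneous across ASVs).
#' @param biomass_log_mean,biomass_log_sd lognormal parameters of per-sample
#'   total 16S copies per gram (default: median 1e9 copies/g).
#' @param metabolite_log_mean,metabolite_log_sd lognormal location
#'   hyper-parameter and per-metabolite scale of concentration margins.
#' @param missing_rate completely-at-random missingness rate for metabolite
#'   cells.
#' @param rng_seed integer seed; the whole bundle is reproducible from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = c(HC = 20L, CD = 23L, UC = 37L),
                              n_genera = 6L,
                              asvs_per_genus = c(1L, 1L, 2L, 2L, 3L, 3L),
                              n_metabolites = 5L,
                              planted_edges = default_planted_edges(),
                              nb_dispersion = 1.0,
                              asv_log_mean = log(100),
                              asv_log_sd = 1.0,
                              biomass_log_mean = log(1e9),
                              biomass_log_sd = 0.5,
                              metabolite_log_mean = log(50),
                              metabolite_log_sd = 1.0,
                              missing_rate = 0.02,
                              rng_seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genera = as.integer(n_genera),
              asvs_per_genus = as.integer(asvs_per_genus),
              n_metabolites = as.integer(n_metabolites),
              planted_edges = planted_edges,
              nb_dispersion = nb_dispersion,
              asv_log_mean = asv_log_mean, asv_log_sd = asv_log_sd,
              biomass_log_mean = biomass_log_mean,
              biomass_log_sd = biomass_log_sd,
              metabolite_log_mean = metabolite_log_mean,
              metabolite_log_sd = metabolite_log_sd,
              missing_rate = missing_rate,
              rng_seed = as.integer(rng_seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (is.null(names(cfg$n_samples)) ||
      !all(names(cfg$n_samples) %in% c("HC", "CD", "UC")))
    stop_mm("n_samples must be named with groups among HC, CD, UC")
  if (any(cfg$n_samples < 3)) stop_mm("each group needs >= 3 samples")
  if (length(cfg$asvs_per_genus) != cfg$n_genera)
    stop_mm("asvs_per_genus must have length n_genera")
  if (any(cfg$asvs_per_genus < 1)) stop_mm("asvs_per_genus must be >= 1")
  pe <- cfg$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    need <- c("genus", "metabolite", "group", "rho")
    if (!all(need %in% names(pe)))
      stop_mm("planted_edges needs columns ", paste(need, collapse = ", "))
    if (any(abs(pe$rho) >= 1)) stop_mm("|target rho| must be < 1")
    if (!all(pe$group %in% names(cfg$n_samples)))
      stop_mm("planted edge group not in n_samples")
    key <- paste(pe$genus, pe$metabolite, pe$group)
    if (anyDuplicated(key))
      stop_mm("duplicate planted (genus, metabolite, group) triple")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_mm("missing_rate must be in [0, 1)")
  if (cfg$nb_dispersion <= 0) stop_mm("nb_dispersion must be > 0")
  invisible(cfg)
}

#' Default planted association set
#'
#' Three strong cohort-specific edges (Spearman 0.7, one per cohort), one
#' extra healthy-cohort edge at 0.6, and one sign-flip pair planted at +0.6
#' in HC and -0.6 in CD on a single-ASV genus.
#'
#' @return A data frame usable as `planted_edges` in [simulation_config()].
#' @export
default_planted_edges <- function() {
  data.frame(
    genus = c("g01", "g03", "g04", "g05", "g02", "g02"),
    metabolite = c("met1", "met2", "met3", "met4", "met5", "met5"),
    group = c("HC", "CD", "UC", "HC", "HC", "CD"),
    rho = c(0.7, 0.7, 0.7, 0.6, 0.6, -0.6),
    stringsAsFactors = FALSE)
}

sim_ids <- function(cfg) {
  genus_ids <- sprintf("g%02d", seq_len(cfg$n_genera))
  asv_genus <- rep(genus_ids, cfg$asvs_per_genus)
  asv_ids <- sprintf("ASV%03d", seq_along(asv_genus))
  met_ids <- sprintf("met%d", seq_len(cfg$n_metabolites))
  list(genus = genus_ids, asv = asv_ids, asv_genus = asv_genus, met = met_ids)
}

sim_taxonomy <- function(cfg) {
  ids <- sim_ids(cfg)
  fam <- sprintf("Family%02d", match(ids$asv_genus, ids$genus))
  genus <- ids$asv_genus
  # last genus carries the Silva missing-genus placeholder to exercise the
  # family-tagged pseudo-genus path downstream
  placeholder <- ids$genus[cfg$n_genera]
  genus[genus == placeholder] <- ""
  data.frame(asv_id = ids$asv, kingdom = "Bacteria", phylum = "PhylumA",
             class = "ClassA", order = "OrderA", family = fam, genus = genus,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort bundle
#'
#' Draws, per group, a latent multivariate normal whose correlation matrix
#' is the identity except for blocks of `spearman_to_latent_pearson(rho)`
#' between the driver ASV of each planted genus and the planted metabolite.
#' Latent ASV margins map through negative-binomial quantiles (heterogeneous
#' means, common dispersion) to counts; metabolite margins map through
#' lognormal quantiles to concentrations. Per-sample biomass is lognormal,
#' metabolite cells go missing completely at random at `missing_rate`, and
#' the planted associations are returned as a truth table.
#'
#' Spearman correlation is invariant under the monotone quantile maps, so a
#' planted effect size is (up to ties among counts) the expected empirical
#' Spearman correlation of the generated pair.
#'
#' @param cfg a [simulation_config()].
#' @return An `mm_bundle` (see [read_inputs()]) whose `truth` element is the
#'   planted-edge table (columns `genus`, `metabolite`, `group`,
#'   `target_spearman_rho`), including a rooted coalescent tree over ASVs.
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  ids <- sim_ids(cfg)
  n_asv <- length(ids$asv); n_met <- length(ids$met)
  with_seed(cfg$rng_seed, {
    asv_mu <- stats::rlnorm(n_asv, cfg$asv_log_mean, cfg$asv_log_sd)
    met_meanlog <- stats::rnorm(n_met, cfg$metabolite_log_mean, 0.5)
    tree <- ape::rcoal(n_asv, tip.label = ids$asv)

    counts <- NULL; mets <- NULL; sample_ids <- character(); groups <- character()
    for (grp in names(cfg$n_samples)) {
      n <- cfg$n_samples[[grp]]
      C <- diag(n_asv + n_met)
      pe <- cfg$planted_edges
      if (!is.null(pe) && nrow(pe)) {
        pe_g <- pe[pe$group == grp, , drop = FALSE]
        for (i in seq_len(nrow(pe_g))) {
          gi <- which(ids$asv_genus == pe_g$genus[i])[1]  # driver ASV
          mj <- match(pe_g$metabolite[i], ids$met)
          if (is.na(gi) || is.na(mj))
            stop_mm("planted edge references unknown genus or metabolite: ",
                    pe_g$genus[i], " / ", pe_g$metabolite[i])
          lat <- spearman_to_latent_pearson(pe_g$rho[i])
          C[gi, n_asv + mj] <- C[n_asv + mj, gi] <- lat
        }
        R <- tryCatch(chol(C), error = function(e) NULL)
        if (is.null(R))
          stop_mm("planted correlation block for group ", grp,
                  " is not positive definite; offending edges: ",
                  paste(sprintf("(%s, %s, %.2f)", pe_g$genus, pe_g$metabolite,
                                pe_g$rho), collapse = ", "))
      } else R <- diag(n_asv + n_met)
      z <- matrix(stats::rnorm(n * (n_asv + n_met)), n) %*% R
      u <- stats::pnorm(z)
      cnt_g <- vapply(seq_len(n_asv), function(j)
        stats::qnbinom(u[, j], size = cfg$nb_dispersion, mu = asv_mu[j]),
        numeric(n))
      met_g <- vapply(seq_len(n_met), function(j)
        stats::qlnorm(u[, n_asv + j], met_meanlog[j], cfg$metabolite_log_sd),
        numeric(n))
      counts <- rbind(counts, cnt_g)
      mets <- rbind(mets, met_g)
      sid <- sprintf("%s_%02d", grp, seq_len(n))
      sample_ids <- c(sample_ids, sid)
      groups <- c(groups, rep(grp, n))
    }
    counts <- t(counts); mets <- t(mets)
    dimnames(counts) <- list(ids$asv, sample_ids)
    dimnames(mets) <- list(ids$met, sample_ids)
    biomass <- data.frame(
      sample_id = sample_ids,
      total_16s_copies = stats::rlnorm(length(sample_ids),
                                       cfg$biomass_log_mean,
                                       cfg$biomass_log_sd),
      stringsAsFactors = FALSE)
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(mets)) < cfg$missing_rate,
                     nrow(mets), ncol(mets))
      # never blank out a whole feature
      keep_one <- apply(drop, 1, all)
      drop[keep_one, 1] <- FALSE
      mets[drop] <- NA_real_
    }
    design <- data.frame(
      sample_id = sample_ids,
      group = factor(groups, levels = names(cfg$n_samples)),
      age = round(stats::runif(length(sample_ids), 18, 75)),
      sex = sample(c("M", "F"), length(sample_ids), replace = TRUE),
      bmi = round(stats::rnorm(length(sample_ids), 24, 3), 1),
      stringsAsFactors = FALSE)
    truth <- if (!is.null(cfg$planted_edges) && nrow(cfg$planted_edges)) {
      data.frame(genus = cfg$planted_edges$genus,
                 metabolite = cfg$planted_edges$metabolite,
                 group = cfg$planted_edges$group,
                 target_spearman_rho = cfg$planted_edges$rho,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(genus = character(), metabolite = character(),
                 group = character(), target_spearman_rho = double())
    }
    suppressMessages(bundle(
      counts = feature_table(counts, "asv_counts"),
      taxonomy = sim_taxonomy(cfg),
      biomass = biomass,
      metabolites = feature_table(mets, "metabolite_concentration"),
      design = design, tree = tree, truth = truth))
  })
}

#' Simulate a small metabolite pathway library
#'
#' Partitions the metabolite panel into a handful of synthetic pathways
#' (plus one broader set), for exercising over-representation analysis on
#' simulated runs. Deterministic given the seed.
#'
#' @param metabolite_ids character vector of metabolite ids.
#' @param n_pathways number of disjoint base pathways.
#' @param rng_seed integer seed.
#' @return A `pathway_library` (see [read_gmt()]).
#' @export
simulate_pathway_library <- function(metabolite_ids, n_pathways = 3L,
                                     rng_seed = 1L) {
  stopifnot(length(metabolite_ids) >= n_pathways)
  with_seed(rng_seed, {
    shuffled <- sample(metabolite_ids)
    grp <- rep(seq_len(n_pathways), length.out = length(shuffled))
    sets <- lapply(seq_len(n_pathways), function(i) {
      list(id = sprintf("PW%02d", i), name = sprintf("synthetic pathway %d", i),
           members = sort(shuffled[grp == i]))
    })
    sets <- c(sets, list(list(id = "PW_broad", name = "synthetic broad set",
                              members = sort(metabolite_ids))))
    names(sets) <- vapply(sets, `[[`, "", "id")
    structure(sets, class = "pathway_library")
  })
}

#' Write a simulated bundle to a directory of plain-text files
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `biomass.tsv`, `metabolites.tsv`,
#' `design.tsv`, `tree.nwk`, and `truth.tsv` (plus `pathways.gmt` when a
#' library is attached), in the formats [read_inputs()] consumes.
#'
#' @param bundle an `mm_bundle`.
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    biomass = file.path(dir, "biomass.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    design = file.path(dir, "design.tsv"))
  write_feature_table(bundle$counts, paths["counts"])
  .write_tsv(bundle$taxonomy, paths["taxonomy"])
  .write_tsv(bundle$biomass, paths["biomass"])
  write_feature_table(bundle$metabolites, paths["metabolites"])
  .write_tsv(bundle$design, paths["design"])
  if (!is.null(bundle$tree)) {
    paths["tree"] <- file.path(dir, "tree.nwk")
    ape::write.tree(bundle$tree, paths["tree"])
  }
  if (!is.null(bundle$truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    .write_tsv(bundle$truth, paths["truth"])
  }
  if (!is.null(bundle$pathways)) {
    paths["pathways"] <- file.path(dir, "pathways.gmt")
    write_gmt(bundle$pathways, paths["pathways"])
  }
  paths
}
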