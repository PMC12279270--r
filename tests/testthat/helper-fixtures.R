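# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(10, 5, 0,
                2, 8, 4,
                0, 0, 6,
                3, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("ASV", 1:4), paste0("s", 1:3)))
  feature_table(m, "asv_counts")
}

toy_taxonomy <- function() {
  data.frame(asv_id = paste0("ASV", 1:4), kingdom = "Bacteria",
             phylum = "P", class = "C", order = "O",
             family = c("F1", "F1", "F2", "Lachnospiraceae"),
             genus = c("g1", "g1", "g2", ""),
             stringsAsFactors = FALSE)
}

toy_biomass <- function(samples = paste0("s", 1:3)) {
  data.frame(sample_id = samples,
             total_16s_copies = c(1e9, 2e9, 5e8)[seq_along(samples)],
             stringsAsFactors = FALSE)
}

toy_metabolites <- function() {
  m <- matrix(c(2, 4, NA,
                1, 1, 1,
                5, 3, 9), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("met", 1:3), paste0("s", 1:3)))
  feature_table(m, "metabolite_concentration")
}

toy_design <- function(samples = paste0("s", 1:3),
                       groups = c("HC", "CD", "UC")) {
  data.frame(sample_id = samples,
             group = factor(groups, levels = c("HC", "CD", "UC")),
             stringsAsFactors = FALSE)
}

write_toy_inputs <- function(dir, n_samples = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(toy_counts(), file.path(dir, "counts.tsv"))
  utils::write.table(toy_taxonomy(), file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(toy_biomass(), file.path(dir, "biomass.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_table(toy_metabolites(), file.path(dir, "metabolites.tsv"))
  utils::write.table(toy_design(), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  dir
}

random_edges <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    cohort = sample(c("HC", "CD", "UC"), n, replace = TRUE),
    taxon_id = sprintf("ASV%03d", sample(1:50, n, replace = TRUE)),
    genus = sprintf("g%02d", sample(1:10, n, replace = TRUE)),
    metabolite_id = sprintf("met%d", sample(1:8, n, replace = TRUE)),
    rho = round(runif(n, -1, 1), 10),
    p = runif(n), q = runif(n), stringsAsFactors = FALSE)
}

toy_tree_text <- "((A:1,B:1):1,(C:1,D:1):1):0;"
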