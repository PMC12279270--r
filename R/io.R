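.read_tsv <- function(path) {
  if (!file.exists(path)) stop_mm("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    quote = "")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# parse a character matrix of cells into numerics, reporting the first
# offending row/column on failure
.numeric_cells <- function(df, path, allow_na = FALSE) {
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_mm(sprintf("non-numeric cell in %s at row %d, column '%s': '%s'",
                    path, bad[1, 1], colnames(m)[bad[1, 2]], m[bad[1, ]]))
  if (!allow_na && anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_mm(sprintf("missing value in %s at row %d, column '%s' (not permitted here)",
                    path, bad[1, 1], colnames(m)[bad[1, 2]]))
  }
  num
}

#' Read a feature table from TSV
#'
#' First column holds feature ids; remaining columns are samples. Empty
#' cells are allowed (as `NA`) only for `metabolite_concentration` tables.
#'
#' @param path TSV file with a header row.
#' @param kind the kind tag, see [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, kind) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop_mm("feature table needs an id column plus >=1 sample: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_mm("duplicate feature ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- .numeric_cells(df[, -1, drop = FALSE], path,
                         allow_na = identical(kind, "metabolite_concentration"))
  rownames(vals) <- ids
  feature_table(vals, kind)
}

#' @rdname read_feature_table
#' @param x a [feature_table()] to write.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), ft_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a Silva-style taxonomy table
#'
#' Expected columns: `asv_id`, then the seven ranks `kingdom` ... `genus`
#' (a `species` column, if present, is carried along). Genus may be empty /
#' a placeholder for unclassified ASVs.
#'
#' @param path TSV file.
#' @return A data frame with one row per ASV.
#' @export
read_taxonomy <- function(path) {
  df <- .read_tsv(path)
  need <- c("asv_id", "kingdom", "phylum", "class", "order", "family", "genus")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_mm("taxonomy file missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$asv_id))
    stop_mm("duplicate asv_id in taxonomy: ",
            paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "))
  df
}

#' Read a per-sample total bacterial biomass series
#'
#' Columns: `sample_id`, `total_16s_copies` (qPCR-derived 16S copies per
#' gram of stool; strictly positive).
#'
#' @param path TSV file.
#' @return A data frame with one row per sample.
#' @export
read_biomass <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample_id", "total_16s_copies") %in% names(df)))
    stop_mm("biomass file needs columns sample_id, total_16s_copies")
  if (anyDuplicated(df$sample_id))
    stop_mm("duplicate sample_id in biomass: ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$total_16s_copies <- as.numeric(df$total_16s_copies)
  if (any(!is.finite(df$total_16s_copies)) || any(df$total_16s_copies <= 0))
    stop_mm("total_16s_copies must be strictly positive and finite")
  df
}

#' Read the cohort design table
#'
#' Columns: `sample_id`, `group` (one of HC, CD, UC); further covariate
#' columns (age, sex, BMI, ...) are carried but not modelled.
#'
#' @param path TSV file.
#' @return A data frame; `group` is a factor with levels HC, CD, UC.
#' @export
read_design <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_mm("design file needs columns sample_id, group")
  if (anyDuplicated(df$sample_id))
    stop_mm("duplicate sample_id in design: ",
            paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("HC", "CD", "UC"))
  if (length(bad)) stop_mm("unknown group labels: ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = c("HC", "CD", "UC"))
  df
}

#' Read / write a metabolite pathway library (GMT)
#'
#' Each GMT line is `pathway_id <TAB> pathway_name <TAB> member1 <TAB> ...`
#' with at least one member.
#'
#' @param path GMT file.
#' @return A `pathway_library`: a named list with `id`, `name`, `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_mm("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_mm("GMT line with fewer than 3 fields: ", ln)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) stop_mm("empty pathway in GMT: ", f[1])
    list(id = f[1], name = f[2], members = members)
  })
  ids <- vapply(sets, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_mm("duplicate pathway ids in GMT: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  structure(sets, class = "pathway_library")
}

#' @rdname read_gmt
#' @param library a `pathway_library`.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(library, function(s)
    paste(c(s$id, s$name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' @param path newick file; leaf labels must be ASV ids, unique, with
#'   non-negative branch lengths.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_mm("could not parse newick tree: ", path)
  if (anyDuplicated(tree$tip.label))
    stop_mm("duplicate leaf labels in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_mm("negative branch lengths in tree")
  tree
}

#' Read and cross-validate the full input bundle
#'
#' Reads counts, taxonomy, biomass, metabolites and design (plus optional
#' tree and pathway library), intersects the sample universe across all
#' sample-indexed tables, reorders everything to a common sample order, and
#' records which samples were dropped from which input.
#'
#' @param counts,taxonomy,biomass,metabolites,design file paths (TSV).
#' @param tree optional newick file path.
#' @param pathways optional GMT file path.
#' @return An `mm_bundle` list with elements `counts`, `taxonomy`,
#'   `biomass`, `metabolites`, `design`, optional `tree` and `pathways`,
#'   `sample_ids`, and a `dropped` report data frame.
#' @export
read_inputs <- function(counts, taxonomy, biomass, metabolites, design,
                        tree = NULL, pathways = NULL) {
  cnt <- read_feature_table(counts, "asv_counts")
  tax <- read_taxonomy(taxonomy)
  bio <- read_biomass(biomass)
  met <- read_feature_table(metabolites, "metabolite_concentration")
  des <- read_design(design)
  bundle(counts = cnt, taxonomy = tax, biomass = bio, metabolites = met,
         design = des,
         tree = if (!is.null(tree)) read_phylo_tree(tree),
         pathways = if (!is.null(pathways)) read_gmt(pathways))
}

#' Assemble and validate an in-memory input bundle
#'
#' Performs the same sample intersection and validation as [read_inputs()]
#' but on objects already in memory (e.g. from [generate_cohort()]).
#'
#' @param counts ASV [feature_table()]; `taxonomy` data frame;
#'   `biomass` data frame; `metabolites` metabolite [feature_table()];
#'   `design` data frame; optional `tree` (`phylo`), `pathways`
#'   (`pathway_library`), `truth` data frame.
#' @param taxonomy,biomass,metabolites,design,tree,pathways,truth see above.
#' @return An `mm_bundle` list; see [read_inputs()].
#' @export
bundle <- function(counts, taxonomy, biomass, metabolites, design,
                   tree = NULL, pathways = NULL, truth = NULL) {
  universes <- list(counts = colnames(counts),
                    biomass = as.character(biomass$sample_id),
                    metabolites = colnames(metabolites),
                    design = as.character(design$sample_id))
  common <- Reduce(intersect, universes)
  if (!length(common)) stop_mm("empty sample intersection across inputs")
  # keep the counts table's order for the common samples
  common <- universes$counts[universes$counts %in% common]
  dropped <- do.call(rbind, lapply(names(universes), function(nm) {
    d <- setdiff(universes[[nm]], common)
    if (!length(d)) return(NULL)
    data.frame(input = nm, sample_id = d, stringsAsFactors = FALSE)
  }))
  if (!is.null(dropped) && nrow(dropped))
    message("read_inputs: dropped ", nrow(dropped),
            " sample entr", if (nrow(dropped) == 1) "y" else "ies",
            " outside the common sample set (",
            paste(unique(dropped$sample_id), collapse = ", "), ")")
  missing_tax <- setdiff(rownames(counts), taxonomy$asv_id)
  if (length(missing_tax))
    stop_mm("ASVs absent from taxonomy: ", paste(missing_tax, collapse = ", "))
  out <- list(
    counts = ft_align(counts, common),
    taxonomy = taxonomy,
    biomass = bio_align(biomass, common),
    metabolites = ft_align(metabolites, common),
    design = des_align(design, common),
    tree = tree, pathways = pathways, truth = truth,
    sample_ids = common,
    dropped = dropped %||% data.frame(input = character(), sample_id = character()))
  class(out) <- "mm_bundle"
  out
}

bio_align <- function(biomass, sample_ids) {
  biomass[match(sample_ids, biomass$sample_id), , drop = FALSE]
}

des_align <- function(design, sample_ids) {
  design[match(sample_ids, design$sample_id), , drop = FALSE]
}

#' @export
print.mm_bundle <- function(x, ...) {
  cat(sprintf("mm_bundle: %d samples, %d ASVs, %d metabolites%s%s\n",
              length(x$sample_ids), nrow(x$counts), nrow(x$metabolites),
              if (!is.null(x$tree)) ", tree" else "",
              if (!is.null(x$truth)) ", truth table" else ""))
  invisible(x)
}

#' Write / read an association network
#'
#' The edge-list TSV has exactly the columns `cohort`, `taxon_id`, `genus`,
#' `metabolite_id`, `rho`, `p`, `q`; values round-trip at full double
#' precision. The GraphML form encodes a bipartite `node_type` vertex
#' attribute (`taxon` / `metabolite`) and `rho`, `p`, `q`, `cohort` edge
#' attributes.
#'
#' @param edges a data frame of association edges (one cohort label per
#'   row in column `cohort`).
#' @param path output file.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return The path, invisibly.
#' @export
write_network <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  cols <- c("cohort", "taxon_id", "genus", "metabolite_id", "rho", "p", "q")
  if (!nrow(edges)) {
    edges <- data.frame(cohort = character(), taxon_id = character(),
                        genus = character(), metabolite_id = character(),
                        rho = double(), p = double(), q = double())
  }
  miss <- setdiff(cols, names(edges))
  if (length(miss)) stop_mm("edges missing columns: ", paste(miss, collapse = ", "))
  edges <- edges[, cols, drop = FALSE]
  if (format == "tsv") {
    out <- edges
    for (nm in c("rho", "p", "q"))
      out[[nm]] <- vapply(edges[[nm]], function(v)
        if (is.na(v)) NA_character_ else sprintf("%.17g", v), "")
    .write_tsv(out, path)
  } else {
    taxa <- unique(edges$taxon_id); mets <- unique(edges$metabolite_id)
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, length(taxa) + length(mets),
                              name = c(taxa, mets),
                              node_type = c(rep("taxon", length(taxa)),
                                            rep("metabolite", length(mets))))
    if (nrow(edges)) {
      ends <- rbind(match(edges$taxon_id, c(taxa, mets)),
                    match(edges$metabolite_id, c(taxa, mets)))
      g <- igraph::add_edges(g, as.vector(ends),
                             cohort = edges$cohort, genus = edges$genus,
                             rho = edges$rho, p = edges$p, q = edges$q)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- .read_tsv(path)
  for (nm in c("rho", "p", "q")) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("cohort", "taxon_id", "genus", "metabolite_id"))
    df[[nm]] <- as.character(df[[nm]])
  df
}

#' Write / read a square distance matrix as TSV
#'
#' @param dm a `dist` object or square symmetric matrix with sample ids.
#' @param path TSV file.
#' @return `read_distance_matrix()` returns a symmetric numeric matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m, t(m)))) stop_mm("distance matrix is not symmetric")
  m
}
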