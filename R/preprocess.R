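#' Transform compositional counts to absolute (ecosystem) abundance
#'
#' Rescales each sample's relative ASV composition by its qPCR-derived
#' total bacterial biomass: `value(f, s) = count(f, s) / library_size(s) *
#' total_16s_copies(s)`. Column sums of the result equal the biomass
#' exactly, so the compositional information is preserved while restoring
#' an ecosystem scale (copies per gram of stool).
#'
#' @param counts an `asv_counts` (or `genus_abundance`) [feature_table()].
#' @param biomass a biomass data frame (see [read_biomass()]) covering every
#'   sample of `counts`.
#' @return An `absolute_abundance` [feature_table()].
#' @export
to_absolute <- function(counts, biomass) {
  b <- bio_align(biomass, colnames(counts))
  if (anyNA(b$total_16s_copies))
    stop_mm("biomass missing for samples: ",
            paste(colnames(counts)[is.na(b$total_16s_copies)], collapse = ", "))
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop_mm("zero library size in samples: ",
            paste(colnames(counts)[lib <= 0], collapse = ", "))
  vals <- sweep(ft_values(counts), 2, b$total_16s_copies / lib, `*`)
  feature_table(vals, "absolute_abundance")
}

genus_placeholders <- c("", "g__", "unclassified", "NA")

# resolve the genus label of each taxonomy row; unclassified ASVs become
# family-tagged pseudo-genera ("<family>_unclassified")
genus_labels <- function(taxonomy) {
  g <- as.character(taxonomy$genus)
  f <- as.character(taxonomy$family)
  miss <- is.na(g) | g %in% genus_placeholders
  f[is.na(f) | f %in% c("", "f__")] <- "Unknown"
  g[miss] <- paste0(f[miss], "_unclassified")
  g
}

#' Aggregate ASV-level values to genus level
#'
#' Sums member-ASV values per genus and sample. ASVs with a missing genus
#' label are retained as distinct family-tagged pseudo-genera
#' (`"<family>_unclassified"`) rather than dropped, since group-level Silva
#' labels can still carry findings. Per-sample totals are conserved.
#'
#' @param table an ASV-level [feature_table()].
#' @param taxonomy taxonomy data frame with one row per ASV
#'   (see [read_taxonomy()]).
#' @return A `genus_abundance` [feature_table()] (genera sorted by name).
#' @export
aggregate_genus <- function(table, taxonomy) {
  miss <- setdiff(rownames(table), taxonomy$asv_id)
  if (length(miss))
    stop_mm("ASVs absent from taxonomy: ", paste(miss, collapse = ", "))
  lab <- genus_labels(taxonomy)[match(rownames(table), taxonomy$asv_id)]
  agg <- rowsum(ft_values(table), group = lab, reorder = TRUE)
  feature_table(agg, "genus_abundance")
}

#' Prevalence filter
#'
#' Keeps features present (value > 0) in at least `prevalence_min` of all
#' samples, computed over the pooled cohort (not per group), and reports
#' the decision for every input feature.
#'
#' @param table a [feature_table()].
#' @param prevalence_min minimum fraction of samples, in `[0, 1]`.
#' @return A list with `table` (filtered [feature_table()]) and `report`
#'   (data frame: `feature_id`, `n_present`, `fraction_present`, `kept`).
#' @export
prevalence_filter <- function(table, prevalence_min = 0.20) {
  if (!nrow(table)) stop_mm("prevalence_filter: empty table")
  pres <- rowSums(ft_values(table) > 0, na.rm = TRUE)
  frac <- pres / ncol(table)
  kept <- frac >= prevalence_min
  report <- data.frame(feature_id = rownames(table), n_present = pres,
                       fraction_present = frac, kept = kept,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(kept)) warning("prevalence_filter removed every feature")
  list(table = table[kept, , drop = FALSE], report = report)
}

#' Centered log-ratio transform
#'
#' Per sample `s`: `x'(f, s) = ln(v(f, s) + pseudocount) - mean_f ln(v(f, s)
#' + pseudocount)`. Each sample's CLR values sum to zero.
#'
#' @param table a non-negative [feature_table()].
#' @param pseudocount added to every value before taking logs; must be
#'   positive when zeros are present.
#' @return A `clr_values` [feature_table()].
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  v <- ft_values(table)
  if (anyNA(v)) stop_mm("clr_transform: missing values present")
  if (pseudocount <= 0 && any(v == 0))
    stop_mm("non-positive pseudocount with zeros present")
  lg <- log(v + pseudocount)
  out <- sweep(lg, 2, colMeans(lg), `-`)
  feature_table(out, "clr_values")
}

#' Condition a metabolite matrix for analysis
#'
#' Imputes missing cells as half the feature's minimum observed positive
#' value (standard metabolomics practice) and produces a log-transformed
#' copy for univariate use. Rank-based analyses should consume the unlogged
#' imputed matrix: ranks are invariant under the log.
#'
#' Features with no observed values are dropped with a warning. In the log
#' copy, non-positive entries (possible only when a zero concentration was
#' observed) are floored at half the feature's minimum positive value.
#'
#' @param table a `metabolite_concentration` [feature_table()].
#' @return A list with `imputed` (a `metabolite_concentration`
#'   [feature_table()], no missing cells) and `logged` (plain numeric
#'   matrix, natural-log copy).
#' @export
condition_metabolites <- function(table) {
  v <- ft_values(table)
  all_missing <- apply(v, 1, function(r) all(is.na(r)))
  if (any(all_missing)) {
    warning("dropping entirely missing metabolites: ",
            paste(rownames(v)[all_missing], collapse = ", "))
    v <- v[!all_missing, , drop = FALSE]
  }
  halfmin <- apply(v, 1, function(r) {
    pos <- r[!is.na(r) & r > 0]
    if (length(pos)) min(pos) / 2 else NA_real_
  })
  for (i in seq_len(nrow(v))) {
    na <- is.na(v[i, ])
    if (any(na)) {
      if (is.na(halfmin[i]))
        stop_mm("metabolite ", rownames(v)[i],
                " has missing cells but no positive observations")
      v[i, na] <- halfmin[i]
    }
  }
  lv <- v
  for (i in seq_len(nrow(lv))) {
    bad <- lv[i, ] <= 0
    if (any(bad)) {
      if (is.na(halfmin[i])) halfmin[i] <- 1
      lv[i, bad] <- halfmin[i]
      warning("flooring non-positive concentrations of ", rownames(lv)[i],
              " before log")
    }
  }
  list(imputed = feature_table(v, "metabolite_concentration"),
       logged = log(lv))
}
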