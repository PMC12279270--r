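#' Median genus-metabolite correlation per cohort
#'
#' For each (genus, metabolite, cohort), the median of the Spearman rho
#' values of all tested member ASVs — all ASVs of the genus that entered
#' the correlation family, not only those passing the edge filters — so
#' that genera with multiple associating strains are summarised by their
#' typical behaviour. Degenerate (constant) pairs are excluded. An even
#' number of member rhos yields the mean of the central pair.
#'
#' @param results the full unfiltered results table from [build_networks()].
#' @return Data frame: `cohort`, `genus`, `metabolite_id`, `median_rho`,
#'   `n_asvs`.
#' @export
median_pair_correlations <- function(results) {
  sub <- results[!results$degenerate, , drop = FALSE]
  key <- interaction(sub$cohort, sub$genus, sub$metabolite_id, drop = TRUE)
  parts <- split(sub, key)
  out <- do.call(rbind, lapply(parts, function(s)
    data.frame(cohort = s$cohort[1], genus = s$genus[1],
               metabolite_id = s$metabolite_id[1],
               median_rho = stats::median(s$rho), n_asvs = nrow(s),
               stringsAsFactors = FALSE)))
  out <- out[order(out$cohort, out$genus, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anticorrelation (sign-flip) clusters
#'
#' Selects genus-metabolite pairs whose median correlation is at least
#' `pos_threshold` in the healthy cohort and at most `neg_threshold` in the
#' disease cohort — associations strongly positive in health that flip
#' negative in disease. Pairs untested in either cohort are excluded from
#' the contrast (not imputed as zero). Scatterplot coordinates (healthy
#' median vs disease median, with the selection flag) are emitted for every
#' shared pair.
#'
#' @param summaries output of [median_pair_correlations()]; must contain HC
#'   and the requested disease cohort(s).
#' @param pos_threshold healthy-cohort threshold (default 0.4).
#' @param neg_threshold disease-cohort threshold (default -0.4).
#' @param disease `"CD"`, `"UC"`, or `"either"` (union of both contrasts).
#' @return A list with `selected` (data frame: `genus`, `metabolite_id`,
#'   `disease`, `hc_median`, `disease_median`) and `scatter` (all shared
#'   pairs per contrast with a `selected` flag).
#' @export
anticorrelation_clusters <- function(summaries, pos_threshold = 0.4,
                                     neg_threshold = -0.4,
                                     disease = c("CD", "UC", "either")) {
  disease <- match.arg(disease)
  targets <- if (disease == "either") c("CD", "UC") else disease
  have <- unique(summaries$cohort)
  if (!("HC" %in% have)) stop_mm("summaries lack the HC cohort")
  missing <- setdiff(targets, have)
  if (length(missing))
    stop_mm("summaries lack cohort(s): ", paste(missing, collapse = ", "))
  hc <- summaries[summaries$cohort == "HC", , drop = FALSE]
  scatter <- NULL; selected <- NULL
  for (d in targets) {
    dd <- summaries[summaries$cohort == d, , drop = FALSE]
    m <- merge(hc[, c("genus", "metabolite_id", "median_rho")],
               dd[, c("genus", "metabolite_id", "median_rho")],
               by = c("genus", "metabolite_id"),
               suffixes = c("_hc", "_disease"))
    if (!nrow(m)) next
    m$disease <- d
    m$selected <- m$median_rho_hc >= pos_threshold &
      m$median_rho_disease <= neg_threshold
    names(m)[names(m) == "median_rho_hc"] <- "hc_median"
    names(m)[names(m) == "median_rho_disease"] <- "disease_median"
    m <- m[order(m$genus, m$metabolite_id), , drop = FALSE]
    scatter <- rbind(scatter, m)
    selected <- rbind(selected,
                      m[m$selected, c("genus", "metabolite_id", "disease",
                                      "hc_median", "disease_median")])
  }
  empty <- data.frame(genus = character(), metabolite_id = character(),
                      disease = character(), hc_median = double(),
                      disease_median = double())
  list(selected = if (is.null(selected)) empty else
         `rownames<-`(unique(selected), NULL),
       scatter = scatter %||% cbind(empty, selected = logical()))
}

#' Node rewiring scores across network states
#'
#' For each node (genus or metabolite), builds one weight vector per state
#' over the union of the node's partners across all states (entry = edge
#' rho when the edge is present in that state's network, else 0), takes the
#' elementwise mean as the centroid, and scores rewiring as the mean
#' Euclidean distance of the state vectors from the centroid:
#' `dn(v) = (1/S) * sum_s ||w_s - centroid||`. A degree-corrected variant
#' divides by the union degree. `dn = 0` exactly when the node's weighted
#' neighbourhood is identical in every state; nodes absent from all states
#' are omitted.
#'
#' The concrete formula is this package's reconstruction of the Dn score of
#' dynamic-network comparison tools; see the methods vignette for the
#' normalisation choices.
#'
#' @param state_edges named list (>= 2 states) of genus-level edge data
#'   frames with columns `genus`, `metabolite_id`, and a weight column
#'   (`median_rho` or `rho`).
#' @return Data frame: `node_id`, `node_type`, `dn`, `union_degree`,
#'   `degree_corrected_dn`, sorted by decreasing `dn`.
#' @export
rewiring_scores <- function(state_edges) {
  if (length(state_edges) < 2) stop_mm("rewiring_scores needs >= 2 states")
  wcol <- function(df) {
    for (cand in c("median_rho", "rho", "weight"))
      if (cand %in% names(df)) return(cand)
    stop_mm("edge table needs a weight column (median_rho, rho or weight)")
  }
  genera <- unique(unlist(lapply(state_edges, `[[`, "genus")))
  mets <- unique(unlist(lapply(state_edges, `[[`, "metabolite_id")))
  clash <- intersect(genera, mets)
  if (length(clash))
    stop_mm("node id(s) used as both genus and metabolite: ",
            paste(clash, collapse = ", "))
  S <- length(state_edges)
  weight_of <- function(df, from, to) {
    w <- wcol(df)
    key <- paste(df$genus, df$metabolite_id, sep = "|")
    stats::setNames(df[[w]], key)
  }
  maps <- lapply(state_edges, function(df) weight_of(df))
  score_node <- function(node, type) {
    partner_key <- function(partner)
      if (type == "genus") paste(node, partner, sep = "|")
      else paste(partner, node, sep = "|")
    partners <- unique(unlist(lapply(state_edges, function(df)
      if (type == "genus") df$metabolite_id[df$genus == node]
      else df$genus[df$metabolite_id == node])))
    if (!length(partners)) return(NULL)
    W <- vapply(maps, function(mp) {
      w <- mp[partner_key(partners)]
      w[is.na(w)] <- 0
      unname(w)
    }, numeric(length(partners)))
    W <- matrix(W, nrow = length(partners), ncol = S)
    centroid <- rowMeans(W)
    dn <- mean(sqrt(colSums((W - centroid)^2)))
    data.frame(node_id = node, node_type = type, dn = dn,
               union_degree = length(partners),
               degree_corrected_dn = dn / length(partners),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(sort(genera), score_node, type = "genus")),
    do.call(rbind, lapply(sort(mets), score_node, type = "metabolite")))
  out <- out[order(-out$dn, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
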