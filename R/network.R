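#' Spearman correlation with small-sample exact p-value
#'
#' Rho is the Pearson correlation of average-ranked values (tie-safe). The
#' two-sided p-value uses the t approximation with n - 2 df for n >= 10 and
#' exact permutation enumeration over all n! orderings for n < 10. A
#' constant input vector yields `rho = 0, p = 1` flagged degenerate.
#'
#' @param x,y numeric vectors of equal length (n >= 4), finite values.
#' @return A list with `rho`, `p`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_mm("length mismatch")
  n <- length(x)
  if (n < 4) stop_mm("spearman_cor needs n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_mm("spearman_cor requires finite values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = 0, p = 1, n = n, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n < 10) spearman_exact_p(rx, ry, rho) else spearman_t_p(rho, n)
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), n - 2)
}

# exact two-sided permutation p over all n! orderings of y
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  P <- all_permutations(n)
  s <- as.vector(matrix(ry[P], nrow(P), n) %*% rx)
  mu <- n * mean(rx) * mean(ry)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_all <- (s - mu) / denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# vectorised Spearman of every row of X against every row of Y over the
# given samples; returns rho / p / degenerate matrices
spearman_matrix <- function(X, Y) {
  n <- ncol(X)
  rx <- t(apply(X, 1, rank)); ry <- t(apply(Y, 1, rank))
  degx <- apply(X, 1, function(r) length(unique(r)) == 1L)
  degy <- apply(Y, 1, function(r) length(unique(r)) == 1L)
  sx <- (rx - rowMeans(rx)) / sqrt(rowSums((rx - rowMeans(rx))^2))
  sy <- (ry - rowMeans(ry)) / sqrt(rowSums((ry - rowMeans(ry))^2))
  rho <- tcrossprod(sx, sy)
  rho[] <- pmin(pmax(rho, -1), 1)
  if (n >= 10) {
    p <- matrix(spearman_t_p(0, n), nrow(X), nrow(Y))
    p[] <- vapply(as.vector(rho), spearman_t_p, 0, n = n)
  } else {
    p <- matrix(NA_real_, nrow(X), nrow(Y))
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
      p[i, j] <- spearman_exact_p(rx[i, ], ry[j, ], rho[i, j])
  }
  deg <- outer(degx, degy, `|`)
  rho[deg] <- 0; p[deg] <- 1
  dimnames(rho) <- dimnames(p) <- dimnames(deg) <-
    list(rownames(X), rownames(Y))
  list(rho = rho, p = p, degenerate = deg)
}

#' Build per-cohort taxon-metabolite Spearman association networks
#'
#' For each cohort independently, correlates every taxon against every
#' metabolite on that cohort's samples, applies Benjamini-Hochberg
#' correction across all pairs of the cohort (degenerate, i.e. constant,
#' pairs are excluded from the family), and retains edges passing
#' `q <= fdr_alpha` and `|rho| >= r_threshold` (both signs kept).
#'
#' @param taxa ASV- or genus-level abundance [feature_table()].
#' @param metabolites imputed metabolite [feature_table()] (rank-based, so
#'   the unlogged scale is used).
#' @param design design data frame (see [read_design()]).
#' @param cfg an [analysis_config()]; `cfg$bh_family = "global"` pools all
#'   cohorts into one BH family.
#' @param taxonomy optional taxonomy data frame used to annotate each edge
#'   with its genus; when absent the taxon id doubles as the genus label
#'   (appropriate for genus-level input).
#' @return A `correlation_networks` list: `results` (full unfiltered table:
#'   cohort, taxon_id, genus, metabolite_id, rho, p, q, n_samples,
#'   degenerate), `networks` (per cohort: list with `cohort`, `edges`,
#'   `taxa`, `metabolites`), and `cfg`.
#' @export
build_networks <- function(taxa, metabolites, design, cfg = analysis_config(),
                           taxonomy = NULL) {
  common <- intersect(colnames(taxa), colnames(metabolites))
  des <- des_align(design, common)
  tx <- ft_values(ft_align(taxa, common))
  mt <- ft_values(ft_align(metabolites, common))
  if (anyNA(mt))
    stop_mm("metabolite table has missing values; run condition_metabolites() first")
  genus_of <- if (!is.null(taxonomy)) {
    stats::setNames(genus_labels(taxonomy), taxonomy$asv_id)[rownames(tx)]
  } else stats::setNames(rownames(tx), rownames(tx))
  results <- NULL
  for (grp in levels(des$group)) {
    idx <- which(des$group == grp)
    if (length(idx) < 4) {
      warning("cohort ", grp, " has fewer than 4 samples; skipped")
      next
    }
    sm <- spearman_matrix(tx[, idx, drop = FALSE], mt[, idx, drop = FALSE])
    df <- expand.grid(taxon_id = rownames(tx), metabolite_id = rownames(mt),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$cohort <- grp
    df$genus <- unname(genus_of[df$taxon_id])
    df$rho <- sm$rho[cbind(df$taxon_id, df$metabolite_id)]
    df$p <- sm$p[cbind(df$taxon_id, df$metabolite_id)]
    df$degenerate <- sm$degenerate[cbind(df$taxon_id, df$metabolite_id)]
    df$n_samples <- length(idx)
    results <- rbind(results, df)
  }
  if (is.null(results)) stop_mm("no cohort had >= 4 samples")
  results$q <- NA_real_
  if (cfg$bh_family == "per_cohort") {
    for (grp in unique(results$cohort)) {
      fam <- results$cohort == grp & !results$degenerate
      results$q[fam] <- bh_adjust(results$p[fam])
    }
  } else {
    fam <- !results$degenerate
    results$q[fam] <- bh_adjust(results$p[fam])
  }
  results <- results[, c("cohort", "taxon_id", "genus", "metabolite_id",
                         "rho", "p", "q", "n_samples", "degenerate")]
  networks <- lapply(unique(results$cohort), function(grp) {
    sub <- results[results$cohort == grp & !results$degenerate &
                     !is.na(results$q) & results$q <= cfg$fdr_alpha &
                     abs(results$rho) >= cfg$r_threshold, , drop = FALSE]
    rownames(sub) <- NULL
    list(cohort = grp, edges = sub,
         taxa = unique(sub$taxon_id), metabolites = unique(sub$metabolite_id))
  })
  names(networks) <- unique(results$cohort)
  structure(list(results = results, networks = networks, cfg = cfg),
            class = "correlation_networks")
}

#' @export
print.correlation_networks <- function(x, ...) {
  for (nw in x$networks)
    cat(sprintf("%s: %d edges (%d taxa, %d metabolites)\n", nw$cohort,
                nrow(nw$edges), length(nw$taxa), length(nw$metabolites)))
  invisible(x)
}

#' Strong-positive edge subset
#'
#' Edges with `rho >= r_threshold` (positive sign only), the subset used by
#' the cross-cohort Venn, per-genus tallies and enrichment queries.
#'
#' @param edges an edge data frame (from `build_networks()$networks`).
#' @param r_threshold positive magnitude threshold.
#' @return The filtered edge data frame.
#' @export
strong_positive <- function(edges, r_threshold = 0.5) {
  edges[edges$rho >= r_threshold, , drop = FALSE]
}

#' Collapse an edge set to genus level
#'
#' Regroups edges by (cohort, genus, metabolite), retaining the per-ASV rho
#' values of each group and their median.
#'
#' @param edges edge data frame with `cohort`, `genus`, `metabolite_id`,
#'   `rho` columns.
#' @return Data frame: `cohort`, `genus`, `metabolite_id`, `n_asvs`,
#'   `median_rho`, and a list column `rhos`.
#' @export
collapse_to_genus <- function(edges) {
  if (!nrow(edges))
    return(data.frame(cohort = character(), genus = character(),
                      metabolite_id = character(), n_asvs = integer(),
                      median_rho = double()))
  key <- interaction(edges$cohort, edges$genus, edges$metabolite_id, drop = TRUE)
  parts <- split(edges, key)
  out <- do.call(rbind, lapply(parts, function(s)
    data.frame(cohort = s$cohort[1], genus = s$genus[1],
               metabolite_id = s$metabolite_id[1], n_asvs = nrow(s),
               median_rho = stats::median(s$rho), stringsAsFactors = FALSE)))
  out$rhos <- I(lapply(parts, function(s) s$rho))
  out <- out[order(out$cohort, out$genus, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cohort shared and unique edge sets (Venn regions)
#'
#' Identifies genus-metabolite edges by `(genus, metabolite_id)` and counts
#' every region of the 2- or 3-set Venn diagram across cohorts, with the
#' member edges of each region.
#'
#' @param edge_sets named list (>= 2 cohorts) of genus-level edge data
#'   frames (columns `genus`, `metabolite_id`) or of character keys
#'   `"genus|metabolite"`.
#' @return A list with `counts` (data frame: `region`, `n`) and `members`
#'   (named list of key vectors). Region names join cohort names with `&`
#'   and suffix `_only` for singletons.
#' @export
cross_state_sets <- function(edge_sets) {
  if (length(edge_sets) < 2) stop_mm("cross_state_sets needs >= 2 cohorts")
  keys <- lapply(edge_sets, function(s) {
    if (is.data.frame(s)) unique(paste(s$genus, s$metabolite_id, sep = "|"))
    else unique(as.character(s))
  })
  states <- names(keys)
  if (is.null(states) || any(!nzchar(states)))
    stop_mm("edge_sets must be a named list")
  universe <- unique(unlist(keys))
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, states))
  subsets <- unlist(lapply(seq_along(states), function(k)
    utils::combn(states, k, simplify = FALSE)), recursive = FALSE)
  counts <- data.frame(region = character(), n = integer())
  members <- list()
  for (ss in subsets) {
    inside <- rowSums(membership[, ss, drop = FALSE]) == length(ss) &
      rowSums(membership[, setdiff(states, ss), drop = FALSE]) == 0
    region <- if (length(ss) == 1) paste0(ss, "_only") else paste(ss, collapse = "&")
    counts <- rbind(counts, data.frame(region = region, n = sum(inside)))
    members[[region]] <- universe[inside]
  }
  list(counts = counts, members = members)
}

#' Rank genera by association count and cross-state variability
#'
#' Per genus: the number of distinct strongly associated metabolites in
#' each state, and a variability score — the number of metabolites in the
#' union that are not shared by all states in which the genus appears
#' (sharing requires presence in at least two states; a genus seen in a
#' single state contributes all its metabolites). Rankings are descending
#' with lexicographic tie-breaks.
#'
#' @param edge_sets named list of genus-level edge data frames per state
#'   (columns `genus`, `metabolite_id`).
#' @return Data frame: `genus`, one `n_<state>` column per state,
#'   `n_union`, `variability`, sorted by decreasing variability then genus.
#' @export
variable_genera <- function(edge_sets) {
  states <- names(edge_sets)
  genera <- sort(unique(unlist(lapply(edge_sets, `[[`, "genus"))))
  rows <- lapply(genera, function(g) {
    sets <- lapply(edge_sets, function(s)
      unique(s$metabolite_id[s$genus == g]))
    present <- names(sets)[lengths(sets) > 0]
    uni <- unique(unlist(sets))
    shared <- if (length(present) >= 2)
      Reduce(intersect, sets[present]) else character(0)
    row <- data.frame(genus = g, stringsAsFactors = FALSE)
    for (st in states) row[[paste0("n_", st)]] <- length(sets[[st]])
    row$n_union <- length(uni)
    row$variability <- length(setdiff(uni, shared))
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$variability, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
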