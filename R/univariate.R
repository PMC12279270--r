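#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-square (k - 1 df) p-value, via
#' [stats::kruskal.test()]. When every observation is identical the tie
#' correction degenerates; the test is then reported as `H = 0, p = 1`
#' (no separation).
#'
#' @param groups a list of numeric vectors (one per group, each non-empty,
#'   total n >= 5).
#' @return A list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_mm("kruskal_wallis needs >= 2 groups")
  if (any(!lengths(groups))) stop_mm("kruskal_wallis: empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 5) stop_mm("kruskal_wallis needs total n >= 5")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, clipped to 1 and mapped back to the
#' input order (the step-up FDR rule), via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; NA entries are
#'   passed through and do not count toward the family size.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  nna <- !is.na(p_values)
  if (any(p_values[nna] < 0 | p_values[nna] > 1))
    stop_mm("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[nna] <- stats::p.adjust(p_values[nna], method = "BH")
  out
}

#' Rank-based group comparisons for a panel of features
#'
#' For each feature (row): a Kruskal-Wallis omnibus p across the three
#' cohorts, then the pairwise contrasts HCvsCD, HCvsUC, CDvsUC via the
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction, no continuity correction). Benjamini-Hochberg correction is
#' applied across features within each contrast (the default, mirroring how
#' per-feature q-values are reported next to an omnibus p in figure
#' panels), or across the three contrasts within each feature when
#' `cfg$univariate_family = "within_feature"`.
#'
#' Contrasts where either cohort has fewer than 3 samples are reported as
#' missing.
#'
#' @param features numeric matrix or [feature_table()], features x samples.
#' @param design design data frame (see [read_design()]) covering the
#'   samples.
#' @param cfg an [analysis_config()].
#' @return Data frame with `feature_id`, `omnibus_p`, per-contrast
#'   `stat/p/q` columns, and `significant` (any contrast q below
#'   `cfg$q_significance`).
#' @export
univariate_table <- function(features, design, cfg = analysis_config()) {
  v <- if (inherits(features, "feature_table")) ft_values(features) else features
  des <- des_align(design, colnames(v))
  grp <- as.character(des$group)
  contrasts <- list(HCvsCD = c("HC", "CD"), HCvsUC = c("HC", "UC"),
                    CDvsUC = c("CD", "UC"))
  res <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE)
  res$omnibus_p <- apply(v, 1, function(x) {
    keep <- !is.na(x)
    gl <- split(x[keep], grp[keep])
    gl <- gl[lengths(gl) > 0]
    if (length(gl) < 2) return(NA_real_)
    kruskal_wallis(gl)$p
  })
  for (cn in names(contrasts)) {
    pair <- contrasts[[cn]]
    stat <- p <- rep(NA_real_, nrow(v))
    for (i in seq_len(nrow(v))) {
      x <- v[i, grp == pair[1]]; y <- v[i, grp == pair[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 3 || length(y) < 3) next
      if (length(unique(c(x, y))) == 1L) { stat[i] <- length(x) * length(y) / 2; p[i] <- 1; next }
      wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
      stat[i] <- unname(wt$statistic); p[i] <- wt$p.value
    }
    res[[paste0(cn, "_stat")]] <- stat
    res[[paste0(cn, "_p")]] <- p
  }
  pcols <- paste0(names(contrasts), "_p")
  if (cfg$univariate_family == "across_features") {
    for (cn in names(contrasts))
      res[[paste0(cn, "_q")]] <- bh_adjust(res[[paste0(cn, "_p")]])
  } else {
    qm <- t(apply(as.matrix(res[, pcols]), 1, bh_adjust))
    for (k in seq_along(contrasts))
      res[[paste0(names(contrasts)[k], "_q")]] <- qm[, k]
  }
  qcols <- paste0(names(contrasts), "_q")
  res$significant <- apply(res[, qcols] < cfg$q_significance, 1, any, na.rm = TRUE)
  # stable column order: feature, omnibus, then stat/p/q per contrast
  ord <- c("feature_id", "omnibus_p",
           unlist(lapply(names(contrasts), function(cn)
             paste0(cn, c("_stat", "_p", "_q")))), "significant")
  res[, ord]
}
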