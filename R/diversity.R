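#' Per-sample alpha diversity panel
#'
#' Computes Shannon entropy (natural log), inverse Simpson, the classic
#' Chao1 richness estimator, and (when a tree is supplied) Faith's
#' phylogenetic diversity including the path to the root.
#'
#' Chao1 follows the classic form `S_obs + F1^2 / (2 F2)` (F1 singletons,
#' F2 doubletons), with the term 0 when `F1 = 0` and the bias form
#' `S_obs + F1 (F1 - 1) / 2` when `F2 = 0`.
#'
#' @param counts an integer `asv_counts` [feature_table()].
#' @param tree optional rooted `phylo` covering all observed ASVs
#'   (required for Faith PD).
#' @return Data frame with columns `sample_id`, `shannon`, `inv_simpson`,
#'   `chao1`, and `faith_pd` (NA when no tree). Empty samples yield NA with
#'   a warning.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  v <- ft_values(counts)
  if (any(v != round(v))) stop_mm("alpha_diversity expects integer counts")
  empty <- colSums(v) == 0
  if (any(empty))
    warning("empty samples reported as NA: ",
            paste(colnames(v)[empty], collapse = ", "))
  comm <- t(v)  # samples x taxa, as the ecology packages expect
  shannon <- vegan::diversity(comm, index = "shannon")
  invsimp <- vegan::diversity(comm, index = "invsimpson")
  chao1 <- apply(v, 2, chao1_classic)
  fpd <- rep(NA_real_, ncol(v))
  if (!is.null(tree)) {
    missing_tips <- setdiff(rownames(v), tree$tip.label)
    if (length(missing_tips))
      stop_mm("tree does not cover ASVs: ", paste(missing_tips, collapse = ", "))
    pd <- picante::pd(comm, tree, include.root = TRUE)
    fpd <- pd$PD
  }
  out <- data.frame(sample_id = colnames(v), shannon = unname(shannon),
                    inv_simpson = unname(invsimp), chao1 = unname(chao1),
                    faith_pd = fpd, row.names = NULL, stringsAsFactors = FALSE)
  out[empty, c("shannon", "inv_simpson", "chao1", "faith_pd")] <- NA_real_
  out
}

chao1_classic <- function(x) {
  x <- x[x > 0]
  s <- length(x)
  if (!s) return(NA_real_)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(s)
  if (f2 == 0) return(s + f1 * (f1 - 1) / 2)
  s + f1^2 / (2 * f2)
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed sample vectors.
#'
#' @param clr a `clr_values` [feature_table()] (see [clr_transform()]).
#' @return A `dist` object over samples.
#' @export
aitchison_distance <- function(clr) {
  if (!identical(ft_kind(clr), "clr_values"))
    stop_mm("aitchison_distance expects a clr_values table")
  stats::dist(t(ft_values(clr)), method = "euclidean")
}

#' Ordinate a distance matrix
#'
#' `pcoa` performs classical scaling of the Gower-centered matrix with axes
#' ordered by eigenvalue (the default, matching principal-coordinate plots
#' of Aitchison distances). `nmds` runs iterative stress minimisation
#' (Kruskal's non-metric MDS) initialised from the PCoA solution, so the
#' result is deterministic.
#'
#' @param dm a `dist` or square symmetric matrix.
#' @param method `"pcoa"` or `"nmds"`.
#' @param k number of dimensions (>= 2).
#' @return A list with `points` (n x k), `method`, plus `eig_fractions`
#'   (PCoA: positive-eigenvalue fractions) or `stress` (NMDS, percent).
#' @export
ordinate <- function(dm, method = c("pcoa", "nmds"), k = 2) {
  method <- match.arg(method)
  m <- as.matrix(dm)
  if (k < 2) stop_mm("k must be >= 2")
  dec <- gower_eigen(m)
  npos <- sum(dec$values > max(dec$values) * 1e-8)
  if (k > npos) {
    warning("k exceeds the rank of the configuration; truncated to ", npos)
    k <- npos
  }
  pts <- dec$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(dec$values[seq_len(k)]), k)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("Axis", seq_len(k))
  if (method == "pcoa") {
    pos <- dec$values[dec$values > 0]
    return(list(points = pts, method = "pcoa",
                eig_fractions = dec$values[seq_len(k)] / sum(pos)))
  }
  fit <- MASS::isoMDS(stats::as.dist(m), y = pts, k = k, trace = FALSE)
  rownames(fit$points) <- rownames(m)
  list(points = fit$points, method = "nmds", stress = fit$stress)
}

# eigen-decomposition of the Gower-centered squared-distance matrix
gower_eigen <- function(m) {
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * 1e-10
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE],
       all_values = e$values)
}

# distance-based sums of squares partition; returns pseudo-F
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# all distinct assignments of labels to positions, as a matrix of label
# indices (rows = assignments); counts multiplicity once
label_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) {
      m <- matrix(avail, nrow = 1)
      return(list(m))
    }
    picks <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) cbind(matrix(p, nrow = 1), r)))
    }
    out
  }
  parts <- rec(seq_len(n), sizes)
  # convert "which samples got which label" into per-sample label vectors
  t(vapply(parts, function(p) {
    lab <- integer(n)
    at <- 1L
    for (k in seq_along(sizes)) {
      lab[p[at:(at + sizes[k] - 1L)]] <- k
      at <- at + sizes[k]
    }
    lab
  }, integer(n)))
}

n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared inter-sample distances into between- and
#' within-group sums of squares and forms the pseudo-F statistic
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value comes
#' from label permutation with the add-one convention; when the number of
#' distinct label assignments is at most `10 * n_permutations` the complete
#' enumeration is used instead and the p-value is exact.
#'
#' @param dm a `dist` or square symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations permutation count for the sampled test.
#' @param seed integer seed, recorded in the result.
#' @return A `permutation_test` list: `statistic`, `p_value`,
#'   `n_permutations` (actual draws or enumeration size), `seed`, `method`,
#'   `exact`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  m <- as.matrix(dm)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop_mm("permanova needs >= 2 groups")
  if (any(sizes < 2)) stop_mm("every group needs >= 2 samples")
  d2 <- m^2
  f_obs <- permanova_f(d2, groups)
  total <- n_assignments(as.integer(sizes))
  if (total <= 10 * n_permutations) {
    labs <- sort(unique(groups))
    assign <- label_assignments(as.integer(sizes[labs]))
    f_all <- apply(assign, 1, function(lab) permanova_f(d2, lab))
    p <- mean(f_all >= f_obs - 1e-12)
    res <- list(statistic = f_obs, p_value = p,
                n_permutations = nrow(assign), seed = seed,
                method = "permanova", exact = TRUE)
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(i)
        permanova_f(d2, sample(groups)) >= f_obs - 1e-12, logical(1)))
    })
    res <- list(statistic = f_obs,
                p_value = (1 + count) / (1 + n_permutations),
                n_permutations = n_permutations, seed = seed,
                method = "permanova", exact = FALSE)
  }
  class(res) <- "permutation_test"
  res
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s: F = %.4f, p = %.4g (%s, %d permutations, seed %d)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "complete enumeration" else "sampled",
              x$n_permutations, x$seed))
  invisible(x)
}

dispersion_f <- function(pts, groups) {
  d <- centroid_distances(pts, groups)
  a <- length(unique(groups)); n <- length(d)
  gm <- mean(d)
  ssb <- sum(tapply(d, groups, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(d, groups, function(z) sum((z - mean(z))^2)))
  if (ssw <= 1e-14 && ssb <= 1e-14) return(0)
  (ssb / (a - 1)) / (ssw / (n - a))
}

centroid_distances <- function(pts, groups) {
  d <- numeric(nrow(pts))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cen <- colMeans(pts[idx, , drop = FALSE])
    d[idx] <- sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, cen)^2))
  }
  d
}

#' Multivariate dispersion homogeneity test
#'
#' Embeds the samples by principal coordinates (all real axes), computes
#' each sample's distance to its group centroid, and tests equality of
#' dispersions with a one-way F statistic whose null distribution is
#' obtained by permuting group labels (add-one convention; distances to the
#' permuted-group centroids are recomputed for every permutation).
#'
#' @inheritParams permanova
#' @return A `permutation_test` list (see [permanova()]).
#' @export
dispersion_test <- function(dm, groups, n_permutations = 999, seed = 1L) {
  m <- as.matrix(dm)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop_mm("dispersion_test needs >= 2 groups")
  if (any(sizes < 2)) stop_mm("every group needs >= 2 samples")
  dec <- gower_eigen(m)
  pts <- dec$vectors %*% diag(sqrt(dec$values), length(dec$values))
  f_obs <- dispersion_f(pts, groups)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i)
      dispersion_f(pts, sample(groups)) >= f_obs - 1e-12, logical(1)))
  })
  res <- list(statistic = f_obs,
              p_value = (1 + count) / (1 + n_permutations),
              n_permutations = n_permutations, seed = seed,
              method = "dispersion", exact = FALSE)
  class(res) <- "permutation_test"
  res
}
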