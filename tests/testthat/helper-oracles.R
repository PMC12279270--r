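# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: permutations are generated recursively, statistics are
# computed from their textbook definitions with explicit loops.

perms_rec <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_rec(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

bf_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

bf_spearman_exact_p <- function(x, y) {
  rho_obs <- bf_spearman_rho(x, y)
  all_y <- perms_rec(y)
  rhos <- vapply(all_y, function(yy) bf_spearman_rho(x, yy), 0)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[o[j]] / j)
    q[o[i]] <- min(cand, 1)
  }
  q
}

bf_kruskal_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(z) sum(z)^2 / length(z))) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / corr
}

# upper-tail hypergeometric p by enumerating every possible draw of n items
# from a background of N (first K of which are pathway members)
bf_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

bf_permanova_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- length(unique(groups))
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + d[idx[i], idx[j]]^2
    ssw <- ssw + s / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

bf_permanova_p <- function(d, groups) {
  f_obs <- bf_permanova_f(d, groups)
  all_labs <- unique(perms_rec(groups))
  fs <- vapply(all_labs, function(lab) bf_permanova_f(d, lab), 0)
  mean(fs >= f_obs - 1e-12)
}

# rewiring Dn from its definition, looping over partner/state combinations
bf_dn <- function(state_edges, node, type) {
  states <- names(state_edges)
  partners <- character()
  for (s in states) {
    df <- state_edges[[s]]
    partners <- union(partners, if (type == "genus")
      df$metabolite_id[df$genus == node] else df$genus[df$metabolite_id == node])
  }
  if (!length(partners)) return(NULL)
  wcol <- intersect(c("median_rho", "rho", "weight"), names(state_edges[[1]]))[1]
  W <- matrix(0, length(partners), length(states),
              dimnames = list(partners, states))
  for (s in states) {
    df <- state_edges[[s]]
    for (r in seq_len(nrow(df))) {
      if (type == "genus" && df$genus[r] == node)
        W[df$metabolite_id[r], s] <- df[[wcol]][r]
      if (type == "metabolite" && df$metabolite_id[r] == node)
        W[df$genus[r], s] <- df[[wcol]][r]
    }
  }
  cen <- rowMeans(W)
  mean(apply(W, 2, function(w) sqrt(sum((w - cen)^2))))
}
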