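test_that("alpha diversity matches closed forms", {
  cnt <- feature_table(matrix(c(5, 5, 5, 5,
                                5, 3, 1, 1), ncol = 2,
                              dimnames = list(LETTERS[1:4], c("u", "v"))),
                       "asv_counts")
  a <- alpha_diversity(cnt)
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$inv_simpson[1], 4)
  # Chao1 on (5,3,1,1,2): S=5, F1=2, F2=1 -> 7
  cnt2 <- feature_table(matrix(c(5, 3, 1, 1, 2), 5, 1,
                               dimnames = list(letters[1:5], "w")),
                        "asv_counts")
  expect_equal(alpha_diversity(cnt2)$chao1, 7)
  # F2 = 0 bias fallback: (4,1,1,1): S=4, F1=3 -> 4 + 3*2/2 = 7
  cnt3 <- feature_table(matrix(c(4, 1, 1, 1), 4, 1,
                               dimnames = list(letters[1:4], "w")),
                        "asv_counts")
  expect_equal(alpha_diversity(cnt3)$chao1, 7)
  # no singletons -> Chao1 = S_obs
  cnt4 <- feature_table(matrix(c(4, 2, 2), 3, 1,
                               dimnames = list(letters[1:3], "w")),
                        "asv_counts")
  expect_equal(alpha_diversity(cnt4)$chao1, 3)
})

test_that("Faith PD spans observed leaves to the root and grows monotonically", {
  tree <- ape::read.tree(text = toy_tree_text)
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 1, 0,
                1, 1, 1, 1), ncol = 3,
              dimnames = list(c("A", "B", "C", "D"), c("ab", "abc", "abcd")))
  a <- alpha_diversity(feature_table(m, "asv_counts"), tree = tree)
  expect_equal(a$faith_pd[a$sample_id == "ab"], 3)
  pd <- a$faith_pd[match(c("ab", "abc", "abcd"), a$sample_id)]
  expect_true(all(diff(pd) >= 0))
  # tree not covering the data is an error
  m2 <- rbind(m, E = 1)
  expect_error(alpha_diversity(feature_table(m2, "asv_counts"), tree = tree),
               "does not cover")
})

test_that("empty samples are reported missing, with a warning", {
  m <- matrix(c(3, 2, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("full", "none")))
  expect_warning(a <- alpha_diversity(feature_table(m, "asv_counts")), "empty")
  expect_true(all(is.na(unlist(a[a$sample_id == "none",
                                 c("shannon", "inv_simpson", "chao1")]))))
})

test_that("Aitchison distance is Euclidean on CLR vectors", {
  clr <- feature_table(matrix(c(0, 0, 3, 4), 2, 2,
                              dimnames = list(c("f1", "f2"), c("s1", "s2"))),
                       "clr_values")
  expect_equal(as.numeric(aitchison_distance(clr)), 5)
  set.seed(6)
  m <- matrix(rnorm(40), 4, 10)
  m <- sweep(m, 2, colMeans(m))
  dimnames(m) <- list(paste0("f", 1:4), paste0("s", 1:10))
  dm <- as.matrix(aitchison_distance(feature_table(m, "clr_values")))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(dm[i, j], sqrt(sum((m[, i] - m[, j])^2)))
  # identical samples at distance zero
  m[, 2] <- m[, 1]
  dm2 <- as.matrix(aitchison_distance(feature_table(m, "clr_values")))
  expect_equal(dm2["s1", "s2"], 0)
})

test_that("PCoA reproduces Euclidean geometry; NMDS runs from that start", {
  set.seed(10)
  x <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  dm <- dist(x)
  ord <- ordinate(dm, "pcoa", k = 3)
  expect_equal(as.matrix(dist(ord$points)), as.matrix(dm), tolerance = 1e-8)
  # three collinear points: axis 1 recovers spacing, axis 2 carries ~nothing
  line <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(paste0("s", 1:3), NULL))
  expect_warning(o2 <- ordinate(dist(line), "pcoa", k = 2), "rank")
  expect_equal(unname(sort(abs(diff(sort(o2$points[, 1]))))), c(1, 2),
               tolerance = 1e-8)
  # duplicate samples get coincident coordinates
  dup <- rbind(x, s7 = x[1, ])
  o3 <- ordinate(dist(dup), "pcoa", k = 2)
  expect_equal(o3$points["s7", ], o3$points["s1", ], tolerance = 1e-8)
  # NMDS returns a stress value and is deterministic
  n1 <- ordinate(dm, "nmds", k = 2)
  n2 <- ordinate(dm, "nmds", k = 2)
  expect_identical(n1$points, n2$points)
  expect_true(is.finite(n1$stress))
})

test_that("PERMANOVA matches the constructed example and brute-force enumeration", {
  # 4 samples, within-pair distance 0.2, across 1: F = 49, exact p = 2/6
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 0.2; dm[3, 4] <- dm[4, 3] <- 0.2
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  res <- permanova(dm, c("A", "A", "B", "B"))
  expect_equal(res$statistic, 49)
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 6)
  # relabelling groups leaves F and p unchanged
  res2 <- permanova(dm, c("B", "B", "A", "A"))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p_value, res$p_value)

  # enumeration equals an independent brute force over all label orderings
  set.seed(12)
  for (rep in 1:3) {
    x <- matrix(rnorm(7 * 2), 7, 2, dimnames = list(paste0("s", 1:7), NULL))
    dmr <- dist(x)
    groups <- c("A", "A", "A", "B", "B", "C", "C")
    mine <- permanova(dmr, groups)
    expect_true(mine$exact)
    expect_equal(mine$statistic, bf_permanova_f(dmr, groups), tolerance = 1e-10)
    expect_equal(mine$p_value, bf_permanova_p(dmr, groups), tolerance = 1e-10)
  }
})

test_that("PERMANOVA pseudo-F agrees with the vegan reference implementation", {
  set.seed(13)
  x <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(paste0("s", 1:12), NULL))
  dm <- dist(x)
  groups <- rep(c("A", "B", "C"), each = 4)
  mine <- permanova(dm, groups, n_permutations = 199, seed = 2)
  ref <- vegan::adonis2(dm ~ g, data = data.frame(g = groups), permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
})

test_that("dispersion test separates constructed contrasts and not symmetric ones", {
  set.seed(14)
  # equal internal geometry in both groups -> F ~ 0, p ~ 1
  base <- matrix(rnorm(10 * 2), 10, 2)
  sym <- rbind(base, base + 100)  # same shape, far apart
  rownames(sym) <- paste0("s", 1:20)
  g <- rep(c("A", "B"), each = 10)
  res <- dispersion_test(dist(sym), g, n_permutations = 199, seed = 3)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.9)
  # one tight and one spread group -> large F, small p
  spread <- rbind(base * 0.05, base * 4)
  rownames(spread) <- paste0("s", 1:20)
  res2 <- dispersion_test(dist(spread), g, n_permutations = 199, seed = 3)
  expect_gt(res2$statistic, 10)
  expect_lt(res2$p_value, 0.05)
  # F invariant to relabelling
  res3 <- dispersion_test(dist(spread), rev(g), n_permutations = 99, seed = 3)
  expect_equal(res3$statistic, res2$statistic)
})

test_that("dispersion F agrees with vegan betadisper on a Euclidean matrix", {
  set.seed(15)
  x <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(paste0("s", 1:15), NULL))
  g <- rep(c("A", "B", "C"), each = 5)
  mine <- dispersion_test(dist(x), g, n_permutations = 99, seed = 1)
  bd <- vegan::betadisper(dist(x), g, type = "centroid")
  ref <- anova(bd)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-8)
})
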