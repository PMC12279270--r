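test_that("spearman_cor handles the canonical examples", {
  x <- c(3, 1, 4, 1.5, 9)
  id <- spearman_cor(x, x)
  expect_equal(id$rho, 1)
  rev <- spearman_cor(x, -x)
  expect_equal(rev$rho, -1)
  ex <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(ex$rho, 0.8)  # 1 - 6*4/(5*24)
  cst <- spearman_cor(rep(2, 6), 1:6)
  expect_true(cst$degenerate)
  expect_equal(cst$rho, 0)
  expect_equal(cst$p, 1)
  expect_error(spearman_cor(1:4, 1:5), "length mismatch")
  expect_error(spearman_cor(1:3, 3:1), "n >= 4")
})

test_that("small-n p-values equal brute-force enumeration over all orderings", {
  set.seed(30)
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
    list(x = rnorm(5), y = rnorm(5)),
    list(x = c(1, 1, 2, 3, 4, 4), y = rnorm(6)),  # ties
    list(x = rnorm(6), y = rnorm(6)))
  for (cs in cases) {
    mine <- spearman_cor(cs$x, cs$y)
    expect_equal(mine$rho, bf_spearman_rho(cs$x, cs$y), tolerance = 1e-12)
    expect_equal(mine$p, bf_spearman_exact_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("large-n p matches the t approximation and cor.test, rho is transform-invariant", {
  set.seed(31)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  mine <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # monotone transform of either argument leaves rho unchanged; reversing
  # one argument's order flips the sign
  tr <- spearman_cor(exp(x), y)
  expect_equal(tr$rho, mine$rho, tolerance = 1e-12)
  fl <- spearman_cor(-x, y)
  expect_equal(fl$rho, -mine$rho, tolerance = 1e-12)
})

test_that("networks recover a planted edge in the right cohort only", {
  cfg <- simulation_config(
    planted_edges = data.frame(genus = "g01", metabolite = "met1",
                               group = "HC", rho = 0.8),
    rng_seed = 103)
  b <- generate_cohort(cfg)
  nets <- micromet:::run_network_stage(b, analysis_config())
  hc <- nets$networks$HC$edges
  expect_true(any(hc$genus == "g01" & hc$metabolite_id == "met1"))
  for (grp in c("CD", "UC")) {
    e <- nets$networks[[grp]]$edges
    expect_false(any(e$genus == "g01" & e$metabolite_id == "met1"))
  }
  # full results table covers every pair per cohort, with per-cohort BH
  expect_identical(nrow(nets$results),
                   3L * nrow(b$counts) * nrow(b$metabolites))
  for (grp in c("HC", "CD", "UC")) {
    sub <- nets$results[nets$results$cohort == grp & !nets$results$degenerate, ]
    expect_equal(sub$q, bf_bh(sub$p), tolerance = 1e-12)
  }
})

test_that("the magnitude threshold behaves at its extreme", {
  b <- generate_cohort(simulation_config(rng_seed = 44))
  nets <- micromet:::run_network_stage(
    b, analysis_config(r_threshold = 1.0))
  # only perfectly monotone pairs could survive; none exist here
  expect_identical(sum(vapply(nets$networks, function(n) nrow(n$edges), 1L)), 0L)
})

test_that("genus collapse groups edges and keeps per-ASV rho lists", {
  edges <- data.frame(
    cohort = "HC",
    taxon_id = c("a1", "a2", "a3"),
    genus = c("g1", "g1", "g2"),
    metabolite_id = c("m1", "m1", "m2"),
    rho = c(0.6, 0.8, 0.55), p = 0.01, q = 0.02)
  col <- collapse_to_genus(edges)
  expect_identical(nrow(col), 2L)
  g1 <- col[col$genus == "g1", ]
  expect_identical(g1$n_asvs, 2L)
  expect_equal(sort(g1$rhos[[1]]), c(0.6, 0.8))
  expect_equal(g1$median_rho, 0.7)
  # edges in distinct genera stay distinct
  solo <- edges[c(1, 3), ]
  expect_identical(nrow(collapse_to_genus(solo)), 2L)
  # per-genus distinct-metabolite tallies equal a brute-force count
  set.seed(32)
  re <- random_edges(60, seed = 9); re <- re[re$cohort == "HC", ]
  col2 <- collapse_to_genus(re)
  for (g in unique(col2$genus))
    expect_identical(sum(col2$genus == g),
                     length(unique(re$metabolite_id[re$genus == g])))
})

test_that("cross-state Venn regions enumerate correctly and sum to the union", {
  sets <- list(HC = c("a", "b", "c"), CD = c("b", "d"), UC = "b")
  v <- cross_state_sets(sets)
  cnt <- setNames(v$counts$n, v$counts$region)
  expect_equal(unname(cnt["HC_only"]), 2)
  expect_equal(unname(cnt["CD_only"]), 1)
  expect_equal(unname(cnt["UC_only"]), 0)
  expect_equal(unname(cnt["HC&CD&UC"]), 1)
  expect_equal(sum(v$counts$n), length(unique(unlist(sets))))
  # identical sets fall entirely in the triple region
  same <- cross_state_sets(list(HC = c("x", "y"), CD = c("x", "y"), UC = c("x", "y")))
  expect_equal(setNames(same$counts$n, same$counts$region)[["HC&CD&UC"]], 2)
  expect_equal(sum(same$counts$n), 2)
  # disjoint sets only populate the _only regions
  disj <- cross_state_sets(list(HC = "x", CD = "y", UC = "z"))
  cntd <- setNames(disj$counts$n, disj$counts$region)
  expect_equal(unname(cntd[c("HC_only", "CD_only", "UC_only")]), c(1, 1, 1))
  expect_equal(sum(cntd), 3)
})

test_that("variability ranks genera by unshared metabolites", {
  mk <- function(g, m) data.frame(genus = g, metabolite_id = m)
  sets <- list(HC = mk("gA", c("m1", "m2")), CD = mk("gA", c("m2", "m3")),
               UC = mk("gB", c("m7", "m8", "m9")))
  vg <- variable_genera(sets)
  expect_equal(vg$variability[vg$genus == "gA"], 2)   # m1, m3 unshared
  expect_equal(vg$variability[vg$genus == "gB"], 3)   # single state: all count
  # identical across all states -> variability 0
  sets2 <- list(HC = mk("gC", "m1"), CD = mk("gC", "m1"), UC = mk("gC", "m1"))
  expect_equal(variable_genera(sets2)$variability, 0)
  # ranking is descending with lexicographic ties
  expect_identical(vg$genus, c("gB", "gA"))
})
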