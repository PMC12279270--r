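test_that("absolute-abundance transform rescales to biomass and conserves zeros", {
  cnt <- feature_table(matrix(c(25, 75, 0, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2")),
                              byrow = FALSE),
                       "asv_counts")
  # s2 has zero library size -> error
  bio <- toy_biomass(c("s1", "s2"))
  expect_error(to_absolute(cnt, bio), "zero library size")

  cnt <- feature_table(matrix(c(25, 75, 10, 30), 2, 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))),
                       "asv_counts")
  abs <- to_absolute(cnt, bio)
  expect_equal(abs["a", "s1"], 25 / 100 * 1e9)  # 2.5e8
  expect_identical(ft_kind(abs), "absolute_abundance")

  # conservation oracle on random input: column sums equal biomass exactly
  set.seed(8)
  m <- matrix(rpois(60, 20) + 1, 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  ft <- feature_table(m, "asv_counts")
  bio <- data.frame(sample_id = paste0("s", 1:10),
                    total_16s_copies = runif(10, 1e8, 1e10))
  out <- to_absolute(ft, bio)
  expect_equal(unname(colSums(out)), bio$total_16s_copies)
  # an all-zero feature stays all-zero
  m2 <- rbind(m, f7 = 0)
  expect_true(all(to_absolute(feature_table(m2, "asv_counts"), bio)["f7", ] == 0))
  # renormalising recovers the original relative composition exactly
  rel_in <- sweep(m, 2, colSums(m), "/")
  rel_out <- sweep(ft_values(out), 2, colSums(out), "/")
  expect_equal(rel_out, rel_in)
})

test_that("genus aggregation sums members, names pseudo-genera, conserves totals", {
  cnt <- toy_counts()
  tax <- toy_taxonomy()
  agg <- aggregate_genus(cnt, tax)
  expect_equal(unname(agg["g1", ]), unname(cnt["ASV1", ] + cnt["ASV2", ]))
  expect_true("Lachnospiraceae_unclassified" %in% rownames(agg))
  expect_equal(colSums(agg), colSums(cnt))
  expect_error(aggregate_genus(cnt, tax[-1, ]), "absent from taxonomy")

  # aggregation and the absolute transform commute
  bio <- toy_biomass()
  via1 <- aggregate_genus(to_absolute(cnt, bio), tax)
  via2 <- to_absolute(aggregate_genus(cnt, tax), bio)
  expect_equal(ft_values(via1), ft_values(via2))
})

test_that("prevalence filter applies the pooled >= threshold rule and is idempotent", {
  set.seed(2)
  n <- 78
  m <- rbind(common = rpois(n, 5) + 1,
             edge16 = c(rep(1, 16), rep(0, n - 16)),   # 16/78 = 0.205
             edge15 = c(rep(1, 15), rep(0, n - 15)))   # 15/78 = 0.192
  colnames(m) <- paste0("s", 1:n)
  ft <- feature_table(m, "genus_abundance")
  res <- prevalence_filter(ft, 0.20)
  expect_true(res$report$kept[res$report$feature_id == "edge16"])
  expect_false(res$report$kept[res$report$feature_id == "edge15"])
  expect_identical(rownames(res$table), c("common", "edge16"))
  expect_equal(res$report$fraction_present,
               res$report$n_present / n)
  # threshold 0 keeps everything
  expect_identical(nrow(prevalence_filter(ft, 0)$table), 3L)
  # idempotence
  twice <- prevalence_filter(res$table, 0.20)
  expect_identical(ft_values(twice$table), ft_values(res$table))
})

test_that("CLR transform matches closed forms and is zero-sum per sample", {
  eq <- feature_table(matrix(1, 4, 1, dimnames = list(letters[1:4], "s1")),
                      "asv_counts")
  expect_equal(unname(ft_values(clr_transform(eq, 0))), matrix(0, 4, 1))
  two <- feature_table(matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1")),
                       "asv_counts")
  expect_equal(unname(ft_values(clr_transform(two, 0))[, 1]),
               c(-log(sqrt(3)), log(sqrt(3))))
  set.seed(4)
  m <- matrix(rpois(50, 10), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:10)))
  out <- clr_transform(feature_table(m, "asv_counts"), 0.5)
  expect_true(all(abs(colSums(out)) < 1e-9))
  expect_error(clr_transform(feature_table(m * 0, "asv_counts"), 0),
               "pseudocount")
})

test_that("metabolite conditioning half-min imputes and preserves ranks", {
  ft <- feature_table(matrix(c(2, 4, NA), 1, 3,
                             dimnames = list("m1", paste0("s", 1:3))),
                      "metabolite_concentration")
  cm <- condition_metabolites(ft)
  expect_equal(unname(ft_values(cm$imputed)[1, ]), c(2, 4, 1))
  # no missing values -> identity
  full <- feature_table(matrix(1:6, 2, 3,
                               dimnames = list(c("a", "b"), paste0("s", 1:3))) * 1.0,
                        "metabolite_concentration")
  expect_equal(ft_values(condition_metabolites(full)$imputed), ft_values(full))
  # entirely-missing feature dropped with warning
  part <- feature_table(matrix(c(NA, NA, NA, 1, 2, 3), 2, 3, byrow = TRUE,
                               dimnames = list(c("gone", "ok"), paste0("s", 1:3))),
                        "metabolite_concentration")
  expect_warning(out <- condition_metabolites(part), "entirely missing")
  expect_identical(rownames(out$imputed), "ok")
  # Spearman between features is identical before/after logging both
  set.seed(9)
  m <- matrix(rlnorm(40, 3, 1), 4, 10,
              dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  cm2 <- condition_metabolites(feature_table(m, "metabolite_concentration"))
  raw <- ft_values(cm2$imputed); lg <- cm2$logged
  for (i in 1:3)
    expect_equal(cor(raw[i, ], raw[i + 1, ], method = "spearman"),
                 cor(lg[i, ], lg[i + 1, ], method = "spearman"))
})
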