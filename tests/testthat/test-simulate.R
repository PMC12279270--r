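test_that("spearman-to-latent map matches its closed form and is odd/monotone", {
  expect_identical(spearman_to_latent_pearson(0), 0)
  expect_equal(spearman_to_latent_pearson(0.5), 2 * sin(pi / 12))
  expect_equal(spearman_to_latent_pearson(0.5), 0.5176381, tolerance = 1e-6)
  expect_equal(spearman_to_latent_pearson(-0.8), -2 * sin(0.8 * pi / 6))
  expect_equal(spearman_to_latent_pearson(-0.8), -0.8134732, tolerance = 1e-6)
  rho <- seq(-0.99, 0.99, by = 0.01)
  lat <- spearman_to_latent_pearson(rho)
  expect_equal(lat, -rev(lat))            # odd
  expect_true(all(diff(lat) > 0))          # monotone
  expect_true(all(abs(lat) < 1))
  expect_error(spearman_to_latent_pearson(1), "< 1")
  expect_error(spearman_to_latent_pearson(-1.2), "< 1")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(rng_seed = 11)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(ft_values(b1$counts), ft_values(b2$counts))
  expect_identical(ft_values(b1$metabolites), ft_values(b2$metabolites))
  expect_identical(b1$biomass, b2$biomass)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_bundle(b1, d1); p2 <- write_bundle(b2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("planted pairs reach their target Spearman; null pairs stay near zero", {
  # planted 0.8 at n = 60: single-replicate values live in a wide band and
  # the replicate mean sits within +-0.05 of the target
  rhos <- vapply(1:60, function(s) {
    cfg <- simulation_config(
      n_samples = c(HC = 60L, CD = 3L, UC = 3L),
      planted_edges = data.frame(genus = "g01", metabolite = "met1",
                                 group = "HC", rho = 0.8),
      missing_rate = 0, rng_seed = 1000 + s)
    b <- generate_cohort(cfg)
    hc <- b$design$sample_id[b$design$group == "HC"]
    cor(as.numeric(b$counts["ASV001", hc]),
        as.numeric(b$metabolites["met1", hc]), method = "spearman")
  }, 0)
  expect_gte(mean(rhos > 0.65 & rhos < 0.92), 0.9)
  expect_true(mean(rhos) > 0.75 && mean(rhos) < 0.85)

  # null simulation: the designated pair's correlation is centred at zero
  # with roughly 1/(n-1) variance
  null_rhos <- vapply(1:20, function(s) {
    cfg <- simulation_config(planted_edges = NULL, missing_rate = 0,
                             rng_seed = 2000 + s)
    b <- generate_cohort(cfg)
    uc <- b$design$sample_id[b$design$group == "UC"]
    cor(as.numeric(b$counts["ASV001", uc]),
        as.numeric(b$metabolites["met1", uc]), method = "spearman")
  }, 0)
  expect_lt(abs(mean(null_rhos)), 0.12)
  expect_gte(mean(abs(null_rhos) < 0.35), 0.9)
})

test_that("biomass parameters do not touch counts or metabolites", {
  a <- generate_cohort(simulation_config(rng_seed = 5))
  b <- generate_cohort(simulation_config(rng_seed = 5,
                                         biomass_log_mean = log(1e7),
                                         biomass_log_sd = 1.5))
  expect_identical(ft_values(a$counts), ft_values(b$counts))
  expect_identical(ft_values(a$metabolites), ft_values(b$metabolites))
  expect_false(isTRUE(all.equal(a$biomass$total_16s_copies,
                                b$biomass$total_16s_copies)))
  # hence relative-abundance-derived Spearman ranks of taxa are unchanged
  rel <- function(x) sweep(ft_values(x$counts), 2, colSums(x$counts), "/")
  expect_identical(apply(rel(a), 1, rank), apply(rel(b), 1, rank))
})

test_that("infeasible correlation blocks are rejected with the offending edges", {
  # three mutually high correlations on the same metabolite cannot be PD
  pe <- data.frame(genus = c("g01", "g02"), metabolite = c("met1", "met1"),
                   group = "HC", rho = c(0.95, 0.95))
  # two drivers each tied to the same metabolite at latent ~0.96: the
  # implied driver-driver correlation 0 is outside the PD envelope
  cfg <- simulation_config(planted_edges = pe, rng_seed = 1)
  expect_error(generate_cohort(cfg), "not positive definite")
})

test_that("simulated bundle carries structure the pipeline expects", {
  b <- generate_cohort(simulation_config(rng_seed = 3))
  expect_identical(ncol(b$counts), 80L)
  expect_identical(table(as.character(b$design$group))[c("HC", "CD", "UC")],
                   table(factor(c(rep("HC", 20), rep("CD", 23), rep("UC", 37)),
                                levels = c("HC", "CD", "UC")))[c("HC", "CD", "UC")])
  expect_true(all(b$biomass$total_16s_copies > 0))
  expect_identical(sort(b$tree$tip.label), sort(rownames(b$counts)))
  expect_identical(nrow(b$truth), nrow(default_planted_edges()))
  # the placeholder genus surfaces as a family-tagged pseudo-genus
  agg <- aggregate_genus(b$counts, b$taxonomy)
  expect_true(any(grepl("_unclassified$", rownames(agg))))
  # missing cells exist at the configured low rate but never a full feature
  expect_true(anyNA(ft_values(b$metabolites)))
  expect_true(all(rowSums(!is.na(ft_values(b$metabolites))) > 0))
})
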