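test_that("population structure follows the configured design", {
  cfg <- sim_config(n_sires = 28, progeny_per_sire = 20, n_markers = 50,
                    seed = 5)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$design), 560)
  expect_equal(dplyr::n_distinct(pop$design$sire_id), 28)
  expect_equal(dim(pop$panel), c(560L, 50L))
  # pens are single-sire and single-sex, nested in one contemporary group
  per_pen <- pop$design |>
    dplyr::summarise(n_sire = dplyr::n_distinct(sire_id),
                     n_sex = dplyr::n_distinct(sex),
                     n_cg = dplyr::n_distinct(contemporary_group),
                     .by = pen_id)
  expect_true(all(per_pen$n_sire == 1))
  expect_true(all(per_pen$n_sex == 1))
  expect_true(all(per_pen$n_cg == 1))
  expect_equal(dplyr::n_distinct(pop$design$contemporary_group), 6)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_sires = 4, progeny_per_sire = 5, n_markers = 80,
                    n_otu = 30, sequencing_depth = 500, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$design, b$design)
  expect_identical(simulate_otu_table(cfg, "Wean")$counts,
                   simulate_otu_table(cfg, "Wean")$counts)
  cfg2 <- sim_config(n_sires = 4, progeny_per_sire = 5, n_markers = 80,
                     n_otu = 30, sequencing_depth = 500, seed = 100)
  expect_false(identical(simulate_population(cfg2)$panel$dosage,
                         a$panel$dosage))
  # stages use distinct substreams
  expect_false(identical(simulate_otu_table(cfg, "Wean")$counts,
                         simulate_otu_table(cfg, "Mid-test")$counts))
})

test_that("half sibs show the expected genomic relationship of ~0.25", {
  cfg <- sim_config(n_sires = 28, progeny_per_sire = 20, n_markers = 5000,
                    seed = 7)
  pop <- simulate_population(cfg)
  G <- as.matrix(build_grm(pop$panel))
  fam <- pop$design$sire_id
  same_fam <- outer(fam, fam, `==`) & upper.tri(G)
  expect_lt(abs(mean(G[same_fam]) - 0.25), 0.03)
  # unrelated animals: relationship near zero
  expect_lt(abs(mean(G[!same_fam & upper.tri(G)])), 0.03)
})

test_that("OTU tables are depth-constrained multinomial compositions", {
  cfg <- sim_config(n_sires = 5, progeny_per_sire = 8, n_otu = 40,
                    sequencing_depth = 2000, seed = 21)
  tab <- simulate_otu_table(cfg, "Wean")
  expect_true(all(rowSums(tab$counts) == 2000))
  expect_identical(otu_stage(tab), "Wean")

  # two OTU with symmetric latent means split evenly
  cfg2 <- sim_config(n_sires = 25, progeny_per_sire = 20, n_otu = 2,
                     sequencing_depth = 10000, otu_log_sd = 0, seed = 31)
  tab2 <- simulate_otu_table(cfg2, "Wean")
  share <- colMeans(tab2$counts / 10000)
  expect_lt(abs(share[1] - 0.5), 0.02)
})

test_that("without a host covariate the microbiome is independent of the genome", {
  cfg <- sim_config(n_sires = 14, progeny_per_sire = 20, n_markers = 600,
                    n_otu = 50, sequencing_depth = 2000, seed = 13)
  pop <- simulate_population(cfg)
  tab <- simulate_otu_table(cfg, "Wean")
  Z <- scale(pop$panel$dosage)
  pc1 <- prcomp(Z, rank. = 1)$x[, 1]
  logab <- log(tab$counts + 1)
  rs <- cor(pc1, logab)
  n <- length(pc1)
  # null correlations: all within a 4/sqrt(n) band around zero
  expect_lt(max(abs(rs)), 4 / sqrt(n))

  # with the dependence channel on, associations become detectable
  tab2 <- simulate_otu_table(cfg, "Wean",
                             host_covariate = setNames(pc1, names(pc1)))
  rs2 <- cor(pc1, log(tab2$counts + 1))
  expect_gt(max(abs(rs2)), 4 / sqrt(n))
})

test_that("phenotype decomposition is exact and variance fractions are hit", {
  cfg <- sim_config(n_sires = 28, progeny_per_sire = 20, n_markers = 2000,
                    n_otu = 200, sequencing_depth = 2000, seed = 17)
  pop <- simulate_population(cfg)
  tab <- simulate_otu_table(cfg, "Wean")
  G <- build_grm(pop$panel)
  M <- suppressMessages(
    build_microbial_kernel(log_standardize_otu(relative_abundance(tab))))
  sim <- simulate_phenotypes(G, M, pop$design, cfg)
  comp <- sim$components
  expect_identical(comp$y,
                   comp$fixed + comp$additive + comp$microbiome +
                     comp$interaction + comp$pen + comp$residual)
  expect_identical(sim$records$trait_1, comp$y)

  # realized component variances track the targets (20 replicate draws)
  targets <- c(additive = 0.30, microbiome = 0.20, interaction = 0.10,
               pen = 0.05, residual = 0.35)
  reps <- vapply(1:20, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    ci <- simulate_phenotypes(G, M, pop$design, cfg_i)$components
    vapply(names(targets), function(k) var(ci[[k]]), 0)
  }, numeric(5))
  expect_true(all(abs(rowMeans(reps) - targets) < 0.05))
})

test_that("zero microbiome and interaction fractions give components identically zero", {
  b <- small_bundle(seed = 23,
                    var_fractions = c(additive = 0.4, microbiome = 0,
                                      interaction = 0, pen = 0.1,
                                      residual = 0.5))
  expect_true(all(b$components$microbiome == 0))
  expect_true(all(b$components$interaction == 0))
  expect_false(all(b$components$additive == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sires = 0), "n_sires")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(var_fractions = c(additive = 0.5, microbiome = 0.2,
                                            interaction = 0.1, pen = 0.1,
                                            residual = 0.2)), "sum to 1")
  expect_error(sim_config(var_fractions = c(additive = -0.1, microbiome = 0.5,
                                            interaction = 0.1, pen = 0.1,
                                            residual = 0.4)),
               "non-negative")
})
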