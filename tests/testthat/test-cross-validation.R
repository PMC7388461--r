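test_that("fold plans partition sires into equal folds", {
  sires <- sprintf("S%02d", 1:28)
  plan <- make_fold_plan(sires, n_folds = 4, seed = 3)
  tab <- table(plan$assignment$fold)
  expect_identical(as.integer(tab), rep(7L, 4))
  expect_setequal(plan$assignment$sire_id, sires)
  expect_error(make_fold_plan(sprintf("S%02d", 1:26), 4), "remainder 2")

  # derived animal memberships partition the population
  design <- tibble::tibble(
    animal_id = sprintf("A%04d", 1:560),
    sire_id = rep(sires, each = 20))
  mem <- fold_membership(plan, design)
  expect_equal(nrow(mem), 560)
  for (f in 1:4) {
    test_ids <- mem$animal_id[mem$fold == f]
    train_ids <- mem$animal_id[mem$fold != f]
    expect_length(intersect(test_ids, train_ids), 0)
    expect_setequal(c(test_ids, train_ids), design$animal_id)
    expect_equal(dplyr::n_distinct(mem$sire_id[mem$fold == f]), 7)
  }
})

test_that("relatedness grouping places related sires in the same fold", {
  sires <- sprintf("S%02d", 1:28)
  # block-diagonal relatedness: 4 clusters of 7
  cluster <- rep(1:4, each = 7)
  A <- outer(cluster, cluster, `==`) * 0.5
  diag(A) <- 1
  dimnames(A) <- list(sires, sires)
  # shuffle the matrix order to make sure assignment is id-driven
  ord <- sample(28)
  A <- A[ord, ord]
  plan <- make_fold_plan(sires, 4, grouping = A)
  got <- plan$assignment |>
    dplyr::mutate(cluster = cluster[match(sire_id, sires)])
  per_fold <- got |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(cluster), .by = fold)
  expect_true(all(per_fold$n_clusters == 1))
})

test_that("prediction scoring matches hand-computed r and MSE", {
  y <- c(1, 2, 3, 4)
  yh <- c(1.1, 1.9, 3.2, 3.8)
  ev <- evaluate_predictions(y, yh)
  # hand oracle
  r_hand <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(ev$r, r_hand)
  expect_equal(ev$mse, mean(c(0.1, 0.1, 0.2, 0.2)^2))
  expect_equal(evaluate_predictions(y, y)$r, 1)
  expect_equal(evaluate_predictions(y, y)$mse, 0)
  ym <- y - mean(y)
  expect_equal(evaluate_predictions(ym, -ym)$r, -1)
  expect_warning(ev0 <- evaluate_predictions(y, rep(1, 4)), "undefined")
  expect_true(is.na(ev0$r))
  expect_equal(ev0$mse, mean((y - 1)^2))
  expect_error(evaluate_predictions(y, yh[1:3]), "Lengths")
  expect_error(evaluate_predictions(y[1:2], yh[1:2]), "At least 3")
})

cv_bundle <- function(seed, fractions) {
  # 4 pens per sire: fixed-effect estimability survives fold masking
  cfg <- sim_config(n_sires = 8, progeny_per_sire = 8, pigs_per_pen = 2,
                    n_markers = 500, n_otu = 80, sequencing_depth = 1500,
                    n_contemporary_groups = 2, var_fractions = fractions,
                    seed = seed)
  pop <- simulate_population(cfg)
  tab <- simulate_otu_table(cfg, "Wean")
  G <- build_grm(pop$panel)
  M <- suppressMessages(
    build_microbial_kernel(log_standardize_otu(relative_abundance(tab))))
  sim <- simulate_phenotypes(G, M, pop$design, cfg)
  list(records = sim$records, panel = pop$panel, tab = tab)
}

test_that("run_cv emits a complete grid and M0 is stage-invariant", {
  b <- cv_bundle(301, c(additive = 0.1, microbiome = 0.4, interaction = 0,
                        pen = 0.05, residual = 0.45))
  tabs <- list(Wean = b$tab,
               `Mid-test` = otu_table(b$tab$counts, "Mid-test"))
  plan <- make_fold_plan(unique(b$records$sire_id), 2, seed = 5)
  res <- suppressMessages(run_cv(
    b$records, b$panel, tabs, plan, models = c("M0", "M2"),
    complexities = "FULL",
    mcmc = mcmc_settings(1500, 500, 5), seed = 9))
  expect_s3_class(res, "cv_results")
  expect_equal(nrow(res), 2 * 2 * 2)  # model x stage x fold
  expect_true(all(res$estimable))
  expect_true(all(res$n_test == 32))
  # M0 has no stage dependence
  m0 <- dplyr::filter(res, model == "M0")
  expect_equal(m0$r[m0$stage == "Wean"], m0$r[m0$stage == "Mid-test"])
  # with dominant microbiome signal, M2 should beat M0 on average
  expect_gt(mean(res$r[res$model == "M2"]), mean(res$r[res$model == "M0"]))
})

test_that("IR and RR sets are fold-specific, nested in FULL and size-matched", {
  b <- cv_bundle(302, c(additive = 0.05, microbiome = 0.55, interaction = 0,
                        pen = 0.05, residual = 0.35))
  plan <- make_fold_plan(unique(b$records$sire_id), 2, seed = 6)
  mem <- fold_membership(plan, b$records)
  all_otus <- colnames(b$tab$counts)
  S <- relative_abundance(b$tab)
  for (f in 1:2) {
    train <- mem$fold != f
    rec_tr <- b$records[train, ]
    scan <- scan_features(rec_tr, S[rec_tr$animal_id, ], "trait_1",
                          fold = f)
    ir <- tryCatch(select_informative(scan),
                   hologen_no_informative_features = function(c) character())
    expect_true(all(ir %in% all_otus))
    if (length(ir)) {
      rr <- select_random(all_otus, length(ir), seed = f)
      expect_length(rr, length(ir))
      expect_true(all(rr %in% all_otus))
    }
  }
})

test_that("a signal confined to the test set cannot inflate IR predictions", {
  b <- cv_bundle(303, c(additive = 0, microbiome = 0, interaction = 0,
                        pen = 0, residual = 1))
  plan <- make_fold_plan(unique(b$records$sire_id), 2, seed = 7)
  mem <- fold_membership(plan, b$records)
  # plant a strong feature-phenotype association only among fold-1 test
  # animals; training folds see pure noise
  S <- relative_abundance(b$tab)
  test1 <- mem$fold == 1
  b$records$trait_1[test1] <- 5 * scale(log(S[test1, 1] + 1e-3)) +
    rnorm(sum(test1), 0, 0.1)
  res <- suppressMessages(run_cv(
    b$records, b$panel, list(Wean = b$tab), plan, models = "M2",
    complexities = "IR", mcmc = mcmc_settings(1500, 500, 5), seed = 8))
  f1 <- dplyr::filter(res, fold == 1)
  # leak-free plumbing: the cell is either not estimable (nothing passes
  # Bonferroni in training) or essentially uninformative
  expect_true(all(!f1$estimable | abs(f1$r) < 0.5))
})
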