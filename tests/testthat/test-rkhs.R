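test_that("posterior summaries recompute fractions exactly", {
  set.seed(3)
  draws <- tibble::tibble(sigma2_additive = rchisq(1000, 3),
                          sigma2_microbiome = rchisq(1000, 3),
                          sigma2_pen = rchisq(1000, 2),
                          sigma2_residual = rchisq(1000, 5))
  s <- summarize_posterior(draws)
  # one-pass oracle recomputation
  tot <- rowSums(draws)
  for (k in names(draws)) {
    comp <- sub("sigma2_", "", k)
    expect_equal(s$frac_mean[s$component == comp], mean(draws[[k]] / tot),
                 tolerance = 1e-12)
    expect_equal(s$var_mean[s$component == comp], mean(draws[[k]]),
                 tolerance = 1e-12)
  }
  fr <- attr(s, "fraction_draws")
  expect_true(all(abs(rowSums(fr) - 1) < 1e-12))

  # a component forced to 29% of the total has fraction 0.29, SD 0
  base <- rchisq(500, 4)
  d2 <- tibble::tibble(sigma2_microbiome = 0.29 * base,
                       sigma2_residual = 0.71 * base)
  s2 <- summarize_posterior(d2)
  expect_equal(s2$frac_mean[s2$fraction == "m2"], 0.29)
  expect_equal(s2$frac_sd[s2$fraction == "m2"], 0)

  # zero variance draws give fraction exactly zero
  d3 <- tibble::tibble(sigma2_microbiome = rep(0, 100),
                       sigma2_residual = rchisq(100, 3))
  expect_equal(summarize_posterior(d3)$frac_mean[1], 0)
  expect_error(summarize_posterior(d3[0, ]), "retained draw")
})

make_fixed_records <- function(n, seed, pen_size = 10) {
  set.seed(seed)
  tibble::tibble(
    animal_id = sprintf("A%03d", seq_len(n)),
    sire_id = rep(sprintf("S%02d", seq_len(max(n %/% 10, 2))),
                  length.out = n),
    dam_line = sample(c("DL1", "DL2"), n, TRUE),
    sex = rep(c("M", "F"), length.out = n),
    contemporary_group = rep(c("CG1", "CG2"), each = pen_size,
                             length.out = n),
    pen_id = rep(sprintf("P%02d", seq_len(ceiling(n / pen_size))),
                 each = pen_size, length.out = n))
}

test_that("M0 posterior fixed effects approach the least-squares solution", {
  rec <- make_fixed_records(160, seed = 4)
  set.seed(5)
  mu <- 2 + 0.8 * (rec$dam_line == "DL2") - 0.5 * (rec$sex == "M") +
    0.4 * (rec$contemporary_group == "CG2")
  rec$trait_1 <- mu + rnorm(160, 0, 0.7)  # no pen variance simulated
  fit <- fit_rkhs(rec, "trait_1", model_spec("M0"),
                  mcmc_settings(6000, 1000, 2, seed = 6))
  ols <- stats::lm(trait_1 ~ dam_line + contemporary_group + sex,
                   data = rec)
  X <- stats::model.matrix(ols)
  se <- sqrt(diag(vcov(ols)))
  expect_true(all(abs(fit$coef_fixed - coef(ols)) < 3 * se))
  # fitted cell predictions agree closely
  expect_lt(max(abs(drop(X %*% fit$coef_fixed) - fitted(ols))),
            3 * max(se))
})

test_that("with fixed variances the sampler solves Henderson's equations", {
  b <- small_bundle(n_sires = 8, progeny = 6, markers = 300, seed = 31)
  rec <- b$records
  n <- nrow(rec)
  # mask one full pen plus scattered animals
  masked <- sort(c(which(rec$pen_id == rec$pen_id[n]), 3, 11))
  y <- rec$trait_1
  y[masked] <- NA
  rec$trait_1 <- y

  vk <- 0.45; vp <- 0.15; ve <- 0.55
  fit <- fit_rkhs(rec, "trait_1", model_spec("M1", G = b$G),
                  mcmc_settings(4000, 1000, 2, seed = 8,
                                fix_variances = list(additive = vk,
                                                     pen = vp,
                                                     residual = ve)))
  X <- stats::model.matrix(~ dam_line + contemporary_group + sex,
                           data = rec)
  orc <- blup_oracle(y, X, rec$pen_id, list(as.matrix(b$G)),
                     var_k = vk, var_pen = vp, var_e = ve)
  expect_lt(max(abs(fit$coef_fixed - orc$beta)), 1e-3)
  expect_lt(max(abs(fit$u$additive - orc$u[[1]])), 1e-3)
  expect_lt(max(abs(unname(fit$yhat) - orc$fitted)), 1e-3)
  # masked predictions equal the BLUP projection
  pred <- predict_masked(fit)
  expect_identical(pred$animal_id, rec$animal_id[masked])
  expect_lt(max(abs(pred$y_hat - orc$fitted[masked])), 1e-3)
  # the fully masked pen contributes no pen effect
  unseen <- which(rec$pen_id == rec$pen_id[n])
  expect_lt(max(abs(fit$yhat[unseen] -
                      drop(X[unseen, ] %*% fit$coef_fixed) -
                      fit$u$additive[unseen])), 1e-3)
})

test_that("M0 predictions for masked records are the fixed-effect cell values", {
  rec <- make_fixed_records(80, seed = 14)
  set.seed(15)
  rec$trait_1 <- 1 + 0.6 * (rec$sex == "M") + rnorm(80, 0, 0.5)
  masked <- which(rec$pen_id == "P01")
  rec$trait_1[masked] <- NA
  y <- rec$trait_1
  fit <- fit_rkhs(rec, "trait_1", model_spec("M0"),
                  mcmc_settings(4000, 1000, 2, seed = 16,
                                fix_variances = list(pen = 0.1,
                                                     residual = 0.3)))
  X <- stats::model.matrix(~ dam_line + contemporary_group + sex,
                           data = rec)
  orc <- blup_oracle(y, X, rec$pen_id, list(), numeric(0), 0.1, 0.3)
  pred <- predict_masked(fit)
  expect_lt(max(abs(pred$y_hat - orc$fitted[masked])), 1e-3)
  # pen P01 is unseen in training: prediction is purely the fixed part
  expect_lt(max(abs(pred$y_hat - drop(X[masked, ] %*% fit$coef_fixed))),
            1e-3)
})

test_that("a masked animal with a duplicated kernel row predicts like its twin", {
  b <- small_bundle(n_sires = 4, progeny = 8, markers = 400, seed = 41,
                    var_fractions = c(additive = 0.85, microbiome = 0,
                                      interaction = 0, pen = 0,
                                      residual = 0.15))
  rec <- b$records
  # make animal 2 a genomic copy of animal 1, then mask it
  K <- as.matrix(b$G)
  K[2, ] <- K[1, ]
  K[, 2] <- K[, 1]
  K[2, 2] <- K[1, 1]
  G2 <- relationship_kernel(K, "G")
  rec$dam_line[2] <- rec$dam_line[1]  # same fixed cell
  rec$sex[2] <- rec$sex[1]
  rec$contemporary_group[2] <- rec$contemporary_group[1]
  rec$pen_id[2] <- rec$pen_id[1]
  rec$trait_1[2] <- NA
  fit <- fit_rkhs(rec, "trait_1", model_spec("M1", G = G2),
                  mcmc_settings(6000, 1000, 2, seed = 42,
                                fix_variances = list(additive = 0.85,
                                                     pen = 1e-4,
                                                     residual = 0.15)))
  expect_lt(abs(fit$yhat[2] - fit$yhat[1]), 0.02)
})

test_that("posterior summaries are stable under animal permutation", {
  b <- small_bundle(n_sires = 8, progeny = 10, seed = 51)
  fit1 <- fit_rkhs(b$records, "trait_1", model_spec("M3", G = b$G, M = b$M),
                   mcmc_settings(4000, 1000, 5, seed = 52))
  set.seed(53)
  perm <- sample(nrow(b$records))
  recp <- b$records[perm, ]
  Gp <- relationship_kernel(as.matrix(b$G)[perm, perm], "G")
  Mp <- relationship_kernel(as.matrix(b$M)[perm, perm], "M")
  fit2 <- fit_rkhs(recp, "trait_1", model_spec("M3", G = Gp, M = Mp),
                   mcmc_settings(4000, 1000, 5, seed = 52))
  s1 <- fit1$summary$frac_mean
  s2 <- fit2$summary$frac_mean
  expect_lt(max(abs(s1 - s2)), 0.06)
})

test_that("adding a zero-variance kernel leaves other fractions unchanged", {
  b <- small_bundle(n_sires = 8, progeny = 12, markers = 600, seed = 61,
                    var_fractions = c(additive = 0.45, microbiome = 0,
                                      interaction = 0, pen = 0.05,
                                      residual = 0.5))
  m1 <- fit_rkhs(b$records, "trait_1", model_spec("M1", G = b$G),
                 mcmc_settings(5000, 1000, 5, seed = 62))
  m3 <- fit_rkhs(b$records, "trait_1", model_spec("M3", G = b$G, M = b$M),
                 mcmc_settings(5000, 1000, 5, seed = 63))
  h2_1 <- m1$summary$frac_mean[m1$summary$fraction == "h2"]
  h2_3 <- m3$summary$frac_mean[m3$summary$fraction == "h2"]
  m2_3 <- m3$summary$frac_mean[m3$summary$fraction == "m2"]
  expect_lt(abs(h2_1 - h2_3), 0.08)
  # at n ~ 100 the prior keeps a little mass on sigma2_o; the fraction
  # must still be small
  expect_lt(m2_3, 0.15)
})

test_that("model/kernel contracts are enforced", {
  b <- small_bundle(n_sires = 4, progeny = 5, markers = 100, seed = 71)
  expect_error(model_spec("M1"), "requires kernel G")
  expect_error(model_spec("M2"), "requires kernel M")
  expect_error(model_spec("M1", G = b$G, M = b$M), "does not use M")
  expect_error(model_spec("M0", M = b$M), "does not use M")
  spec <- model_spec("M4", G = b$G, M = b$M)
  expect_named(spec$kernels, c("additive", "microbiome", "interaction"))

  rec <- b$records
  rec$trait_1 <- NA_real_
  expect_error(fit_rkhs(rec, "trait_1", model_spec("M0"),
                        mcmc_settings(100, 10, 1)),
               "non-missing phenotype")
  rec2 <- b$records[order(b$records$animal_id, decreasing = TRUE), ]
  expect_error(fit_rkhs(rec2, "trait_1", model_spec("M1", G = b$G),
                        mcmc_settings(100, 10, 1)),
               "not indexed")
  # a dam line present only among masked records is an error
  rec3 <- b$records
  rec3$trait_1[rec3$dam_line == "DL2"] <- NA
  expect_error(fit_rkhs(rec3, "trait_1", model_spec("M0"),
                        mcmc_settings(100, 10, 1)),
               "absent from records")
})

test_that("the sampler is deterministic given the seed", {
  b <- small_bundle(n_sires = 4, progeny = 5, markers = 100, seed = 81)
  f1 <- fit_rkhs(b$records, "trait_1", model_spec("M1", G = b$G),
                 mcmc_settings(800, 200, 2, seed = 9))
  f2 <- fit_rkhs(b$records, "trait_1", model_spec("M1", G = b$G),
                 mcmc_settings(800, 200, 2, seed = 9))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$yhat, f2$yhat)
})
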