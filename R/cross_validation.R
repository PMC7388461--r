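# Sire-grouped fourfold cross-validation. Sires are partitioned into
# equal-size fold groups (by greedy agglomeration on a sire relatedness
# matrix when one is supplied, so related sires never straddle train and
# test), test phenotypes are masked, feature preselection and kernel
# statistics are recomputed inside each training fold, and predictions are
# scored against raw phenotypes by Pearson correlation and MSE.

#' Build a sire-grouped fold plan
#'
#' Partitions sires into `n_folds` groups of equal size. With a
#' relatedness matrix, a greedy agglomerative rule seeds each fold with
#' the most-related remaining sire pair and grows it by mean relatedness,
#' keeping related sires inside one fold; otherwise the split is random.
#'
#' @param sires Character vector of sire ids (no duplicates).
#' @param n_folds Number of folds; must divide the number of sires.
#' @param grouping Optional symmetric sire-by-sire relatedness matrix with
#'   dimnames covering `sires`.
#' @param seed Seed for the random split (unused when `grouping` given).
#' @return An object of class `fold_plan` with the sire-to-fold
#'   assignment.
#' @export
make_fold_plan <- function(sires, n_folds = 4, grouping = NULL, seed = 1) {
  sires <- as.character(sires)
  if (anyDuplicated(sires)) abort("`sires` must be duplicate-free.")
  n <- length(sires)
  assert_scalar_count(n_folds, "n_folds")
  if (n %% n_folds != 0) {
    abort(sprintf(
      "%d sires cannot be split into %d equal folds (remainder %d).",
      n, n_folds, n %% n_folds))
  }
  per <- n %/% n_folds
  if (is.null(grouping)) {
    shuffled <- with_seed(seed, sample(sires))
    fold_of <- rep(seq_len(n_folds), each = per)
    assignment <- tibble::tibble(sire_id = shuffled, fold = fold_of)
  } else {
    if (!is.matrix(grouping) || !identical(rownames(grouping),
                                           colnames(grouping)) ||
        !all(sires %in% rownames(grouping))) {
      abort("`grouping` must be a symmetric matrix with sire id dimnames.")
    }
    if (max(abs(grouping[sires, sires] - t(grouping[sires, sires]))) >
        1e-8) {
      abort("`grouping` must be symmetric.")
    }
    remaining <- sort(sires)
    folds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      if (per == 1L || length(remaining) <= 2L) {
        cur <- remaining[seq_len(per)]
      } else {
        sub <- grouping[remaining, remaining]
        diag(sub) <- -Inf
        top <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        cur <- remaining[as.integer(top)]
        while (length(cur) < per) {
          cand <- setdiff(remaining, cur)
          score <- rowMeans(grouping[cand, cur, drop = FALSE])
          cur <- c(cur, cand[which.max(score)])
        }
        cur <- cur[seq_len(per)]
      }
      folds[[f]] <- cur
      remaining <- setdiff(remaining, cur)
    }
    assignment <- tibble::tibble(
      sire_id = unlist(folds),
      fold = rep(seq_len(n_folds), lengths(folds)))
  }
  structure(list(assignment = assignment, n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d sires in %d folds\n",
              nrow(x$assignment), x$n_folds))
  invisible(x)
}

#' @method tidy fold_plan
#' @export
tidy.fold_plan <- function(x, ...) x$assignment

#' Animal fold membership under a plan
#'
#' @param plan A [make_fold_plan()] object.
#' @param design Tibble with `animal_id` and `sire_id`.
#' @return Tibble `animal_id`, `sire_id`, `fold` (the fold in which the
#'   animal is a *test* animal).
#' @export
fold_membership <- function(plan, design) {
  stopifnot(inherits(plan, "fold_plan"))
  out <- dplyr::inner_join(design[c("animal_id", "sire_id")],
                           plan$assignment, by = "sire_id")
  if (nrow(out) != nrow(design)) {
    abort("Some animals have sires absent from the fold plan.")
  }
  out
}

#' Score predictions against observed phenotypes
#'
#' @param y_obs,y_hat Numeric vectors of equal length (>= 3).
#' @return Tibble with `r` (Pearson correlation; `NA` with a warning if
#'   either vector has zero variance), `mse` and `n_test`.
#' @export
evaluate_predictions <- function(y_obs, y_hat) {
  if (length(y_obs) != length(y_hat)) abort("Lengths differ.")
  if (length(y_obs) < 3) abort("At least 3 pairs are required.")
  mse <- mean((y_obs - y_hat)^2)
  if (sd(y_obs) == 0 || sd(y_hat) == 0) {
    warn("Zero variance in observed or predicted values; r is undefined.")
    r <- NA_real_
  } else {
    r <- cor(y_obs, y_hat)
  }
  tibble::tibble(r = r, mse = mse, n_test = length(y_obs))
}

# Fit one masked-phenotype cell and score the test predictions.
cv_fit_cell <- function(records_masked, y_full, test_idx, trait, spec,
                        mcmc) {
  fit <- fit_rkhs(records_masked, trait, spec, mcmc)
  pred <- fit$yhat[test_idx]
  evaluate_predictions(y_full[test_idx], unname(pred))
}

#' Run the cross-validation grid
#'
#' Executes every trait x stage x model x complexity cell of the design
#' over the folds of `plan`. Inside each fold, test phenotypes are masked;
#' allele frequencies, OTU standardization statistics and the IR/RR
#' feature sets are computed from training animals only. Cells whose
#' informative selection is empty are recorded as not estimable and the
#' run continues.
#'
#' @param records Phenotype/design tibble (all animals, raw phenotypes).
#' @param genotypes QC'd [genotype_panel()] over `records$animal_id`.
#' @param otu_tables Named list of rarefied [otu_table()]s (one per
#'   stage; names are stage labels) covering `records$animal_id`, or a
#'   single `otu_table`.
#' @param plan A [make_fold_plan()].
#' @param models Subset of `c("M0","M1","M2","M3","M4")`.
#' @param complexities Subset of `c("FULL","IR","RR")`.
#' @param traits Trait column names; defaults to columns matching
#'   `"^trait_"`.
#' @param mcmc [mcmc_settings()]; the default is a reduced-iteration
#'   profile (12,000 iterations, 2,000 burn-in, thin 5) suited to
#'   repeated fitting; per-cell sampler seeds are derived from `seed`.
#' @param alpha Bonferroni family-wise level for the IR selection.
#' @param seed Root seed for random feature reduction and sampler seeds.
#' @param otu_centering Centering convention for [log_standardize_otu()].
#' @return A `cv_results` tibble: `trait`, `stage`, `model`,
#'   `complexity`, `fold`, `r`, `mse`, `n_test`, `estimable`.
#' @export
run_cv <- function(records, genotypes, otu_tables, plan,
                   models = c("M0", "M1", "M2", "M3", "M4"),
                   complexities = "FULL",
                   traits = NULL,
                   mcmc = mcmc_settings(n_iter = 12000, burn_in = 2000,
                                        thin = 5),
                   alpha = 0.05, seed = 1,
                   otu_centering = "mean-of-logs") {
  stopifnot(inherits(plan, "fold_plan"),
            inherits(genotypes, "genotype_panel"))
  models <- match.arg(models, several.ok = TRUE)
  complexities <- match.arg(complexities, c("FULL", "IR", "RR"),
                            several.ok = TRUE)
  if (inherits(otu_tables, "otu_table")) {
    otu_tables <- setNames(list(otu_tables), otu_stage(otu_tables))
  }
  stages <- names(otu_tables)
  traits <- traits %||% grep("^trait_", names(records), value = TRUE)
  if (!length(traits)) abort("No trait columns found.")
  ids <- records$animal_id
  if (!identical(animal_ids(genotypes), ids)) {
    abort("Genotype panel must be indexed by `records$animal_id` in order.")
  }
  S_list <- lapply(otu_tables, function(tab) {
    S <- relative_abundance(tab)
    if (!all(ids %in% rownames(S))) {
      abort("OTU tables must cover all animals in `records`.")
    }
    S[ids, , drop = FALSE]
  })
  membership <- fold_membership(plan, records)
  needs_otu <- function(m) m %in% c("M2", "M3", "M4")
  needs_geno <- function(m) m %in% c("M1", "M3", "M4")

  rows <- list()
  add_row <- function(trait, stage, model, complexity, fold, score) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      trait = trait, stage = stage, model = model,
      complexity = complexity, fold = fold,
      r = score$r %||% NA_real_, mse = score$mse %||% NA_real_,
      n_test = score$n_test %||% 0L,
      estimable = !is.null(score$r))
  }
  not_estimable <- list(r = NULL, mse = NULL, n_test = NULL)

  for (f in seq_len(plan$n_folds)) {
    test <- membership$fold == f
    train_ids <- ids[!test]
    test_idx <- which(test)
    p_train <- colMeans(genotypes$dosage[train_ids, , drop = FALSE]) / 2
    G_full <- build_grm(genotypes, allele_freq = p_train)
    M_full <- lapply(stages, function(s) {
      X <- log_standardize_otu(S_list[[s]], stat_rows = train_ids,
                               centering = otu_centering)
      build_microbial_kernel(X)
    })
    names(M_full) <- stages
    rec_train <- records[!test, , drop = FALSE]
    geno_train <- genotype_panel_imputed(
      genotypes$dosage[train_ids, , drop = FALSE])

    for (trait in traits) {
      y_full <- records[[trait]]
      rec_masked <- records
      rec_masked[[trait]][test] <- NA_real_
      cell_mcmc <- function(stage, model, complexity) {
        m <- mcmc
        m$seed <- substream_seed(seed, paste("fit", trait, stage, model,
                                             complexity, f))
        m
      }
      score_cell <- function(spec, m) {
        cv_fit_cell(rec_masked, y_full, test_idx, trait, spec, m)
      }

      # marker-side feature sets, per training fold and trait
      marker_sets <- list(FULL = colnames(genotypes$dosage))
      if (any(c("IR", "RR") %in% complexities) &&
          any(vapply(models, needs_geno, TRUE))) {
        scan_m <- scan_features(rec_train, geno_train, trait, fold = f)
        ir <- tryCatch(select_informative(scan_m, alpha = alpha),
                       hologen_no_informative_features = function(c) NULL)
        marker_sets$IR <- ir
        marker_sets$RR <- if (is.null(ir)) NULL else
          select_random(colnames(genotypes$dosage), length(ir),
                        seed = substream_seed(seed,
                                              paste("rr-marker", trait, f)))
      }
      G_of <- function(cx) {
        set <- marker_sets[[cx]]
        if (is.null(set)) return(NULL)
        if (cx == "FULL") return(G_full)
        build_grm(
          genotype_panel_imputed(genotypes$dosage[, set, drop = FALSE]),
          allele_freq = p_train[set])
      }

      if ("M0" %in% models) {
        sc <- score_cell(model_spec("M0"), cell_mcmc("-", "M0", "FULL"))
        for (s in stages) for (cx in complexities) {
          add_row(trait, s, "M0", cx, f, sc)
        }
      }
      if ("M1" %in% models) {
        for (cx in complexities) {
          G_cx <- G_of(cx)
          sc <- if (is.null(G_cx)) not_estimable else
            score_cell(model_spec("M1", G = G_cx, complexity = cx),
                       cell_mcmc("-", "M1", cx))
          for (s in stages) add_row(trait, s, "M1", cx, f, sc)
        }
      }

      otu_models <- intersect(models, c("M2", "M3", "M4"))
      if (length(otu_models)) {
        for (s in stages) {
          otu_sets <- list(FULL = colnames(S_list[[s]]))
          if (any(c("IR", "RR") %in% complexities)) {
            scan_o <- scan_features(rec_train,
                                    S_list[[s]][train_ids, , drop = FALSE],
                                    trait, stage = s, fold = f)
            ir <- tryCatch(select_informative(scan_o, alpha = alpha),
                           hologen_no_informative_features =
                             function(c) NULL)
            otu_sets$IR <- ir
            otu_sets$RR <- if (is.null(ir)) NULL else
              select_random(colnames(S_list[[s]]), length(ir),
                            seed = substream_seed(
                              seed, paste("rr-otu", trait, s, f)))
          }
          M_of <- function(cx) {
            set <- otu_sets[[cx]]
            if (is.null(set)) return(NULL)
            if (cx == "FULL") return(M_full[[s]])
            X <- log_standardize_otu(S_list[[s]][, set, drop = FALSE],
                                     stat_rows = train_ids,
                                     centering = otu_centering)
            build_microbial_kernel(X)
          }
          for (model in otu_models) {
            for (cx in complexities) {
              M_cx <- M_of(cx)
              G_cx <- if (needs_geno(model)) G_of(cx) else NULL
              ok <- !is.null(M_cx) && (!needs_geno(model) || !is.null(G_cx))
              sc <- if (!ok) not_estimable else
                score_cell(model_spec(model, G = G_cx, M = M_cx,
                                      stage = s, complexity = cx),
                           cell_mcmc(s, model, cx))
              add_row(trait, s, model, cx, f, sc)
            }
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_results", class(out))
  out
}
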