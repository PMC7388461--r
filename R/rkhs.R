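# Bayesian RKHS regression by Gibbs sampling. Models M0-M4 share the fixed
# part (dam line, contemporary group, sex) and an iid pen effect nested in
# contemporary group; M1-M4 add kernel-structured random effects (genomic
# G, microbial M, interaction G*M). Each kernel effect is sampled in the
# eigenbasis of its kernel: with u = U sqrt(L) alpha and orthonormal U, the
# coefficients alpha have a diagonal full conditional, so one n x r
# matrix-vector product per kernel per iteration suffices. The sampler
# runs on the observed records only; masked records receive the kernel
# projection of the sampled training effects, which equals the joint
# masked-record BLUP prediction under the RKHS model.

#' MCMC settings for the RKHS sampler
#'
#' @param n_iter Total Gibbs iterations (default 120,000).
#' @param burn_in Iterations discarded as burn-in (default 20,000).
#' @param thin Thinning interval (default 5).
#' @param seed Sampler seed.
#' @param prior_df Prior degrees of freedom for every variance component.
#' @param prior_r2 Prior proportion of phenotypic variance assigned to the
#'   random terms jointly; it is split equally among the active terms
#'   (kernels plus pen) to set the prior scales, the convention of
#'   Bayesian kernel-regression software.
#' @param fix_variances Optional named list fixing variance components
#'   (names among the kernel roles, `"pen"`, `"residual"`); fixed
#'   components are not sampled. A component fixed at 0 pins its effect
#'   at 0.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 120000, burn_in = 20000, thin = 5,
                          seed = 1, prior_df = 5, prior_r2 = 0.5,
                          fix_variances = NULL) {
  assert_scalar_count(n_iter, "n_iter")
  assert_scalar_count(burn_in, "burn_in", min = 0L)
  assert_scalar_count(thin, "thin")
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df, prior_r2 = prior_r2,
                 fix_variances = fix_variances),
            class = "mcmc_settings")
}

#' Model specification for the kernel hierarchy M0-M4
#'
#' M0 is the baseline (fixed effects + pen); M1 adds the genomic kernel,
#' M2 the microbial kernel, M3 both, and M4 additionally their Hadamard
#' product for genome-by-microbiome interaction (built here from `G` and
#' `M`).
#'
#' @param model One of `"M0"` to `"M4"`.
#' @param G,M [relationship_kernel()] objects; exactly those required by
#'   the model id must be supplied.
#' @param stage Optional growth-stage label carried into results.
#' @param complexity Feature-set label (`"FULL"`, `"IR"`, `"RR"`) carried
#'   into results.
#' @return A list of class `model_spec` with the attached kernels.
#' @export
model_spec <- function(model = c("M0", "M1", "M2", "M3", "M4"),
                       G = NULL, M = NULL, stage = NULL,
                       complexity = c("FULL", "IR", "RR")) {
  model <- match.arg(model)
  complexity <- match.arg(complexity)
  need_G <- model %in% c("M1", "M3", "M4")
  need_M <- model %in% c("M2", "M3", "M4")
  if (need_G && is.null(G)) abort(sprintf("%s requires kernel G.", model))
  if (need_M && is.null(M)) abort(sprintf("%s requires kernel M.", model))
  if (!need_G && !is.null(G)) abort(sprintf("%s does not use G.", model))
  if (!need_M && !is.null(M)) abort(sprintf("%s does not use M.", model))
  kernels <- list()
  if (need_G) kernels$additive <- G
  if (need_M) kernels$microbiome <- M
  if (model == "M4") kernels$interaction <- interaction_kernel(G, M)
  structure(list(model = model, kernels = kernels, stage = stage,
                 complexity = complexity),
            class = "model_spec")
}

# Eigenbasis design of a kernel: W = U diag(sqrt(lambda)) with eigenvalues
# below 1e-10 truncated (numerical PSD enforcement with negligible
# variance loss).
kernel_basis <- function(K, label) {
  ed <- eigen(K, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    abort(sprintf("Kernel %s is not numerically PSD after clipping.", label))
  }
  keep <- ed$values > 1e-10
  if (!any(keep)) abort(sprintf("Kernel %s has no positive eigenvalues.",
                                label))
  lam <- ed$values[keep]
  W <- sweep(ed$vectors[, keep, drop = FALSE], 2, sqrt(lam), "*")
  list(W = W, lambda = lam, r = length(lam))
}

fixed_design <- function(records, obs) {
  terms <- c("dam_line", "contemporary_group", "sex")
  df <- as.data.frame(records[terms])
  for (v in terms) {
    f <- factor(df[[v]])
    if (nlevels(f) > 1 && any(!levels(f) %in% unique(as.character(f[obs])))) {
      abort(sprintf(
        "Factor `%s` has levels absent from records with phenotypes.", v))
    }
    df[[v]] <- f
  }
  active <- terms[vapply(df, nlevels, 0L) > 1]
  fml <- if (length(active)) {
    stats::reformulate(active)
  } else {
    ~1
  }
  X <- model.matrix(fml, df)
  if (qr(X[obs, , drop = FALSE])$rank < ncol(X)) {
    abort(paste("Fixed-effect design is rank-deficient among records",
                "with observed phenotypes."))
  }
  X
}

#' Fit an RKHS mixed model by Gibbs sampling
#'
#' Samples fixed effects (flat prior), an iid pen effect, one variance per
#' kernel term, and scaled-inverse-chi-square variance components.
#' Records with a missing trait value contribute nothing to the likelihood
#' but receive predictions (the kernel projection of the sampled training
#' effects plus the fixed part). Deterministic given the settings seed.
#'
#' @param records Tibble with columns `animal_id`, `dam_line`,
#'   `contemporary_group`, `sex`, `pen_id` and the trait; `NA` trait
#'   values mark records to predict.
#' @param trait Name of the trait column.
#' @param spec A [model_spec()]; every attached kernel must be indexed by
#'   `records$animal_id` in order.
#' @param mcmc An [mcmc_settings()].
#' @return An object of class `rkhs_fit` with posterior variance draws,
#'   a [summarize_posterior()] summary, posterior-mean fixed, pen and
#'   kernel effects, and fitted values for all animals.
#' @export
fit_rkhs <- function(records, trait, spec, mcmc = mcmc_settings()) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_settings"))
  if (!trait %in% names(records)) {
    abort(sprintf("Trait `%s` not found in records.", trait))
  }
  ids <- records$animal_id
  n <- length(ids)
  y <- records[[trait]]
  obs <- !is.na(y)
  if (!any(obs)) abort("At least one non-missing phenotype is required.")
  for (k in names(spec$kernels)) {
    if (!identical(animal_ids(spec$kernels[[k]]), ids)) {
      abort(sprintf("Kernel `%s` is not indexed by the records' animals.", k))
    }
  }

  X <- fixed_design(records, obs)
  Xo <- X[obs, , drop = FALSE]
  p_fix <- ncol(X)
  XtX <- crossprod(Xo)
  Rx <- chol(XtX)
  n_obs <- sum(obs)

  # pen levels observed in training; animals in unseen pens contribute no
  # pen term and predict with pen effect 0
  pen_levels <- sort(unique(records$pen_id[obs]))
  pen_idx <- match(records$pen_id, pen_levels)   # NA for unseen pens
  pen_obs <- pen_idx[obs]                        # never NA
  n_pen <- length(pen_levels)
  n_l <- as.numeric(tabulate(pen_obs, nbins = n_pen))
  # fixed effects and pen effects are sampled as one joint block (their
  # strong cross-correlation would otherwise dominate the autocorrelation
  # time); C0 is the constant part of the joint precision
  XtZ <- t(rowsum(Xo, pen_obs))
  C0 <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), diag(n_l, n_pen)))
  pen_diag_idx <- (p_fix + seq_len(n_pen) - 1L) * (p_fix + n_pen) +
    p_fix + seq_len(n_pen)

  # sampling runs in the eigenbasis of the observed block of each kernel
  # (diagonal full conditionals); masked animals receive the kernel
  # projection u = K[, obs] K_obs^+ u_obs, the conditional mean of their
  # effect given the sampled training effects. P maps the basis
  # coefficients to effects for all animals; its observed rows reduce to
  # W = U sqrt(lambda).
  bases <- lapply(names(spec$kernels), function(k) {
    K <- as.matrix(spec$kernels[[k]])
    b <- kernel_basis(K[obs, obs, drop = FALSE], k)
    b$P <- K[, obs, drop = FALSE] %*%
      sweep(b$W, 2, b$lambda, "/")       # = K[, obs] U / lambda * sqrt(..)
    b
  })
  names(bases) <- names(spec$kernels)
  kn <- names(bases)

  vy <- var(y[obs])
  df0 <- mcmc$prior_df
  n_rand <- length(kn) + 1L
  target <- vy * mcmc$prior_r2 / n_rand
  S0 <- c(vapply(kn, function(k) {
    target / mean(diag(as.matrix(spec$kernels[[k]]))) * (df0 + 2) / df0
  }, 0), pen = target * (df0 + 2) / df0,
  residual = vy * (1 - mcmc$prior_r2) * (df0 + 2) / df0)

  fixv <- mcmc$fix_variances %||% list()
  is_fixed <- function(nm) nm %in% names(fixv)

  # Effect-update scheme. Small problems use one joint Gaussian block over
  # (fixed, pen, all kernel coefficients): a two-block Gibbs with the
  # variances that mixes much faster when pens align with families, and is
  # exact draw-by-draw when all variances are fixed. Large problems cycle
  # per-block in the eigenbasis, where each update costs one matrix-vector
  # product instead of a cubic solve.
  pen_active <- !(is_fixed("pen") && fixv$pen == 0)
  kernel_active <- vapply(kn, function(k) !(is_fixed(k) && fixv[[k]] == 0),
                          TRUE)
  d_joint <- p_fix + if (pen_active) n_pen else 0L
  d_joint <- d_joint + sum(vapply(bases[kernel_active], function(b) b$r, 0L))
  joint_scheme <- d_joint <= 200L
  if (joint_scheme) {
    Bj <- Xo
    idx_beta <- seq_len(p_fix)
    idx_pen <- integer(0)
    if (pen_active) {
      Z <- matrix(0, n_obs, n_pen)
      Z[cbind(seq_len(n_obs), pen_obs)] <- 1
      idx_pen <- p_fix + seq_len(n_pen)
      Bj <- cbind(Bj, Z)
    }
    idx_alpha <- list()
    for (k in kn[kernel_active]) {
      idx_alpha[[k]] <- ncol(Bj) + seq_len(bases[[k]]$r)
      Bj <- cbind(Bj, bases[[k]]$W)
    }
    BtB <- crossprod(Bj)
    d_all <- ncol(Bj)
  }

  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  if (n_keep < 1) abort("No retained draws: increase n_iter or cut burn_in.")
  comp_names <- c(kn, "pen", "residual")
  draws <- matrix(NA_real_, n_keep, length(comp_names),
                  dimnames = list(NULL, paste0("sigma2_", comp_names)))

  with_seed(mcmc$seed, {
    # state: everything lives on the observed records; masked records
    # contribute nothing to any full conditional
    yo <- y[obs]
    beta <- numeric(p_fix)
    beta[1] <- mean(yo)
    Xb <- drop(Xo %*% beta)
    pen_eff <- numeric(n_pen)
    alpha <- lapply(bases, function(b) numeric(b$r))
    u <- lapply(bases, function(b) numeric(n_obs))
    s2 <- c(vapply(kn, function(k) {
      if (is_fixed(k)) fixv[[k]] else S0[[k]] * df0 / (df0 + 2)
    }, 0), pen = if (is_fixed("pen")) fixv$pen else target,
    residual = if (is_fixed("residual")) fixv$residual else
      vy * (1 - mcmc$prior_r2))
    names(s2) <- comp_names
    e <- yo - Xb

    beta_acc <- numeric(p_fix)
    pen_acc <- numeric(n_pen)
    amean_acc <- lapply(bases, function(b) numeric(b$r))
    kept <- 0L

    if (joint_scheme) {
      Bty <- drop(crossprod(Bj, yo))
      dj <- function(idx) (idx - 1L) * d_all + idx
    }

    for (it in seq_len(mcmc$n_iter)) {
      if (joint_scheme) {
        # one Gaussian block over every effect given the variances
        Cmat <- BtB / s2[["residual"]]
        if (pen_active) {
          Cmat[dj(idx_pen)] <- Cmat[dj(idx_pen)] + 1 / s2[["pen"]]
        }
        for (k in kn[kernel_active]) {
          Cmat[dj(idx_alpha[[k]])] <- Cmat[dj(idx_alpha[[k]])] + 1 / s2[[k]]
        }
        Rc <- chol(Cmat)
        jmean <- drop(backsolve(Rc, forwardsolve(t(Rc),
                                                 Bty / s2[["residual"]])))
        jdraw <- jmean + drop(backsolve(Rc, rnorm(d_all)))
        bmean <- jmean[idx_beta]
        beta <- jdraw[idx_beta]
        if (pen_active) {
          pen_mean <- jmean[idx_pen]
          pen_eff <- jdraw[idx_pen]
        } else {
          pen_mean <- numeric(n_pen)
          pen_eff <- numeric(n_pen)
        }
        alpha_mean <- alpha
        for (k in kn[kernel_active]) {
          alpha_mean[[k]] <- jmean[idx_alpha[[k]]]
          alpha[[k]] <- jdraw[idx_alpha[[k]]]
        }
        e <- yo - drop(Bj %*% jdraw)
        if (!is_fixed("pen") && s2[["pen"]] > 0) {
          s2[["pen"]] <- (df0 * S0[["pen"]] + sum(pen_eff^2)) /
            rchisq(1, df0 + n_pen)
        }
        for (k in kn[kernel_active]) {
          if (!is_fixed(k)) {
            s2[[k]] <- (df0 * S0[[k]] + sum(alpha[[k]]^2)) /
              rchisq(1, df0 + bases[[k]]$r)
          }
        }
        if (!is_fixed("residual")) {
          s2[["residual"]] <- (df0 * S0[["residual"]] + sum(e^2)) /
            rchisq(1, df0 + n_obs)
        }
        if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L &&
            kept < n_keep) {
          kept <- kept + 1L
          draws[kept, ] <- s2
          beta_acc <- beta_acc + bmean
          pen_acc <- pen_acc + pen_mean
          for (k in kn) {
            amean_acc[[k]] <- amean_acc[[k]] + alpha_mean[[k]]
          }
        }
        next
      }
      # joint (fixed, pen) block: flat prior on fixed effects, iid normal
      # prior on pen effects
      yt <- e + Xb + pen_eff[pen_obs]
      if (s2[["pen"]] > 0) {
        rhs <- c(crossprod(Xo, yt),
                 rowsum(yt, pen_obs)) / s2[["residual"]]
        Cmat <- C0 / s2[["residual"]]
        Cmat[pen_diag_idx] <- Cmat[pen_diag_idx] + 1 / s2[["pen"]]
        Rc <- chol(Cmat)
        jmean <- drop(backsolve(Rc, forwardsolve(t(Rc), rhs)))
        jdraw <- jmean + drop(backsolve(Rc, rnorm(p_fix + n_pen)))
        bmean <- jmean[seq_len(p_fix)]
        pen_mean <- jmean[-seq_len(p_fix)]
        beta <- jdraw[seq_len(p_fix)]
        pen_eff <- jdraw[-seq_len(p_fix)]
        if (!is_fixed("pen")) {
          s2[["pen"]] <- (df0 * S0[["pen"]] + sum(pen_eff^2)) /
            rchisq(1, df0 + n_pen)
        }
      } else {
        bmean <- drop(backsolve(Rx, forwardsolve(t(Rx), crossprod(Xo, yt))))
        beta <- bmean + sqrt(s2[["residual"]]) *
          drop(backsolve(Rx, rnorm(p_fix)))
        pen_mean <- numeric(n_pen)
        pen_eff <- numeric(n_pen)
      }
      Xb <- drop(Xo %*% beta)
      e <- yt - Xb - pen_eff[pen_obs]

      # kernel effects in the eigenbasis: diagonal full conditional
      alpha_mean <- vector("list", length(kn))
      names(alpha_mean) <- kn
      for (k in kn) {
        if (s2[[k]] <= 0) {
          alpha_mean[[k]] <- alpha[[k]]
          next
        }
        b <- bases[[k]]
        v <- drop(crossprod(b$W, e)) + b$lambda * alpha[[k]]
        cprec <- b$lambda / s2[["residual"]] + 1 / s2[[k]]
        amean <- (v / s2[["residual"]]) / cprec
        a_new <- amean + rnorm(b$r) / sqrt(cprec)
        u_new <- drop(b$W %*% a_new)
        e <- e + u[[k]] - u_new
        alpha[[k]] <- a_new
        u[[k]] <- u_new
        alpha_mean[[k]] <- amean
        if (!is_fixed(k)) {
          s2[[k]] <- (df0 * S0[[k]] + sum(a_new^2)) / rchisq(1, df0 + b$r)
        }
      }

      # residual variance
      if (!is_fixed("residual")) {
        s2[["residual"]] <- (df0 * S0[["residual"]] + sum(e^2)) /
          rchisq(1, df0 + n_obs)
      }

      # guard against residual drift
      if (it %% 2000L == 0L) {
        e <- yo - Xb - pen_eff[pen_obs] - Reduce(`+`, u, numeric(n_obs))
      }

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L &&
          kept < n_keep) {
        # Rao-Blackwellized accumulation: averaging the conditional means
        # of each block (given the current draws of the others) estimates
        # the same posterior means as averaging the draws, with a much
        # smaller Monte Carlo error.
        kept <- kept + 1L
        draws[kept, ] <- s2
        beta_acc <- beta_acc + bmean
        pen_acc <- pen_acc + pen_mean
        for (k in kn) {
          amean_acc[[k]] <- amean_acc[[k]] + alpha_mean[[k]]
        }
      }
    }

    draws <- tibble::as_tibble(draws[seq_len(kept), , drop = FALSE])
    beta_hat <- beta_acc / kept
    pen_hat <- pen_acc / kept
    # posterior-mean effects for all animals via the kernel projection
    u_hat <- lapply(kn, function(k) {
      setNames(drop(bases[[k]]$P %*% (amean_acc[[k]] / kept)), ids)
    })
    names(u_hat) <- kn
    penvec <- ifelse(is.na(pen_idx), 0, pen_hat[pen_idx])
    yhat <- drop(X %*% beta_hat) + penvec +
      Reduce(`+`, u_hat, numeric(n))
    structure(list(
      trait = trait, model = spec$model, stage = spec$stage,
      complexity = spec$complexity,
      draws = draws,
      summary = summarize_posterior(draws),
      coef_fixed = setNames(beta_hat, colnames(X)),
      pen_effects = setNames(pen_hat, pen_levels),
      u = u_hat,
      yhat = setNames(yhat, ids),
      animal_id = ids, missing = !obs, y = y,
      mcmc = mcmc, n_obs = n_obs
    ), class = "rkhs_fit")
  })
}

#' @export
print.rkhs_fit <- function(x, ...) {
  cat(sprintf("<rkhs_fit %s> trait %s, %d records (%d masked), %d draws\n",
              x$model, x$trait, length(x$animal_id), sum(x$missing),
              nrow(x$draws)))
  print(x$summary)
  invisible(x)
}

# Effective sample size via the autocorrelation time, truncating the
# lagged sum at the first negative pair (Geyer's initial positive
# sequence).
ess_estimate <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  rho <- drop(acf(x, lag.max = min(1000L, n - 2L), plot = FALSE,
                  demean = TRUE)$acf)[-1]
  npair <- length(rho) %/% 2
  tau <- 1
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g < 0) break
    tau <- tau + 2 * g
  }
  n / tau
}

#' Summarize posterior variance draws
#'
#' Computes per-draw variance fractions (each component's variance divided
#' by the sum of all random-effect variances plus the residual, pen
#' included), their posterior means and SDs, and effective sample sizes.
#' The fraction for the genomic component is the heritability `h2`, for
#' the microbial component the microbiability `m2`, and for the
#' interaction component `i2`.
#'
#' @param draws Data frame or matrix of variance draws with columns named
#'   `sigma2_<component>`, one of which must be `sigma2_residual`.
#' @return A tibble of class `posterior_summary` with one row per
#'   component; the per-draw fraction matrix is attached as attribute
#'   `"fraction_draws"`.
#' @export
summarize_posterior <- function(draws) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 1) abort("At least one retained draw is required.")
  cols <- grep("^sigma2_", names(draws), value = TRUE)
  if (!"sigma2_residual" %in% cols) {
    abort("`draws` must contain a `sigma2_residual` column.")
  }
  V <- as.matrix(draws[cols])
  comp <- sub("^sigma2_", "", cols)
  tot <- rowSums(V)
  frac <- V / tot
  labels <- c(additive = "h2", microbiome = "m2", interaction = "i2",
              pen = "pen2", residual = "e2")
  out <- tibble::tibble(
    component = comp,
    fraction = unname(labels[comp]),
    var_mean = unname(colMeans(V)),
    var_sd = unname(apply(V, 2, sd)),
    frac_mean = unname(colMeans(frac)),
    frac_sd = unname(apply(frac, 2, sd)),
    ess = unname(apply(V, 2, ess_estimate))
  )
  out$fraction[is.na(out$fraction)] <- out$component[is.na(out$fraction)]
  colnames(frac) <- out$fraction
  attr(out, "fraction_draws") <- frac
  class(out) <- c("posterior_summary", class(out))
  out
}

#' Predictions for masked records
#'
#' Extracts the posterior-mean fitted values (fixed part plus pen effect
#' where the pen was observed in training, plus all kernel effects) for
#' the records whose trait value was missing at fit time.
#'
#' @param fit An [rkhs_fit()] object.
#' @return Tibble with `animal_id` and `y_hat`, one row per masked record.
#' @export
predict_masked <- function(fit) {
  stopifnot(inherits(fit, "rkhs_fit"))
  tibble::tibble(animal_id = fit$animal_id[fit$missing],
                 y_hat = unname(fit$yhat[fit$missing]))
}
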