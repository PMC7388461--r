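# Independent oracles used across the suite. These deliberately use naive
# double loops and direct generalized-least-squares algebra, not the
# package's own code paths.

# VanRaden GRM by an element-by-element double loop.
grm_oracle <- function(dos, p = colMeans(dos) / 2) {
  n <- nrow(dos)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n, dimnames = list(rownames(dos), rownames(dos)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- sum((dos[i, ] - 2 * p) * (dos[j, ] - 2 * p)) / denom
    }
  }
  G
}

# Microbial kernel by a double-loop dot product.
mkernel_oracle <- function(X) {
  n <- nrow(X)
  q <- ncol(X)
  M <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- sum(X[i, ] * X[j, ]) / q
    }
  }
  M
}

# Mixed-model (GLS) oracle: BLUE of fixed effects and BLUP of kernel and
# pen effects with known variance components, plus fitted values for all
# animals (kernel effects projected onto masked animals; pen effects only
# for pens observed in training).
blup_oracle <- function(y, X, pen, kernels, var_k, var_pen, var_e) {
  obs <- !is.na(y)
  pen <- as.character(pen)
  pen_lvl <- sort(unique(pen[obs]))
  Z <- outer(pen, pen_lvl, `==`) * 1
  Zo <- Z[obs, , drop = FALSE]
  V <- diag(var_e, sum(obs)) + var_pen * tcrossprod(Zo)
  for (i in seq_along(kernels)) {
    V <- V + var_k[i] * kernels[[i]][obs, obs]
  }
  Vi <- solve(V)
  Xo <- X[obs, , drop = FALSE]
  beta <- solve(t(Xo) %*% Vi %*% Xo, t(Xo) %*% Vi %*% y[obs])
  r <- Vi %*% (y[obs] - Xo %*% beta)
  u <- lapply(seq_along(kernels), function(i) {
    drop(var_k[i] * kernels[[i]][, obs] %*% r)
  })
  pen_eff <- drop(var_pen * crossprod(Zo, r))
  fitted <- drop(X %*% beta) + Reduce(`+`, u, numeric(length(y))) +
    drop(Z %*% pen_eff)
  list(beta = drop(beta), u = u, pen = pen_eff, fitted = fitted)
}

# Small simulated bundle shared by several tests.
small_bundle <- function(n_sires = 8, progeny = 10, markers = 400,
                         otus = 60, depth = 1000, seed = 11, n_cg = 2,
                         ...) {
  cfg <- sim_config(n_sires = n_sires, progeny_per_sire = progeny,
                    n_markers = markers, n_otu = otus,
                    sequencing_depth = depth, seed = seed,
                    n_contemporary_groups = n_cg, ...)
  pop <- simulate_population(cfg)
  tab <- simulate_otu_table(cfg, "Wean")
  G <- build_grm(pop$panel)
  M <- suppressMessages(
    build_microbial_kernel(log_standardize_otu(relative_abundance(tab))))
  sim <- simulate_phenotypes(G, M, pop$design, cfg)
  list(cfg = cfg, pop = pop, tab = tab, G = G, M = M,
       records = sim$records, components = sim$components)
}
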