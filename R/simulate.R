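# Synthetic hologenomic study generator: a half-sib pig population with
# genotypes, stage-wise gut microbiome compositions, and phenotypes built
# as the sum of fixed effects, pen, genomic, microbial, genome-by-microbiome
# and residual deviations with a known variance partition.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a
#' paternal half-sib design (single-sire, single-sex pens nested in
#' contemporary groups), biallelic marker genotypes, logistic-normal OTU
#' compositions per growth stage, and phenotypes with configurable variance
#' fractions.
#'
#' @param n_sires Number of sires (default 28).
#' @param progeny_per_sire Progeny per sire (default 20).
#' @param n_markers Number of biallelic markers.
#' @param maf_range Range of minor allele frequencies markers are drawn
#'   from, within `(0, 0.5]`.
#' @param n_otu Number of OTU per stage.
#' @param n_stages Number of growth stages.
#' @param stage_labels Labels for the stages.
#' @param sequencing_depth Multinomial counts per microbiome sample.
#' @param n_contemporary_groups Number of contemporary groups pens are
#'   nested in (default 6).
#' @param pigs_per_pen Pen size; pens are single-sire and single-sex
#'   (default 20).
#' @param var_fractions Named numeric with entries `additive`,
#'   `microbiome`, `interaction`, `pen`, `residual`, non-negative and
#'   summing to 1; or a list of such vectors, one per trait.
#' @param n_traits Number of traits to simulate.
#' @param fixed_effect_sizes Named list with elements `dam_line`, `sex`
#'   (half-difference between the two levels, in phenotypic SD units) and
#'   `contemporary_group` (SD of the group effects).
#' @param total_variance Total phenotypic variance excluding fixed effects.
#' @param otu_log_sd SD of the baseline log-abundance profile across OTU
#'   (0 gives symmetric latent means).
#' @param otu_latent_sd SD of the per-animal latent log-abundance noise.
#' @param otu_latent_cor Share of latent variance carried by a shared
#'   per-animal factor, inducing correlation among OTU.
#' @param host_assoc_strength Scale of the optional genome-to-microbiome
#'   dependence channel (used only when a host covariate is supplied).
#' @param seed Root seed; all generator streams are derived from it by
#'   named substreams.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 28,
                       progeny_per_sire = 20,
                       n_markers = 5000,
                       maf_range = c(0.05, 0.5),
                       n_otu = 500,
                       n_stages = 3,
                       stage_labels = c("Wean", "Mid-test", "Off-test"),
                       sequencing_depth = 10000,
                       n_contemporary_groups = 6,
                       pigs_per_pen = 20,
                       var_fractions = c(additive = 0.30, microbiome = 0.20,
                                         interaction = 0.10, pen = 0.05,
                                         residual = 0.35),
                       n_traits = 1,
                       fixed_effect_sizes = list(dam_line = 0.25,
                                                 sex = 0.25,
                                                 contemporary_group = 0.30),
                       total_variance = 1,
                       otu_log_sd = 1.5,
                       otu_latent_sd = 1,
                       otu_latent_cor = 0.3,
                       host_assoc_strength = 0.5,
                       seed = 1) {
  assert_scalar_count(n_sires, "n_sires")
  assert_scalar_count(progeny_per_sire, "progeny_per_sire")
  assert_scalar_count(n_markers, "n_markers")
  assert_scalar_count(n_otu, "n_otu", min = 2L)
  assert_scalar_count(n_stages, "n_stages")
  assert_scalar_count(sequencing_depth, "sequencing_depth")
  assert_scalar_count(n_contemporary_groups, "n_contemporary_groups")
  assert_scalar_count(pigs_per_pen, "pigs_per_pen")
  assert_scalar_count(n_traits, "n_traits")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  stage_labels <- as.character(stage_labels)
  if (length(stage_labels) < n_stages) {
    abort("Need at least `n_stages` stage labels.")
  }
  stage_labels <- stage_labels[seq_len(n_stages)]

  if (is.numeric(var_fractions)) {
    var_fractions <- rep(list(var_fractions), n_traits)
  }
  if (length(var_fractions) != n_traits) {
    abort("`var_fractions` must have one entry per trait.")
  }
  needed <- c("additive", "microbiome", "interaction", "pen", "residual")
  var_fractions <- lapply(var_fractions, function(v) {
    if (!all(needed %in% names(v))) {
      abort(paste("Each var_fractions vector needs components:",
                  paste(needed, collapse = ", ")))
    }
    v <- v[needed]
    if (any(v < 0)) abort("Variance fractions must be non-negative.")
    if (abs(sum(v) - 1) > 1e-12) {
      abort("Variance fractions must sum to 1 (within 1e-12).")
    }
    v
  })

  structure(
    list(n_sires = as.integer(n_sires),
         progeny_per_sire = as.integer(progeny_per_sire),
         n_markers = as.integer(n_markers),
         maf_range = as.numeric(maf_range),
         n_otu = as.integer(n_otu),
         n_stages = as.integer(n_stages),
         stage_labels = stage_labels,
         sequencing_depth = as.integer(sequencing_depth),
         n_contemporary_groups = as.integer(n_contemporary_groups),
         pigs_per_pen = as.integer(pigs_per_pen),
         var_fractions = var_fractions,
         n_traits = as.integer(n_traits),
         fixed_effect_sizes = fixed_effect_sizes,
         total_variance = total_variance,
         otu_log_sd = otu_log_sd,
         otu_latent_sd = otu_latent_sd,
         otu_latent_cor = otu_latent_cor,
         host_assoc_strength = host_assoc_strength,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d sires x %d progeny, %d markers, ",
                     "%d OTU x %d stages, %d traits, seed %d\n"),
              x$n_sires, x$progeny_per_sire, x$n_markers, x$n_otu,
              x$n_stages, x$n_traits, x$seed))
  invisible(x)
}

animal_id_labels <- function(n) sprintf("A%04d", seq_len(n))

#' Simulate a half-sib population with genotypes and design factors
#'
#' Each sire carries two alleles per marker; every progeny receives one
#' allele sampled from the sire's pair and one allele drawn from the
#' population frequency, inducing the half-sib genomic covariance of 0.25.
#' Markers are simulated independently (no linkage): the downstream kernels
#' depend only on the relationship structure, which half-sib sampling
#' provides. Pens are single-sire and single-sex, nested in contemporary
#' groups; dam line is assigned at random per animal.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (a [genotype_panel()]) and `design`, a
#'   tibble with columns `animal_id`, `sire_id`, `dam_line`, `sex`,
#'   `contemporary_group`, `pen_id`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_s <- config$n_sires
  k <- config$progeny_per_sire
  m <- config$n_markers
  n <- n_s * k
  ids <- animal_id_labels(n)
  sire_ids <- sprintf("S%02d", seq_len(n_s))

  dosage <- with_seed(substream_seed(config$seed, "genotypes"), {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    # sire allele pairs, one row per sire
    a1 <- matrix(rbinom(n_s * m, 1L, rep(p, each = n_s)), n_s, m)
    a2 <- matrix(rbinom(n_s * m, 1L, rep(p, each = n_s)), n_s, m)
    out <- matrix(0, n, m)
    for (s in seq_len(n_s)) {
      rows <- (s - 1L) * k + seq_len(k)
      pick <- matrix(rbinom(k * m, 1L, 0.5), k, m)
      sire_allele <- pick * matrix(a1[s, ], k, m, byrow = TRUE) +
        (1 - pick) * matrix(a2[s, ], k, m, byrow = TRUE)
      dam_allele <- matrix(rbinom(k * m, 1L, rep(p, each = k)), k, m)
      out[rows, ] <- sire_allele + dam_allele
    }
    out
  })
  dimnames(dosage) <- list(ids, sprintf("SNP%05d", seq_len(m)))

  design <- with_seed(substream_seed(config$seed, "design"), {
    sire <- rep(sire_ids, each = k)
    pens_per_sire <- ceiling(k / config$pigs_per_pen)
    pen_within <- rep(rep(seq_len(pens_per_sire),
                          each = config$pigs_per_pen)[seq_len(k)],
                      times = n_s)
    pen_global <- (rep(seq_len(n_s), each = k) - 1L) * pens_per_sire +
      pen_within
    pen_id <- sprintf("P%03d", pen_global)
    n_pens <- n_s * pens_per_sire
    # single-sex pens with randomized balanced sexes; contemporary groups
    # cycle over pens so every group spans many sires and survives
    # sire-grouped cross-validation masking. Sexes are reshuffled if the
    # draw happens to confound sex with group (possible with few pens).
    cg_of_pen <- sprintf("CG%d",
                         ((seq_len(n_pens) - 1L) %%
                            config$n_contemporary_groups) + 1L)
    sex_levels <- rep(c("M", "F"), length.out = n_pens)
    sex_of_pen <- sample(sex_levels)
    if (n_pens >= 4 && length(unique(cg_of_pen)) > 1) {
      for (try in seq_len(100)) {
        D <- model.matrix(~ sex_of_pen + cg_of_pen)
        # a full-rank sex + group design may be infeasible for very small
        # pen counts; in that case keep the draw
        if (ncol(D) > n_pens || qr(D)$rank == ncol(D)) break
        sex_of_pen <- sample(sex_levels)
      }
    }
    tibble::tibble(
      animal_id = ids,
      sire_id = sire,
      dam_line = sample(c("DL1", "DL2"), n, replace = TRUE),
      sex = sex_of_pen[pen_global],
      contemporary_group = cg_of_pen[pen_global],
      pen_id = pen_id
    )
  })

  list(panel = genotype_panel(dosage), design = design)
}

#' Simulate an OTU count table for one growth stage
#'
#' Per animal, a latent log-abundance vector is drawn from a correlated
#' normal model (a shared per-animal factor plus independent noise around a
#' baseline OTU profile), mapped to relative abundances by the logistic
#' (softmax) transform, and sampled as multinomial counts at the configured
#' sequencing depth. An optional host covariate shifts the latent means to
#' induce genome-microbiome dependence.
#'
#' @param config A [sim_config()].
#' @param stage Stage label; must be one of `config$stage_labels`.
#' @param host_covariate Optional named numeric vector (one value per
#'   animal) inducing dependence of the microbiome on the host; `NULL`
#'   (default) gives a microbiome independent of the genome.
#' @param ids Sample ids; defaults to the full population of the config.
#' @return An [otu_table()] with counts summing to `sequencing_depth` per
#'   sample.
#' @export
simulate_otu_table <- function(config, stage, host_covariate = NULL,
                               ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!stage %in% config$stage_labels) {
    abort(sprintf("Unknown stage '%s'.", stage))
  }
  if (config$sequencing_depth < 1) abort("Sequencing depth must be >= 1.")
  n <- config$n_sires * config$progeny_per_sire
  if (is.null(ids)) ids <- animal_id_labels(n)
  n <- length(ids)
  q <- config$n_otu
  if (!is.null(host_covariate)) {
    if (is.null(names(host_covariate)) ||
        !all(ids %in% names(host_covariate))) {
      abort("`host_covariate` must be named with all sample ids.")
    }
    hc <- as.numeric(scale(host_covariate[ids]))
  }

  counts <- with_seed(substream_seed(config$seed, paste0("otu:", stage)), {
    mu <- rnorm(q, 0, config$otu_log_sd)
    rho <- config$otu_latent_cor
    load <- rnorm(q) * sqrt(rho) * config$otu_latent_sd
    f <- rnorm(n)
    z <- outer(f, load) +
      matrix(rnorm(n * q, 0, sqrt(1 - rho) * config$otu_latent_sd), n, q)
    z <- sweep(z, 2, mu, "+")
    if (!is.null(host_covariate)) {
      gamma <- rnorm(q)
      z <- z + config$host_assoc_strength * outer(hc, gamma)
    }
    # softmax per animal, then multinomial sampling at fixed depth
    pr <- exp(z - apply(z, 1, max))
    pr <- pr / rowSums(pr)
    t(apply(pr, 1, function(p) {
      rmultinom(1, config$sequencing_depth, p)[, 1]
    }))
  })
  dimnames(counts) <- list(ids, sprintf("OTU%04d", seq_len(q)))
  otu_table(counts, stage = stage)
}

# Expected sample variance of a kernel-structured effect per unit variance
# parameter: E[var_hat(u)] = (tr(K)/n - mean(K)) * sigma^2.
kernel_var_scale <- function(K) {
  n <- nrow(K)
  s <- sum(diag(K)) / n - mean(K)
  if (s <= 0) 0 else s
}

draw_kernel_effect <- function(ed, sigma2) {
  lam <- pmax(ed$values, 0)
  as.numeric(ed$vectors %*% (sqrt(lam * sigma2) * rnorm(length(lam))))
}

#' Simulate phenotypes with a known variance partition
#'
#' Phenotypes are built as the sum of fixed effects (dam line, sex,
#' contemporary group), an iid pen effect, a genomic deviation with
#' covariance `G`, a microbial deviation with covariance `M`, a
#' genome-by-microbiome deviation with covariance the Hadamard product of
#' `G` and `M`, and an iid residual. Variance parameters are scaled so the
#' expected realized sample variance of each component equals its target
#' fraction of the total.
#'
#' @param G,M [relationship_kernel()] objects indexed by the same animals
#'   as `design` (eigenvalues in `[-1e-8, 0)` are clipped to 0).
#' @param design Design tibble from [simulate_population()].
#' @param config A [sim_config()].
#' @return A list with `records` (tibble of design factors plus one column
#'   per trait) and `components` (long tibble of the realized fixed,
#'   additive, microbiome, interaction, pen and residual deviations per
#'   animal and trait; the phenotype equals their sum exactly).
#' @export
simulate_phenotypes <- function(G, M, design, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- design$animal_id
  if (!identical(animal_ids(G), ids) || !identical(animal_ids(M), ids)) {
    abort("`G` and `M` must be indexed by the animals of `design`, in order.")
  }
  n <- length(ids)
  Gm <- as.matrix(G)
  Mm <- as.matrix(M)
  GxM <- Gm * Mm
  check_psd <- function(K, lab) {
    if (min_eigenvalue(K) < -1e-8) {
      abort(sprintf("Kernel %s is not numerically PSD.", lab))
    }
  }
  check_psd(Gm, "G"); check_psd(Mm, "M"); check_psd(GxM, "GxM")
  eds <- list(additive = eigen(Gm, symmetric = TRUE),
              microbiome = eigen(Mm, symmetric = TRUE),
              interaction = eigen(GxM, symmetric = TRUE))
  scales <- c(additive = kernel_var_scale(Gm),
              microbiome = kernel_var_scale(Mm),
              interaction = kernel_var_scale(GxM))

  fes <- config$fixed_effect_sizes
  vt <- config$total_variance
  pen_f <- factor(design$pen_id)

  with_seed(substream_seed(config$seed, "phenotypes"), {
    cg_levels <- sort(unique(design$contemporary_group))
    cg_eff <- rnorm(length(cg_levels), 0, fes$contemporary_group) * sqrt(vt)
    names(cg_eff) <- cg_levels
    fixed_part <- unname(
      (ifelse(design$dam_line == "DL2", 1, -1) * fes$dam_line +
         ifelse(design$sex == "M", 1, -1) * fes$sex) * sqrt(vt) +
        cg_eff[design$contemporary_group])

    records <- design
    comps <- vector("list", config$n_traits)
    for (t in seq_len(config$n_traits)) {
      fr <- config$var_fractions[[t]]
      sig2 <- function(name, scale) {
        if (fr[[name]] == 0 || scale == 0) 0 else fr[[name]] * vt / scale
      }
      a <- draw_kernel_effect(eds$additive, sig2("additive",
                                                 scales["additive"]))
      o <- draw_kernel_effect(eds$microbiome, sig2("microbiome",
                                                   scales["microbiome"]))
      ao <- draw_kernel_effect(eds$interaction, sig2("interaction",
                                                     scales["interaction"]))
      pen_eff <- rnorm(nlevels(pen_f), 0, sqrt(fr[["pen"]] * vt))
      pen <- pen_eff[as.integer(pen_f)]
      e <- rnorm(n, 0, sqrt(fr[["residual"]] * vt))
      y <- fixed_part + a + o + ao + pen + e
      trait <- sprintf("trait_%d", t)
      records[[trait]] <- y
      comps[[t]] <- tibble::tibble(
        animal_id = ids, trait = trait, fixed = unname(fixed_part),
        additive = a, microbiome = o, interaction = ao,
        pen = pen, residual = e, y = unname(y))
    }
    list(records = records, components = dplyr::bind_rows(comps))
  })
}
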