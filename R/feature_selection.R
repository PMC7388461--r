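# Single-feature preselection scans. Each marker dosage or OTU relative
# abundance is tested as a linear covariate in a least-squares model with
# dam line, contemporary group, sex, pen and sire as nuisance factors. The
# design is projected out once and each residualized feature regressed on
# the residualized phenotype, which is mathematically identical to the
# per-feature full fit but orders of magnitude faster for 40k markers.

#' Single-feature association scan
#'
#' For each feature, fits `y = mu + dam line + contemporary group + sex +
#' pen + sire + beta * feature + e` by least squares and reports the Wald
#' p-value for `beta`. Features collinear with the design (zero residual
#' variance after projection) get a missing p-value and are reported.
#'
#' @param records Training-fold tibble with `animal_id`, `sire_id`,
#'   `dam_line`, `contemporary_group`, `sex`, `pen_id` and the trait.
#' @param features A [genotype_panel()] (dosages; feature type "marker")
#'   or a numeric matrix of OTU relative abundances with animal row names
#'   (feature type "OTU"). Rows must match `records$animal_id`.
#' @param trait Trait column name.
#' @param stage,fold Optional labels carried into the result.
#' @return A `scan_result` tibble: `feature_id`, `feature_type`,
#'   `estimate`, `std_error`, `p_value`, `trait`, `stage`, `fold`.
#' @export
scan_features <- function(records, features, trait, stage = NA_character_,
                          fold = NA_integer_) {
  if (inherits(features, "genotype_panel")) {
    F_mat <- features$dosage
    type <- "marker"
  } else if (is.matrix(features)) {
    F_mat <- features
    type <- "OTU"
  } else {
    abort("`features` must be a genotype_panel or a numeric matrix.")
  }
  if (!identical(rownames(F_mat), records$animal_id)) {
    abort("Feature rows must match `records$animal_id` in order.")
  }
  y <- records[[trait]]
  if (anyNA(y)) abort("Training records must have no missing phenotypes.")
  if (length(unique(records$sire_id)) < 2) {
    abort("The sire factor needs at least 2 levels.")
  }

  nuisance <- c("dam_line", "contemporary_group", "sex", "pen_id", "sire_id")
  df <- as.data.frame(lapply(records[nuisance], factor))
  active <- names(df)[vapply(df, nlevels, 0L) > 1]
  D <- model.matrix(if (length(active)) stats::reformulate(active) else ~1,
                    df)
  qrD <- qr(D)
  Q <- qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]
  n <- length(y)
  rdf <- n - qrD$rank - 1L
  if (rdf < 1) abort("Not enough residual degrees of freedom for the scan.")

  yr <- y - Q %*% crossprod(Q, y)
  Fr <- F_mat - Q %*% crossprod(Q, F_mat)
  sxx <- colSums(Fr^2)
  syy <- sum(yr^2)
  # collinear with the design: essentially no residual feature variance
  ok <- sxx > 1e-10 * pmax(colSums(F_mat^2), 1)
  sxy <- drop(crossprod(Fr, yr))
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- pmax(syy - beta^2 * sxx, 0)
  sigma2 <- rss / rdf
  se <- ifelse(ok, sqrt(sigma2 / sxx), NA_real_)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = rdf)
  if (any(!ok)) {
    inform(sprintf("scan_features: %d feature(s) collinear with the design.",
                   sum(!ok)))
  }
  out <- tibble::tibble(
    feature_id = colnames(F_mat),
    feature_type = type,
    estimate = unname(beta),
    std_error = unname(se),
    p_value = unname(pval),
    trait = trait, stage = stage, fold = fold
  )
  class(out) <- c("scan_result", class(out))
  out
}

#' Bonferroni-informative feature selection
#'
#' Retains features with `p < alpha / q`, where `q` is the number of
#' tested features of the same type within the scan (markers and OTU are
#' corrected separately, since they enter separate kernels).
#'
#' @param scan A `scan_result` tibble from [scan_features()]; may mix
#'   feature types.
#' @param alpha Family-wise significance level.
#' @return Character vector of retained feature ids. Raises a condition
#'   of class `hologen_no_informative_features` when the selection is
#'   empty; callers running cross-validation catch it and mark the cell
#'   not estimable.
#' @export
select_informative <- function(scan, alpha = 0.05) {
  if (nrow(scan) == 0) abort("`scan` is empty.")
  sel <- scan |>
    dplyr::group_by(.data$feature_type) |>
    dplyr::mutate(.q = sum(!is.na(.data$p_value))) |>
    dplyr::filter(!is.na(.data$p_value),
                  .data$p_value < alpha / .data$.q) |>
    dplyr::ungroup()
  if (nrow(sel) == 0) {
    abort("No feature passed the Bonferroni threshold.",
          class = "hologen_no_informative_features")
  }
  sel$feature_id
}

#' Random size-matched feature selection
#'
#' Uniform sample of `k` feature ids without replacement; `k` is taken
#' from the matched informatively-reduced set so the randomly reduced set
#' is size-comparable.
#'
#' @param ids Character vector of available feature ids.
#' @param k Number of features to sample.
#' @param seed Seed making the draw reproducible.
#' @return Character vector of `k` feature ids.
#' @export
select_random <- function(ids, k, seed = 1) {
  assert_scalar_count(k, "k", min = 1L)
  if (k > length(ids)) {
    abort(sprintf("k = %d exceeds the %d available features.",
                  k, length(ids)))
  }
  with_seed(seed, sample(ids, k))
}
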