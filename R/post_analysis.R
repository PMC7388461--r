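# Factorial post-analysis of predictive abilities pooled over the design
# grid: trait, stage, model, complexity and fold main effects plus the
# stage:model, stage:complexity, model:complexity, trait:stage,
# trait:model and trait:complexity interactions, tested with type-III sums
# of squares under sum-to-zero coding (type-III tests are coding-dependent
# and this is the standard convention), followed by least-squares means
# and Tukey-adjusted pairwise contrasts.

cv_factors <- c("trait", "stage", "model", "complexity", "fold")
cv_interactions <- c("stage:model", "stage:complexity",
                     "model:complexity", "trait:stage", "trait:model",
                     "trait:complexity")

#' Type-III factorial ANOVA of a cross-validation grid
#'
#' Fits `response ~ trait + stage + model + complexity + fold` plus the
#' pairwise interactions involving stage, model, complexity and trait, by
#' least squares with sum-to-zero factor coding, and tabulates type-III
#' sums of squares with F tests against the residual mean square. Factors
#' absent from the grid, constant, or inestimable (aliased by empty
#' cells) are flagged rather than silently dropped.
#'
#' @param grid A `cv_results` tibble (or any data frame with a subset of
#'   the factor columns `trait`, `stage`, `model`, `complexity`, `fold`
#'   and a numeric response).
#' @param response Response column name (default `"r"`, the predictive
#'   ability).
#' @return A list of class `factorial_anova` with elements `anova` (a
#'   tibble: term, sum_sq, df, mean_sq, statistic, p_value), `fit` (the
#'   underlying `lm`), and `flagged` (inestimable terms, if any).
#' @export
fit_factorial_anova <- function(grid, response = "r") {
  grid <- as.data.frame(grid)
  if (!response %in% names(grid)) {
    abort(sprintf("Response `%s` not found.", response))
  }
  grid <- grid[is.finite(grid[[response]]), , drop = FALSE]
  if (nrow(grid) < 2) abort("Need at least two finite responses.")
  present <- intersect(cv_factors, names(grid))
  for (v in present) grid[[v]] <- factor(grid[[v]])
  active <- present[vapply(grid[present], nlevels, 0L) > 1]
  if (!length(active)) abort("No factor with more than one level.")
  inter <- Filter(function(tm) {
    all(strsplit(tm, ":")[[1]] %in% active)
  }, cv_interactions)
  fml <- stats::reformulate(c(active, inter), response = response)
  contr <- setNames(replicate(length(active), "contr.sum",
                              simplify = FALSE), active)
  fit <- stats::lm(fml, data = grid, contrasts = contr)

  flagged <- character()
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias)) {
    flagged <- unique(unlist(lapply(
      c(active, inter),
      function(tm) if (any(grepl(gsub(":", ".*:", tm),
                                 rownames(alias)))) tm)))
    warn(paste("Inestimable (aliased) terms:",
               paste(flagged, collapse = ", ")))
  }

  if (sd(grid[[response]]) == 0) {
    # degenerate response: zero residual SS, F undefined
    tab <- tibble::tibble(term = c(active, inter, "Residuals"),
                          sum_sq = 0, df = NA_integer_,
                          mean_sq = 0, statistic = NA_real_,
                          p_value = NA_real_)
  } else {
    a3 <- car::Anova(fit, type = 3)
    tab <- tibble::as_tibble(as.data.frame(a3), rownames = "term") |>
      dplyr::rename(sum_sq = "Sum Sq", df = "Df",
                    statistic = "F value", p_value = "Pr(>F)") |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::mutate(mean_sq = .data$sum_sq / .data$df,
                    .after = "df")
  }
  structure(list(anova = tab, fit = fit, flagged = flagged,
                 response = response),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("<factorial_anova> response `%s`, type-III tests\n",
              x$response))
  print(as.data.frame(x$anova), digits = 4)
  invisible(x)
}

#' @method tidy factorial_anova
#' @export
tidy.factorial_anova <- function(x, ...) x$anova

#' @method glance factorial_anova
#' @export
glance.factorial_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma,
                 df_residual = x$fit$df.residual,
                 nobs = length(x$fit$fitted.values))
}

#' Least-squares means and pairwise contrasts
#'
#' Estimated marginal means for a fitted factor (or interaction), with
#' pairwise differences, standard errors from the coefficient covariance,
#' and multiplicity-adjusted p-values.
#'
#' @param fit A [fit_factorial_anova()] object.
#' @param term Factor or interaction name present in the fitted model
#'   (e.g. `"model"`, `"stage:model"`).
#' @param adjust Multiplicity adjustment for the pairwise contrasts:
#'   `"tukey"` (default), `"bonferroni"` or `"none"`.
#' @return A list of class `lsmeans_result` with tibbles `means` and
#'   `contrasts`.
#' @export
lsmeans_contrasts <- function(fit, term, adjust = c("tukey", "bonferroni",
                                                    "none")) {
  stopifnot(inherits(fit, "factorial_anova"))
  adjust <- match.arg(adjust)
  terms_in <- attr(stats::terms(fit$fit), "term.labels")
  norm <- function(tm) {
    vapply(strsplit(tm, ":"), function(p) paste(sort(p), collapse = ":"),
           "")
  }
  if (!norm(term) %in% norm(terms_in)) {
    abort(sprintf("Term `%s` is not in the fitted model.", term))
  }
  emm <- emmeans::emmeans(fit$fit, stats::reformulate(strsplit(
    term, ":")[[1]]))
  means <- tibble::as_tibble(as.data.frame(emm))
  ctr <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = adjust)))
  structure(list(means = means, contrasts = ctr, term = term,
                 adjust = adjust),
            class = "lsmeans_result")
}

#' @export
print.lsmeans_result <- function(x, ...) {
  cat(sprintf("<lsmeans_result> term `%s` (%s-adjusted contrasts)\n",
              x$term, x$adjust))
  print(as.data.frame(x$means), digits = 4)
  invisible(x)
}

#' @method tidy lsmeans_result
#' @export
tidy.lsmeans_result <- function(x, ...) x$means
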