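# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @method tidy rkhs_fit
#' @export
tidy.rkhs_fit <- function(x, ...) {
  out <- x$summary
  class(out) <- class(tibble::tibble())
  dplyr::mutate(out, trait = x$trait, model = x$model, .before = 1)
}

#' @method glance rkhs_fit
#' @export
glance.rkhs_fit <- function(x, ...) {
  s <- x$summary
  pick <- function(lbl) {
    v <- s$frac_mean[s$fraction == lbl]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    trait = x$trait, model = x$model,
    stage = x$stage %||% NA_character_,
    complexity = x$complexity,
    n = length(x$animal_id), n_masked = sum(x$missing),
    n_draws = nrow(x$draws),
    h2 = pick("h2"), m2 = pick("m2"), i2 = pick("i2"),
    pen2 = pick("pen2"), e2 = pick("e2"),
    min_ess = min(s$ess, na.rm = TRUE)
  )
}

#' @method autoplot posterior_summary
#' @export
autoplot.posterior_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                   y = .data$frac_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$frac_mean - 2 * .data$frac_sd, 0),
      ymax = pmin(.data$frac_mean + 2 * .data$frac_sd, 1)), width = 0.2) +
    ggplot2::labs(x = NULL, y = "posterior mean variance fraction") +
    ggplot2::theme_minimal()
}

#' @method autoplot rkhs_fit
#' @export
autoplot.rkhs_fit <- function(object, ...) {
  fr <- attr(object$summary, "fraction_draws")
  df <- tibble::as_tibble(fr) |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "fraction",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~fraction, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = "variance fraction",
                  title = sprintf("%s, trait %s", object$model,
                                  object$trait)) +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_results
#' @export
autoplot.cv_results <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$estimable)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$r,
                                        fill = .data$complexity)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "model", y = "predictive ability (Pearson r)") +
    ggplot2::theme_minimal()
  if (length(unique(df$stage)) > 1 || length(unique(df$trait)) > 1) {
    p <- p + ggplot2::facet_grid(trait ~ stage)
  }
  p
}

#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~feature_type, scales = "free_x") +
    ggplot2::labs(x = "feature index", y = "-log10 p") +
    ggplot2::theme_minimal()
}
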