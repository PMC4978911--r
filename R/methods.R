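#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a rate regression
#'
#' @param x A `rate_regression` from [loglog_regression()] or
#'   [origin_regression()].
#' @param ... Unused.
#' @return Tibble with one row per coefficient: term, estimate, std.error,
#'   statistic, p.value.
#' @export
tidy.rate_regression <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of a rate regression
#'
#' @inheritParams tidy.rate_regression
#' @return Tibble: r.squared, slope, intercept, p.value, df, nobs,
#'   through_origin.
#' @export
glance.rate_regression <- function(x, ...) {
  tibble(r.squared = x$r2, slope = x$slope, intercept = x$intercept,
         p.value = x$p_value, df = x$df, nobs = x$n,
         through_origin = x$through_origin)
}

#' Tidy a drift-barrier report
#'
#' @param x A `drift_barrier_report` from [reproduce_analysis()].
#' @param ... Unused.
#' @return Tibble with one row per fit: fit name plus [glance()] columns.
#' @export
tidy.drift_barrier_report <- function(x, ...) {
  purrr::imap_dfr(x$fits, ~ mutate(glance(.x), fit = .y)) %>%
    select("fit", dplyr::everything())
}

#' Plot a rate regression
#'
#' Scatter of the (log-scale or contrast) data with the fitted line;
#' through-origin fits are drawn through zero.
#'
#' @param object A `rate_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_regression <- function(object, ...) {
  d <- object$data
  names(d) <- c("x", "y")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = if (object$through_origin) object$xlab
          else paste0("log10(", object$xlab, ")"),
      y = if (object$through_origin) object$ylab
          else paste0("log10(", object$ylab, ")"),
      subtitle = sprintf("slope = %.2f (%.2f), r2 = %.2f, P = %.2g",
                         object$slope, object$se_slope, object$r2,
                         object$p_value)) +
    ggplot2::theme_minimal()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Burden-versus-Ne scatter for a species table
#'
#' Convenience plot of log10 genome-wide indel burden against log10 Ne,
#' coloured by taxonomic group, with the OLS fit overlaid.
#'
#' @param records Species tibble (see [read_species_table()]).
#' @param genome Genome-size column for the burden.
#' @return A ggplot object.
#' @export
plot_burden_ne <- function(records, genome = "Ge") {
  recs <- mutational_burden(records, genome = genome)
  fit <- loglog_regression(recs$Ne, recs$burden)
  ggplot2::ggplot(recs, ggplot2::aes(x = log10(.data$Ne),
                                     y = log10(.data$burden),
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "log10(Ne)",
                  y = sprintf("log10(u_id x %s)", genome),
                  subtitle = sprintf("slope = %.2f (%.2f), r2 = %.2f",
                                     fit$slope, fit$se_slope, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Plot independent contrasts with the through-origin fit
#'
#' @param cx,cy Predictor and response `contrast_set`s (or numeric
#'   vectors).
#' @param ... Passed to [origin_regression()].
#' @return A ggplot object.
#' @export
plot_contrasts <- function(cx, cy, ...) {
  fit <- origin_regression(cx, cy, ...)
  autoplot(fit)
}
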