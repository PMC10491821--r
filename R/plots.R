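#' Diagnostic plots for a fitted hormone distribution
#'
#' Quantile-quantile or empirical-vs-fitted CDF diagnostics built from
#' [dist_diagnostics()], or the fitted density over the sample rug.
#'
#' @param object A [hormone_fit] carrying data.
#' @param type `"qq"`, `"cdf"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hormone_fit <- function(object, type = c("qq", "cdf", "density"), ...) {
  type <- match.arg(type)
  lab <- object$label %||% object$family
  if (type == "qq") {
    d <- dist_diagnostics(object)
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$theoretical, .data$empirical)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                             colour = "grey50") +
        ggplot2::geom_point() +
        ggplot2::labs(x = "Theoretical quantile (pg/mL)",
                      y = "Sample quantile (pg/mL)",
                      title = paste("Q-Q:", lab)))
  }
  x <- sort(object$data)
  if (type == "cdf") {
    d <- tibble::tibble(x = x, empirical = seq_along(x) / length(x),
                        fitted = fit_pfun(object)(x))
    d <- tidyr::pivot_longer(d, c("empirical", "fitted"),
                             names_to = "which", values_to = "cdf")
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$cdf,
                                      colour = .data$which)) +
        ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$which == "empirical")) +
        ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$which == "fitted")) +
        ggplot2::labs(x = "Testosterone (pg/mL)", y = "CDF",
                      colour = NULL, title = paste("CDF:", lab)))
  }
  grid <- seq(min(x) * 0.5, max(x) * 1.2, length.out = 400)
  dd <- tibble::tibble(x = grid, density = fit_dfun(object)(grid))
  ggplot2::ggplot(dd, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble::tibble(x = x),
                      ggplot2::aes(x = .data$x), inherit.aes = FALSE) +
    ggplot2::labs(x = "Testosterone (pg/mL)", y = "Density",
                  title = paste("Fitted density:", lab))
}

#' Plot fitted sex-specific densities with a decision rule overlaid
#'
#' Draws the female and male fitted lognormal densities on the log
#' concentration axis and shades the rule's unknown band (if any), with
#' vertical lines at the decision bounds.
#'
#' @param fit_f,fit_m Lognormal [hormone_fit]s.
#' @param rule Optional `threshold_set` or [empirical_rule()].
#' @param xlim Concentration range (pg/mL) to draw.
#' @return A ggplot object.
#' @export
plot_sex_densities <- function(fit_f, fit_m, rule = NULL,
                               xlim = c(1, 5000)) {
  check_lognormal_pair(fit_f, fit_m)
  grid <- exp(seq(log(xlim[1]), log(xlim[2]), length.out = 500))
  d <- dplyr::bind_rows(
    tibble::tibble(x = grid, density = fit_dfun(fit_f)(grid), sex = "F"),
    tibble::tibble(x = grid, density = fit_dfun(fit_m)(grid), sex = "M"))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$density,
                                       colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Testosterone (pg/mL, log scale)", y = "Density",
                  colour = "Sex")
  if (!is.null(rule)) {
    if (rule$female_upper < rule$male_lower) {
      p <- p + ggplot2::annotate("rect", xmin = rule$female_upper,
                                 xmax = rule$male_lower, ymin = -Inf,
                                 ymax = Inf, alpha = 0.15)
    }
    p <- p +
      ggplot2::geom_vline(xintercept = unique(c(rule$female_upper,
                                                rule$male_lower)),
                          linetype = 2, colour = "grey40")
  }
  p
}

#' Plot Monte Carlo assignment tallies
#'
#' Stacked per-true-sex bars of assigned F / M / U counts from a
#' [run_misid()] report.
#'
#' @param object A `misid_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.misid_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$counts, dplyr::starts_with("assigned_"),
                           names_to = "assigned", values_to = "count",
                           names_prefix = "assigned_")
  ggplot2::ggplot(d, ggplot2::aes(.data$true_sex, .data$count,
                                  fill = .data$assigned)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "True sex", y = "Replicates", fill = "Assigned")
}

#' Plot a fitted 4PL curve over its dilution series
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fourpl_fit <- function(object, ...) {
  xr <- range(object$data$concentration)
  grid <- exp(seq(log(xr[1]), log(xr[2]), length.out = 200))
  curve <- tibble::tibble(concentration = grid,
                          response_bb0 = predict_4pl(object, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$concentration, .data$response_bb0)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (pg/mL, log scale)", y = "%B/B0")
}
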