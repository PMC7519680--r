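#' Plot transience estimates against the environmental covariate
#'
#' Mean and 95% confidence band of the estimated transient probability per
#' age-at-first-breeding group, against the covariate when the model includes
#' one (otherwise against the interval index).
#'
#' @param object A `tau_estimates` tibble (see [tau_estimates()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tau_estimates
#' @export
autoplot.tau_estimates <- function(object, ...) {
  xvar <- if ("cov" %in% names(object)) "cov" else "time"
  xlab <- if (xvar == "cov") "density-dependence covariate (standardized)" else "interval"
  dat <- dplyr::arrange(tibble::as_tibble(object), .data$group, .data[[xvar]])
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data[[xvar]], y = .data$tau,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = xlab, y = expression("transient probability" ~ tau),
      colour = "age at first breeding", fill = "age at first breeding"
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2, colour = NA
    )
  }
  p
}

#' Plot a population-growth-rate response surface
#'
#' @param object A `lambda_surface` (see [lambda_surface()]).
#' @param ... Unused.
#' @return A ggplot (filled raster with lambda = 1 contour).
#' @method autoplot lambda_surface
#' @export
autoplot.lambda_surface <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$density, y = .data$tau4, z = .data$lambda
  )) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$lambda)) +
    ggplot2::geom_contour(colour = "white", breaks = 1) +
    ggplot2::scale_fill_viridis_c(name = expression(lambda)) +
    ggplot2::labs(
      x = "population density (0 = good season, 1 = bad season)",
      y = expression("transient probability of 4-year-olds" ~ tau[4])
    ) +
    ggplot2::theme_minimal()
}

#' Compare LTRE contributions with sensitivities
#'
#' Mirrors the retrospective-versus-prospective comparison: parameters with
#' the largest sensitivities (adult survival) are not necessarily those that
#' contributed most to the observed change in growth rate.
#'
#' @param object An `ltre` (see [ltre_decompose()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ltre
#' @export
autoplot.ltre <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::filter(!grepl("^(tau|gamma)[0-9]", .data$parameter), .data$parameter != "x") |>
    tidyr::pivot_longer(c("sensitivity_mean", "contribution"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::mutate(value = ifelse(.data$quantity == "contribution",
      abs(.data$value), .data$value
    ))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$parameter, y = .data$value, fill = .data$quantity
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sensitivity / |contribution|", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-occasion goodness-of-fit contributions
#'
#' @param object A `gof_component` (see [test_3sr()], [test_3sm()]).
#' @param ... Unused.
#' @return A ggplot of per-occasion chi-square contributions.
#' @method autoplot gof_component
#' @export
autoplot.gof_component <- function(object, ...) {
  dat <- tidy(object) |> dplyr::filter(.data$df > 0)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$occasion, y = .data$statistic, fill = .data$method
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "occasion", y = "chi-square contribution",
      title = paste("test", object$name), fill = "method"
    ) +
    ggplot2::theme_minimal()
}
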