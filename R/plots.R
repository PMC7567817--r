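#' Plot a fitted response surface
#'
#' Filled-contour view of the second-order surface over the coded treatment
#' space, with the design points overlaid.
#'
#' @param object A `cue_rsm` fit.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cue_rsm <- function(object, n = 60, ...) {
  grid <- tidyr::crossing(eCO2 = seq(-1, 1, length.out = n),
                          eT = seq(-1, 1, length.out = n))
  grid$fit <- stats::predict(object$lm, newdata = grid)
  lab <- if (object$log_transform) paste0("log ", object$response) else
    object$response
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$eT, y = .data$eCO2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fit)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$fit), colour = "white",
                          linewidth = 0.3) +
    ggplot2::geom_point(data = object$data, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$eT, y = .data$eCO2),
                        shape = 21, fill = "white") +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(
      x = "warming (coded)", y = "CO2 enrichment (coded)",
      title = sprintf("Response surface: %s%s", lab,
                      if (is.na(object$date)) "" else paste0(", ", object$date))
    ) +
    ggplot2::theme_minimal()
}

#' Residual diagnostics for a seasonal GLS fit
#'
#' Standardised residuals (each divided by its date's estimated residual SD)
#' against fitted values, panelled by date.
#'
#' @param object A `cue_gls` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cue_gls <- function(object, ...) {
  e <- object$engine
  df <- dplyr::tibble(
    fitted = e$fitted,
    std_resid = e$residuals / e$sigma[as.character(object$data$date)],
    date = object$data$date
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$std_resid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~date) +
    ggplot2::labs(x = "fitted", y = "standardised residual",
                  title = sprintf("Seasonal GLS diagnostics: %s",
                                  object$response)) +
    ggplot2::theme_minimal()
}

#' Drought-factorial boxplot with Tukey letters
#'
#' @param object A `cue_anova` fit.
#' @param tukey Optional matching `cue_tukey` result; computed if missing.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cue_anova <- function(object, tukey = NULL, ...) {
  if (is.null(tukey)) tukey <- tukey_hsd(object)
  df <- dplyr::tibble(group = as.character(object$data$group),
                      y = object$data$.y)
  lab <- dplyr::left_join(
    df |> dplyr::group_by(.data$group) |>
      dplyr::summarise(ymax = max(.data$y), .groups = "drop"),
    tukey$letters, by = "group"
  )
  ylab <- if (object$log_transform) paste0("log ", object$response) else
    object$response
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$y)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_text(data = lab, ggplot2::aes(y = .data$ymax,
                                                label = .data$letters),
                       vjust = -0.8) +
    ggplot2::labs(x = NULL, y = ylab,
                  title = sprintf("Drought factorial, %s", object$date)) +
    ggplot2::theme_minimal()
}

#' Boxplots of physiology across treatments and dates
#'
#' @param physiology A physiology tibble from [compute_physiology()].
#' @param design A plot-level design.
#' @param response Column to plot (default `"CUE"`).
#' @return A ggplot object.
#' @export
plot_physiology <- function(physiology, design, response = "CUE") {
  df <- physiology |>
    drop_flagged() |>
    dplyr::inner_join(
      dplyr::select(design, "plot_id", "warming_delta", "co2_delta"),
      by = "plot_id"
    ) |>
    dplyr::mutate(
      warming = factor(.data$warming_delta, levels = c(0, 1.5, 3),
                       labels = c("ambient", "+1.5 degC", "+3 degC")),
      co2 = factor(.data$co2_delta, levels = c(0, 150, 300),
                   labels = c("ambient", "+150 ppm", "+300 ppm"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$warming,
                                   y = .data[[response]],
                                   fill = .data$co2)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~date) +
    ggplot2::scale_fill_grey(start = 1, end = 0.5, name = "CO2") +
    ggplot2::labs(x = "warming", y = response) +
    ggplot2::theme_minimal()
}
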