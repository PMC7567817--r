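#' Default experimental-design configuration
#'
#' The field experiment crosses three warming levels (ambient, +1.5, +3 degC)
#' with three CO2 enrichment levels (ambient, +150, +300 ppm) in a
#' surface-response layout of 54 plots, of which 34 are analysed. Rain-out
#' shelters (drought) sit on four ambient-climate plots and four
#' future-climate (+3 degC, +300 ppm) plots. The per-cell replicate counts of
#' the analysed subset are not uniquely determined by the published text, so
#' they live in this configuration and can be overridden: the default places
#' 10 analysed plots in each of the two drought cells (6 unsheltered controls
#' + 4 sheltered) and 2 analysed plots in each remaining cell, which
#' reproduces the published totals (54 plots, 34 analysed, 26 in the
#' surface-response subset per date, 20 in the drought factorial, 8
#' sheltered).
#'
#' @return A list with elements `cells` (a tibble with one row per
#'   warming x CO2 cell: `warming_delta`, `co2_delta`, `n_total`,
#'   `n_analysed`, `n_drought`) and `drought_cells` (a two-row tibble naming
#'   the cells where shelters are permitted).
#' @export
#' @examples
#' cfg <- default_design_config()
#' sum(cfg$cells$n_total)    # 54
#' sum(cfg$cells$n_analysed) # 34
default_design_config <- function() {
  cells <- tibble::tribble(
    ~warming_delta, ~co2_delta, ~n_total, ~n_analysed, ~n_drought,
    0,   0,   10, 10, 4,
    0,   150,  5,  2, 0,
    0,   300,  5,  2, 0,
    1.5, 0,    5,  2, 0,
    1.5, 150,  4,  2, 0,
    1.5, 300,  5,  2, 0,
    3,   0,    5,  2, 0,
    3,   150,  5,  2, 0,
    3,   300, 10, 10, 4
  )
  list(
    cells = cells,
    drought_cells = tibble::tibble(
      warming_delta = c(0, 3),
      co2_delta = c(0, 300)
    )
  )
}

warming_levels <- function() c(0, 1.5, 3)
co2_levels <- function() c(0, 150, 300)

is_drought_cell <- function(warming_delta, co2_delta, drought_cells) {
  paste(warming_delta, co2_delta) %in%
    paste(drought_cells$warming_delta, drought_cells$co2_delta)
}

#' Build the plot-level experimental design
#'
#' Expands a design configuration into one row per plot, with treatment
#' levels, drought (rain-out shelter) assignment and membership in the
#' analysed subset. The construction is deterministic: plot ids are
#' zero-padded strings assigned in cell order so that lexicographic sorting
#' reproduces the build order.
#'
#' @param config A configuration as returned by [default_design_config()].
#' @return A tibble with columns `plot_id`, `warming_delta` (degC above
#'   ambient), `co2_delta` (ppm above ambient), `drought` (logical) and
#'   `in_study` (logical; member of the analysed subset).
#' @export
#' @examples
#' design <- build_design()
#' nrow(design)                # 54
#' sum(design$in_study)        # 34
#' sum(design$drought)         # 8
build_design <- function(config = default_design_config()) {
  cells <- config$cells
  stopifnot(is.data.frame(cells))
  required <- c("warming_delta", "co2_delta", "n_total", "n_analysed", "n_drought")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("design config cells lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cells$warming_delta %in% warming_levels())) {
    stop("invalid warming level(s): warming_delta must be one of 0, 1.5, 3",
         call. = FALSE)
  }
  if (!all(cells$co2_delta %in% co2_levels())) {
    stop("invalid CO2 level(s): co2_delta must be one of 0, 150, 300",
         call. = FALSE)
  }
  if (anyDuplicated(cells[, c("warming_delta", "co2_delta")]) > 0) {
    stop("duplicate treatment cell in design config", call. = FALSE)
  }
  if (any(cells$n_analysed > cells$n_total) || any(cells$n_drought > cells$n_analysed)) {
    stop("cell counts must satisfy n_drought <= n_analysed <= n_total",
         call. = FALSE)
  }
  bad_drought <- cells$n_drought > 0 &
    !is_drought_cell(cells$warming_delta, cells$co2_delta, config$drought_cells)
  if (any(bad_drought)) {
    stop("drought plots assigned to a cell without rain-out shelters",
         call. = FALSE)
  }

  n_total_all <- sum(cells$n_total)
  design <- cells |>
    dplyr::arrange(.data$warming_delta, .data$co2_delta) |>
    dplyr::rowwise() |>
    dplyr::mutate(plot = list(seq_len(.data$n_total))) |>
    tidyr::unnest("plot") |>
    dplyr::ungroup() |>
    dplyr::mutate(
      plot_id = sprintf(paste0("P%0", nchar(n_total_all), "d"),
                        dplyr::row_number()),
      in_study = .data$plot <= .data$n_analysed,
      drought = .data$plot <= .data$n_drought
    ) |>
    dplyr::select("plot_id", "warming_delta", "co2_delta", "drought", "in_study")
  if (anyDuplicated(design$plot_id) > 0) {
    stop("duplicate plot ids generated", call. = FALSE)
  }
  design
}

#' Sampling dates of the study
#'
#' Three harvests across the 2017 growing season. The incubation temperature
#' is the assay temperature of the ambient treatment at each date; warmed
#' plots are incubated `warming_delta` degrees higher.
#'
#' @return A tibble with columns `date` (factor May/July/October) and
#'   `incubation_base_c` (degC).
#' @export
sampling_dates <- function() {
  tibble::tibble(
    date = date_factor(c("May", "July", "October")),
    incubation_base_c = c(16, 20, 10)
  )
}

date_factor <- function(x) {
  factor(as.character(x), levels = c("May", "July", "October"))
}

#' Expand a plot-level design over the sampling dates
#'
#' @param design A plot-level design from [build_design()].
#' @param dates A tibble of dates from [sampling_dates()].
#' @param analysed_only Keep only analysed plots (default `TRUE`).
#' @return A tibble with one row per plot x date, including the assay
#'   incubation temperature (`incubation_c`).
#' @export
expand_design <- function(design, dates = sampling_dates(), analysed_only = TRUE) {
  if (analysed_only) design <- dplyr::filter(design, .data$in_study)
  tidyr::crossing(design, dates) |>
    dplyr::mutate(incubation_c = .data$incubation_base_c + .data$warming_delta) |>
    dplyr::arrange(.data$plot_id, .data$date)
}

#' Surface-response subset of the design
#'
#' The plots used for per-date response-surface fits: analysed plots without
#' rain-out shelters. With the default configuration this is 26 plots.
#'
#' @param design A plot-level design from [build_design()].
#' @return The filtered design tibble.
#' @export
rsm_subset <- function(design) {
  dplyr::filter(design, .data$in_study, !.data$drought)
}

#' Drought-factorial subset of the design
#'
#' The 2 x 2 factorial testing drought under ambient versus future climate:
#' all analysed plots in the treatment cells carrying rain-out shelters,
#' sheltered or not. With the default configuration this is 20 plots, 8 of
#' them sheltered.
#'
#' @param design A plot-level design from [build_design()].
#' @param drought_cells Cells where shelters are permitted; by default the
#'   cells in which `design` actually contains sheltered plots.
#' @return The filtered design tibble with an added `climate` column
#'   (`"ambient"` or `"future"`).
#' @export
drought_subset <- function(design, drought_cells = NULL) {
  if (is.null(drought_cells)) {
    drought_cells <- design |>
      dplyr::filter(.data$drought) |>
      dplyr::distinct(.data$warming_delta, .data$co2_delta)
  }
  design |>
    dplyr::filter(
      .data$in_study,
      is_drought_cell(.data$warming_delta, .data$co2_delta, drought_cells)
    ) |>
    dplyr::mutate(
      climate = ifelse(.data$warming_delta > 0 | .data$co2_delta > 0,
                       "future", "ambient")
    )
}

#' Add coded design units
#'
#' Codes the treatment levels onto the unit scale used by the
#' response-surface models: `eT = warming_delta / 1.5 - 1` and
#' `eCO2 = co2_delta / 150 - 1`, both in {-1, 0, 1}.
#'
#' @param design A design tibble with `warming_delta` and `co2_delta`.
#' @param coding `"design_units"` (default) or `"physical_units"` (leave the
#'   physical offsets as predictors).
#' @return The tibble with added columns `eT` and `eCO2`.
#' @export
add_coded_units <- function(design, coding = c("design_units", "physical_units")) {
  coding <- match.arg(coding)
  if (coding == "design_units") {
    dplyr::mutate(design,
                  eT = .data$warming_delta / 1.5 - 1,
                  eCO2 = .data$co2_delta / 150 - 1)
  } else {
    dplyr::mutate(design, eT = .data$warming_delta, eCO2 = .data$co2_delta)
  }
}
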