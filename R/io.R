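# CSV schemas for the five raw instrument tables. Column names are exact;
# unknown extra columns are tolerated with a warning (forward compatibility).
raw_table_schemas <- function() {
  list(
    irms = c(plot_id = "c", date = "c", labeled = "l",
             dna_at_percent = "d", total_oxygen_ug_per_gdm = "d"),
    dna = c(plot_id = "c", date = "c", dna_ug_per_gdm = "d"),
    gc = c(plot_id = "c", date = "c", headspace_ml = "d", sampled_ml = "d",
           co2_t0_ppm = "d", co2_repl_ppm = "d", co2_tend_ppm = "d",
           temp_c = "d", duration_h = "d", dry_mass_g = "d"),
    cfe = c(plot_id = "c", date = "c", eoc_fum = "d", eoc_unfum = "d"),
    gravimetry = c(plot_id = "c", date = "c", fresh_soil_g = "d",
                   gwc_g_per_g = "d", label_water_g = "d", label_atpct = "d")
  )
}

check_schema <- function(df, schema, name) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop(sprintf("table '%s' is missing required column(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra) > 0) {
    warning(sprintf("table '%s' has unknown column(s) %s; ignoring",
                    name, paste(extra, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Validate a raw measurement bundle
#'
#' Checks that all five tables are present with their exact required columns,
#' coerces `date` to the May/July/October factor, and rejects duplicate
#' `plot_id` x `date` keys (x labelled status for the IRMS table).
#'
#' @param raw A named list of tibbles (`irms`, `dna`, `gc`, `cfe`,
#'   `gravimetry`).
#' @return The validated bundle (invisibly the same shape).
#' @export
validate_raw_tables <- function(raw) {
  schemas <- raw_table_schemas()
  missing <- setdiff(names(schemas), names(raw))
  if (length(missing) > 0) {
    stop("raw bundle is missing table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::imap(schemas, function(schema, name) {
    df <- check_schema(raw[[name]], schema, name)
    df <- dplyr::mutate(df, date = date_factor(.data$date))
    if (any(is.na(df$date))) {
      stop(sprintf("table '%s' has dates outside May/July/October", name),
           call. = FALSE)
    }
    keycols <- if (name == "irms") c("plot_id", "date", "labeled") else
      c("plot_id", "date")
    if (anyDuplicated(df[, keycols]) > 0) {
      stop(sprintf("table '%s' has duplicate keys", name), call. = FALSE)
    }
    df
  })
  out
}

#' Read the five raw instrument CSVs from a directory
#'
#' Expects `irms.csv`, `dna.csv`, `gc.csv`, `cfe.csv` and `gravimetry.csv`
#' (UTF-8, comma-separated, "." decimal, empty field for NA) and validates
#' them against the package schemas.
#'
#' @param dir Directory containing the files.
#' @return A validated named list of tibbles.
#' @export
read_raw_tables <- function(dir) {
  schemas <- raw_table_schemas()
  raw <- purrr::imap(schemas, function(schema, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      stop("missing raw table file: ", path, call. = FALSE)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  })
  validate_raw_tables(raw)
}

#' Write a raw measurement bundle to CSV files
#'
#' @param raw A raw bundle (named list of tibbles).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_raw_tables <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::iwalk(raw[names(raw_table_schemas())], function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  })
  invisible(dir)
}

#' Read or write the plot-level design table
#'
#' `design.csv` carries columns `plot_id`, `warming_delta_C`,
#' `co2_delta_ppm`, `drought`, `in_study`.
#'
#' @param path File path.
#' @return `read_design_csv()` returns the design tibble with the package's
#'   internal column names.
#' @export
read_design_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("plot_id", "warming_delta_C", "co2_delta_ppm", "drought", "in_study")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("design.csv is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::tibble(
    plot_id = as.character(df$plot_id),
    warming_delta = df$warming_delta_C,
    co2_delta = df$co2_delta_ppm,
    drought = as.logical(df$drought),
    in_study = as.logical(df$in_study)
  )
}

#' @rdname read_design_csv
#' @param design A plot-level design tibble.
#' @export
write_design_csv <- function(design, path) {
  out <- dplyr::tibble(
    plot_id = design$plot_id,
    warming_delta_C = design$warming_delta,
    co2_delta_ppm = design$co2_delta,
    drought = design$drought,
    in_study = design$in_study
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML configuration with sections `design`, `simulation`, `qc`, `stats`,
#' `io` and a top-level `seed`. Unknown top-level keys are rejected; absent
#' sections take package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    design = NULL,
    simulation = list(enabled = TRUE),
    qc = list(drop_flagged = TRUE),
    stats = list(coding = "design_units", anova_log = TRUE, alpha = 0.05,
                 correlation = "AIC"),
    io = list(digits = 6)
  )
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  if (!is.numeric(out$stats$alpha) || out$stats$alpha <= 0 || out$stats$alpha >= 1) {
    stop("stats.alpha must lie in (0, 1)", call. = FALSE)
  }
  out
}
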