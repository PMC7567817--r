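#' Derive microbial physiology from a raw measurement bundle
#'
#' Orchestrates the measurement model over a raw instrument bundle (see
#' [read_raw_tables()] for the five table schemas): soil-water enrichment
#' from gravimetry, DNA production from the IRMS labelled/control pairs,
#' MBC from the fumigation pairs, respiration from the headspace series, and
#' from these growth, uptake, CUE and the biomass-specific rates.
#'
#' Quality control never censors silently: negative MBC, negative DNA
#' production or negative CO2 accumulation are reported as computed and
#' tagged in `qc_flags` (`NEGATIVE_MBC`, `NEGATIVE_DNA_PRODUCTION`,
#' `NEGATIVE_RESPIRATION`); a missing headspace series gives
#' `MISSING_RESPIRATION`; rows where CUE is undefined (G or R negative or
#' missing, or zero uptake) carry `CUE_UNDEFINED` with `CUE = NA` but are
#' retained.
#'
#' @param raw A named list of tibbles `irms`, `dna`, `gc`, `cfe`,
#'   `gravimetry` sharing `plot_id` and `date` keys.
#' @param natural_abundance Natural 18O abundance (at%), default 0.2005.
#' @param kec Fumigation extraction-efficiency factor, default 0.45.
#' @param incubation_hours Labelling incubation duration (h), default 24.
#' @return A tibble with one row per plot x date: `DNA_p`, `DNA_total`,
#'   `MBC`, `G`, `R`, `U`, `CUE`, `G_m`, `R_m`, `water_at` and `qc_flags`
#'   (semicolon-separated codes, `""` when clean).
#' @export
#' @examples
#' study <- generate_study(seed = 1)
#' phys <- compute_physiology(study$raw)
#' dplyr::glimpse(phys)
compute_physiology <- function(raw, natural_abundance = NATURAL_ABUNDANCE_18O,
                               kec = 0.45, incubation_hours = 24) {
  raw <- validate_raw_tables(raw)
  key <- c("plot_id", "date")

  grav <- raw$gravimetry |>
    dplyr::mutate(
      water_at = soil_water_enrichment(
        .data$fresh_soil_g, .data$gwc_g_per_g, .data$label_water_g,
        .data$label_atpct, natural_abundance
      )
    )

  irms_lab <- dplyr::filter(raw$irms, .data$labeled)
  irms_ctl <- raw$irms |>
    dplyr::filter(!.data$labeled) |>
    dplyr::select(dplyr::all_of(key), control_at = "dna_at_percent")
  if (anyDuplicated(irms_lab[, key]) > 0 || anyDuplicated(irms_ctl[, key]) > 0) {
    stop("duplicate plot_id x date keys in irms table", call. = FALSE)
  }
  missing_ctl <- dplyr::anti_join(irms_lab, irms_ctl, by = key)
  if (nrow(missing_ctl) > 0) {
    stop("missing natural-abundance control for: ",
         paste(missing_ctl$plot_id, missing_ctl$date, collapse = "; "),
         call. = FALSE)
  }

  base <- irms_lab |>
    dplyr::inner_join(irms_ctl, by = key) |>
    dplyr::left_join(grav, by = key) |>
    dplyr::left_join(raw$dna, by = key) |>
    dplyr::left_join(raw$cfe, by = key)
  incomplete <- is.na(base$water_at) | is.na(base$dna_ug_per_gdm) |
    is.na(base$eoc_fum)
  if (any(incomplete)) {
    stop("key mismatch across raw tables: gravimetry, dna and cfe must cover ",
         "every labelled IRMS sample (first offender: ",
         base$plot_id[which(incomplete)[1]], " ",
         as.character(base$date)[which(incomplete)[1]], ")", call. = FALSE)
  }

  resp <- raw$gc |>
    dplyr::mutate(
      R = respiration_rate(
        .data$headspace_ml, .data$sampled_ml, .data$co2_t0_ppm,
        .data$co2_repl_ppm, .data$co2_tend_ppm, .data$temp_c,
        .data$duration_h, .data$dry_mass_g
      )
    ) |>
    dplyr::select(dplyr::all_of(key), "R")

  out <- base |>
    dplyr::left_join(resp, by = key) |>
    dplyr::mutate(
      DNA_total = .data$dna_ug_per_gdm,
      MBC = mbc_from_cfe(.data$eoc_fum, .data$eoc_unfum, kec),
      DNA_p = dna_production(
        .data$dna_at_percent, .data$control_at,
        .data$total_oxygen_ug_per_gdm, .data$water_at,
        natural_abundance, incubation_hours
      ),
      G = dplyr::if_else(.data$MBC > 0 & .data$DNA_total > 0,
                         .data$DNA_p * .data$MBC / .data$DNA_total, NA_real_),
      U = .data$G + .data$R,
      CUE = cue(.data$G, .data$R),
      G_m = dplyr::if_else(.data$MBC > 0, 1000 * .data$G / .data$MBC, NA_real_),
      R_m = dplyr::if_else(.data$MBC > 0, 1000 * .data$R / .data$MBC, NA_real_)
    )

  flags <- dplyr::tibble(
    NEGATIVE_MBC = out$MBC < 0,
    NEGATIVE_DNA_PRODUCTION = out$DNA_p < 0,
    MISSING_RESPIRATION = is.na(out$R),
    NEGATIVE_RESPIRATION = !is.na(out$R) & out$R < 0,
    CUE_UNDEFINED = is.na(out$CUE)
  )
  qc <- apply(as.matrix(flags), 1L, function(row) {
    paste(names(flags)[!is.na(row) & row], collapse = ";")
  })

  out |>
    dplyr::mutate(qc_flags = qc) |>
    dplyr::select(dplyr::all_of(key), "DNA_p", "DNA_total", "MBC", "G", "R",
                  "U", "CUE", "G_m", "R_m", "water_at", "qc_flags") |>
    dplyr::arrange(.data$plot_id, .data$date)
}

#' Drop qc-flagged physiology rows
#'
#' Convenience filter used before all statistical fits by default: keeps only
#' rows with an empty `qc_flags` field.
#'
#' @param physiology A physiology tibble from [compute_physiology()].
#' @return The filtered tibble.
#' @export
drop_flagged <- function(physiology) {
  dplyr::filter(physiology, .data$qc_flags == "")
}

#' Summarise carbon use efficiency
#'
#' Grand mean, per-row range and per-treatment x date means of CUE over the
#' qc-passing rows.
#'
#' @param physiology A physiology tibble from [compute_physiology()].
#' @param design Optional plot-level design to attach treatment levels for
#'   the per-treatment means.
#' @return A list with `grand_mean`, `min`, `max`, `n` and (when a design is
#'   supplied) `by_treatment`, a tibble of per-(warming, CO2, date) means.
#' @export
summarize_cue <- function(physiology, design = NULL) {
  ok <- physiology |>
    dplyr::filter(.data$qc_flags == "", !is.na(.data$CUE))
  if (nrow(ok) == 0) stop("no qc-passing CUE rows to summarise", call. = FALSE)
  out <- list(
    grand_mean = mean(ok$CUE),
    min = min(ok$CUE),
    max = max(ok$CUE),
    n = nrow(ok)
  )
  if (!is.null(design)) {
    out$by_treatment <- ok |>
      dplyr::inner_join(
        dplyr::select(design, "plot_id", "warming_delta", "co2_delta"),
        by = "plot_id"
      ) |>
      dplyr::group_by(.data$warming_delta, .data$co2_delta, .data$date) |>
      dplyr::summarise(mean_cue = mean(.data$CUE), n = dplyr::n(),
                       .groups = "drop")
  }
  structure(out, class = "cue_summary")
}

#' @export
print.cue_summary <- function(x, ...) {
  cat(sprintf("CUE summary over %d plot x date rows\n", x$n))
  cat(sprintf("  grand mean: %.3f\n", x$grand_mean))
  cat(sprintf("  range:      [%.3f, %.3f]\n", x$min, x$max))
  if (!is.null(x$by_treatment)) {
    cat(sprintf("  per-treatment means: %.3f - %.3f\n",
                min(x$by_treatment$mean_cue), max(x$by_treatment$mean_cue)))
  }
  invisible(x)
}
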