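#' Simulation parameters for the synthetic study
#'
#' Defines the study conditions the forward simulator emulates: date-specific
#' second-order treatment surfaces on the log biomass-specific rates (the
#' published per-date coefficient estimates where printed, zero otherwise),
#' per-date residual standard deviations with within-plot correlation across
#' dates, additive log-scale drought effects applied at the July harvest,
#' lognormal MBC and soil-DNA pools, instrument-level noise, and the
#' labelling/incubation setup shared by all samples.
#'
#' @param surface Tibble of surface coefficients with columns `response`
#'   (`"G_m"` or `"R_m"`), `date`, `b0`, `eCO2`, `eT`, `eCO2_eT`, `eCO2_sq`,
#'   `eT_sq`, on the natural-log scale in coded design units.
#' @param sigma Named per-date residual SDs on the log scale.
#' @param rho Within-plot correlation of residuals across dates, |rho| < 1.
#' @param drought Tibble of additive log-scale July drought effects by
#'   climate (`ambient`, `future`) for G_m (`dG`) and R_m (`dR`).
#' @param mbc_meanlog,mbc_sdlog Lognormal parameters of MBC
#'   (ug C per g dry mass).
#' @param dna_meanlog,dna_sdlog Lognormal parameters of soil DNA
#'   (ug DNA per g dry mass).
#' @param noise Named instrument noise SDs: `irms_at` (absolute at%),
#'   `gc_rel`, `eoc_rel`, `dna_rel` (relative).
#' @param assay Labelling and incubation setup (masses in g, volumes in ml,
#'   duration in h, CO2 in ppm, enrichments in at%).
#' @return A list of class `cue_sim_params`.
#' @export
sim_params <- function(
    surface = default_surface_truth(),
    sigma = c(May = 0.45, July = 0.12, October = 0.10),
    rho = 0.3,
    drought = tibble::tibble(climate = c("ambient", "future"),
                             dG = c(-0.2, 0.6), dR = c(0, 0.7)),
    mbc_meanlog = log(800), mbc_sdlog = 0.25,
    dna_meanlog = log(30), dna_sdlog = 0.25,
    noise = c(irms_at = 0.005, gc_rel = 0.01, eoc_rel = 0.05, dna_rel = 0.05),
    assay = list(fresh_soil_g = 0.4, gwc_g_per_g = 0.25, label_water_g = 0.05,
                 target_water_at = 25, headspace_ml = 26, sampled_ml = 5,
                 co2_ambient_ppm = 400, duration_h = 24,
                 natural_abundance = NATURAL_ABUNDANCE_18O,
                 eoc_unfum = 55)) {
  stopifnot(all(sigma >= 0), abs(rho) < 1, all(noise >= 0))
  stopifnot(all(c("May", "July", "October") %in% names(sigma)))
  structure(
    list(surface = surface, sigma = sigma, rho = rho, drought = drought,
         mbc_meanlog = mbc_meanlog, mbc_sdlog = mbc_sdlog,
         dna_meanlog = dna_meanlog, dna_sdlog = dna_sdlog,
         noise = noise, assay = assay),
    class = "cue_sim_params"
  )
}

#' Default latent response-surface coefficients
#'
#' Per-date coefficients of the second-order surfaces on log biomass-specific
#' growth and respiration in coded design units. The treatment terms are the
#' published per-date estimates where a term was retained in the reduced
#' models; terms not retained default to zero. Intercepts set the seasonal
#' level of the rates (highest in May, lowest in October) and the typical
#' growth/respiration balance.
#'
#' @return A tibble with one row per response x date.
#' @export
default_surface_truth <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      response = "G_m", date = c("May", "July", "October"),
      b0 = c(0.0, -0.5, -1.2),
      eCO2 = c(0.51, 0.05, 0.01),
      eT = c(-0.56, -0.23, 0.10),
      eCO2_eT = c(0.12, 0, 0),
      eCO2_sq = c(-0.30, 0, 0),
      eT_sq = c(0.24, 0, 0)
    ),
    tibble::tibble(
      response = "R_m", date = c("May", "July", "October"),
      b0 = c(0.45, -0.05, -0.75),
      eCO2 = c(0.19, 0.27, 0.01),
      eT = c(0.06, -0.52, 0.26),
      eCO2_eT = 0, eCO2_sq = 0, eT_sq = 0
    )
  ) |>
    dplyr::mutate(date = date_factor(.data$date))
}

# residual draws for one response: n_plots x 3 dates, heteroscedastic
# compound-symmetric covariance Sigma_ij = rho * s_i * s_j (i != j)
draw_plot_residuals <- function(n_plots, sigma, rho) {
  s <- sigma[c("May", "July", "October")]
  z <- matrix(stats::rnorm(n_plots * 3), n_plots, 3)
  if (all(s == 0)) {
    e <- z * 0
  } else if (any(s == 0)) {
    if (rho != 0) {
      stop("implied residual covariance across dates is not positive definite",
           call. = FALSE)
    }
    e <- sweep(z, 2, s, "*")
  } else {
    corr <- matrix(rho, 3, 3)
    diag(corr) <- 1
    cov <- diag(s) %*% corr %*% diag(s)
    ch <- tryCatch(chol(cov), error = function(e) {
      stop("implied residual covariance across dates is not positive definite",
           call. = FALSE)
    })
    e <- z %*% ch
  }
  colnames(e) <- c("May", "July", "October")
  e
}

#' Simulate latent plot-level physiology
#'
#' Draws the true (noise-free) biomass-specific growth and respiration of
#' every analysed plot at every date from the date-specific log-scale
#' treatment surfaces, with heteroscedastic, within-plot-correlated
#' residuals, additive July drought effects, and lognormal MBC and soil DNA
#' pools; then derives the per-dry-mass rates and CUE.
#'
#' @param params A [sim_params()] object.
#' @param design A plot-level design from [build_design()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with one row per analysed plot x date carrying the
#'   latent `G_m`, `R_m`, `MBC`, `DNA_total` and derived `G`, `R`, `CUE`.
#' @export
simulate_latent <- function(params, design = build_design(), seed = 1L) {
  stopifnot(inherits(params, "cue_sim_params"))
  base <- expand_design(design) |>
    add_coded_units() |>
    dplyr::mutate(climate = dplyr::case_when(
      .data$warming_delta == 0 & .data$co2_delta == 0 ~ "ambient",
      .data$warming_delta == 3 & .data$co2_delta == 300 ~ "future",
      TRUE ~ NA_character_
    ))
  plots <- sort(unique(base$plot_id))
  n_plots <- length(plots)

  mu_for <- function(resp) {
    coefs <- params$surface |>
      dplyr::filter(.data$response == resp) |>
      dplyr::select(-"response")
    joined <- dplyr::left_join(base, coefs, by = "date")
    joined$b0 + joined$eCO2.y * joined$eCO2.x + joined$eT.y * joined$eT.x +
      joined$eCO2_eT * joined$eCO2.x * joined$eT.x +
      joined$eCO2_sq * joined$eCO2.x^2 + joined$eT_sq * joined$eT.x^2
  }
  mu_g <- mu_for("G_m")
  mu_r <- mu_for("R_m")

  # drought effects: applied at the July harvest only (the shelter window)
  dr <- dplyr::left_join(
    dplyr::select(base, "plot_id", "date", "drought", "climate"),
    params$drought, by = "climate"
  )
  is_july_drought <- dr$drought & dr$date == "July" & !is.na(dr$dG)
  mu_g <- mu_g + ifelse(is_july_drought, dr$dG, 0)
  mu_r <- mu_r + ifelse(is_july_drought, dr$dR, 0)

  set.seed(seed + 11L)
  e_g <- draw_plot_residuals(n_plots, params$sigma, params$rho)
  set.seed(seed + 13L)
  e_r <- draw_plot_residuals(n_plots, params$sigma, params$rho)
  idx <- cbind(match(base$plot_id, plots), match(as.character(base$date),
                                                colnames(e_g)))

  set.seed(seed + 17L)
  mbc <- stats::rlnorm(nrow(base), params$mbc_meanlog, params$mbc_sdlog)
  set.seed(seed + 19L)
  dna <- stats::rlnorm(nrow(base), params$dna_meanlog, params$dna_sdlog)

  base |>
    dplyr::mutate(
      G_m = exp(mu_g + e_g[idx]),
      R_m = exp(mu_r + e_r[idx]),
      MBC = mbc,
      DNA_total = dna,
      G = .data$G_m * .data$MBC / 1000,
      R = .data$R_m * .data$MBC / 1000,
      CUE = .data$G / (.data$G + .data$R)
    ) |>
    dplyr::select("plot_id", "date", "warming_delta", "co2_delta", "drought",
                  "climate", "eT", "eCO2", "incubation_c", "G_m", "R_m",
                  "MBC", "DNA_total", "G", "R", "CUE")
}

#' Invert the measurement model: latent physiology to raw instrument tables
#'
#' Computes the IRMS, fluorometry, gas-chromatography, fumigation and
#' gravimetry readings that would reproduce the latent physiology exactly
#' through [compute_physiology()], then (optionally) adds instrument-level
#' noise. At zero noise the round trip is an identity to numerical
#' precision.
#'
#' @param latent A latent table from [simulate_latent()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the instrument noise.
#' @param noise Add instrument noise (default `TRUE`); `FALSE` gives the
#'   exact inverse.
#' @return A named list of the five raw tibbles (`irms`, `dna`, `gc`, `cfe`,
#'   `gravimetry`).
#' @export
latent_to_raw <- function(latent, params, seed = 1L, noise = TRUE) {
  stopifnot(inherits(params, "cue_sim_params"))
  a <- params$assay
  nat <- a$natural_abundance
  m_native <- a$fresh_soil_g * a$gwc_g_per_g
  label_atpct <- label_enrichment_for_target(m_native, a$label_water_g,
                                             a$target_water_at, nat)
  water_at <- soil_water_enrichment(a$fresh_soil_g, a$gwc_g_per_g,
                                    a$label_water_g, label_atpct, nat)
  dm <- dry_mass(a$fresh_soil_g, a$gwc_g_per_g)

  dna_p <- latent$G * latent$DNA_total / latent$MBC
  f_new <- dna_p * a$duration_h / latent$DNA_total
  if (any(f_new >= 1)) {
    stop("infeasible latent physiology: implied DNA 18O enrichment would ",
         "reach or exceed the soil-water enrichment", call. = FALSE)
  }
  dna_at_labeled <- nat + f_new * (water_at - nat)
  total_oxygen <- latent$DNA_total * DNA_O_FRACTION

  # invert the headspace mass balance (t0 and replacement air at ambient CO2)
  t_k <- latent$incubation_c + 273.15
  mol <- latent$R * a$duration_h * dm / (C_MOLAR_MASS * 1e6)
  delta_ppm <- mol * R_GAS_L_ATM * t_k / (a$headspace_ml / 1000) * 1e6
  co2_tend <- a$co2_ambient_ppm + delta_ppm

  eoc_fum <- a$eoc_unfum + latent$MBC * 0.45

  key <- dplyr::select(latent, "plot_id", "date")
  n <- nrow(latent)
  ns <- params$noise
  if (!noise) ns[] <- 0
  set.seed(seed + 23L)
  at_lab_obs <- dna_at_labeled + stats::rnorm(n, 0, ns[["irms_at"]])
  at_ctl_obs <- nat + stats::rnorm(n, 0, ns[["irms_at"]])
  o_obs <- total_oxygen * (1 + stats::rnorm(n, 0, ns[["dna_rel"]]))
  o_ctl_obs <- total_oxygen * (1 + stats::rnorm(n, 0, ns[["dna_rel"]]))
  set.seed(seed + 29L)
  dna_obs <- latent$DNA_total * (1 + stats::rnorm(n, 0, ns[["dna_rel"]]))
  set.seed(seed + 31L)
  t0_obs <- a$co2_ambient_ppm * (1 + stats::rnorm(n, 0, ns[["gc_rel"]]))
  tend_obs <- co2_tend * (1 + stats::rnorm(n, 0, ns[["gc_rel"]]))
  set.seed(seed + 37L)
  fum_obs <- eoc_fum * (1 + stats::rnorm(n, 0, ns[["eoc_rel"]]))
  unfum_obs <- a$eoc_unfum * (1 + stats::rnorm(n, 0, ns[["eoc_rel"]]))

  list(
    irms = dplyr::bind_rows(
      dplyr::mutate(key, labeled = TRUE, dna_at_percent = at_lab_obs,
                    total_oxygen_ug_per_gdm = o_obs),
      dplyr::mutate(key, labeled = FALSE, dna_at_percent = at_ctl_obs,
                    total_oxygen_ug_per_gdm = o_ctl_obs)
    ) |> dplyr::arrange(.data$plot_id, .data$date, !.data$labeled),
    dna = dplyr::mutate(key, dna_ug_per_gdm = dna_obs),
    gc = dplyr::mutate(key,
                       headspace_ml = a$headspace_ml, sampled_ml = a$sampled_ml,
                       co2_t0_ppm = t0_obs, co2_repl_ppm = a$co2_ambient_ppm,
                       co2_tend_ppm = tend_obs, temp_c = latent$incubation_c,
                       duration_h = a$duration_h, dry_mass_g = dm),
    cfe = dplyr::mutate(key, eoc_fum = fum_obs, eoc_unfum = unfum_obs),
    gravimetry = dplyr::mutate(key,
                               fresh_soil_g = a$fresh_soil_g,
                               gwc_g_per_g = a$gwc_g_per_g,
                               label_water_g = a$label_water_g,
                               label_atpct = label_atpct)
  )
}

#' Generate a complete synthetic study
#'
#' Builds the design, simulates latent physiology, inverts it to raw
#' instrument tables with noise, and optionally writes everything
#' (`design.csv`, the five raw CSVs, `truth.csv`, `params.json`) to a
#' directory.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed controlling all randomness.
#' @param dir Output directory, or `NULL` (default) to return in memory only.
#' @param config Design configuration, default [default_design_config()].
#' @param noise Add instrument noise (default `TRUE`).
#' @return A list with `design` (plot-level tibble), `latent` (truth table)
#'   and `raw` (the five-table bundle), invisibly when writing.
#' @export
#' @examples
#' study <- generate_study(seed = 42)
#' nrow(study$latent)  # 34 plots x 3 dates = 102
generate_study <- function(params = sim_params(), seed = 1L, dir = NULL,
                           config = default_design_config(), noise = TRUE) {
  design <- build_design(config)
  latent <- simulate_latent(params, design, seed = seed)
  raw <- latent_to_raw(latent, params, seed = seed + 1000L, noise = noise)
  out <- list(design = design, latent = latent, raw = raw)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_design_csv(design, file.path(dir, "design.csv"))
    write_raw_tables(raw, dir)
    readr::write_csv(latent, file.path(dir, "truth.csv"), progress = FALSE)
    prov <- list(seed = seed, sigma = as.list(params$sigma), rho = params$rho,
                 noise = as.list(params$noise), assay = params$assay)
    jsonlite::write_json(prov, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
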