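#' Parameter-recovery experiment for the response-surface estimator
#'
#' Repeatedly simulates a full study (latent surfaces, instrument tables,
#' physiology recomputation), fits the per-date second-order surface on the
#' chosen response, and compares the estimates against the generating truth.
#' Coverage uses the two-sided t-based Wald interval at the requested level.
#'
#' @param params A [sim_params()] object holding the generating truth.
#' @param replicates Number of simulated studies, >= 1.
#' @param seed Integer root seed; replicate r uses `seed + r`.
#' @param dates Dates to fit (default `"May"`).
#' @param response `"G_m"` or `"R_m"`.
#' @param level Confidence level, default 0.95.
#' @param noise Propagate instrument noise (default `TRUE`).
#' @return A list of class `cue_recovery`: `$summary` (per date x term:
#'   truth, mean estimate, bias, RMSE, CI coverage, mean SE) and `$draws`
#'   (per replicate estimates).
#' @export
parameter_recovery_experiment <- function(params = sim_params(),
                                          replicates = 100L, seed = 1L,
                                          dates = "May", response = "G_m",
                                          level = 0.95, noise = TRUE) {
  stopifnot(replicates >= 1)
  truth <- params$surface |>
    dplyr::filter(.data$response == !!response) |>
    dplyr::select(-"response") |>
    tidyr::pivot_longer(-"date", names_to = "term", values_to = "truth") |>
    dplyr::mutate(term = dplyr::recode(.data$term,
                                       b0 = "(Intercept)", eCO2_eT = "eCO2:eT",
                                       eCO2_sq = "eCO2^2", eT_sq = "eT^2"))
  design <- build_design()
  codes <- design |>
    rsm_subset() |>
    add_coded_units() |>
    dplyr::select("plot_id", "eT", "eCO2")

  draws <- purrr::map_dfr(seq_len(replicates), function(r) {
    latent <- simulate_latent(params, design, seed = seed + r)
    raw <- latent_to_raw(latent, params, seed = seed + r + 500000L,
                         noise = noise)
    phys <- compute_physiology(raw) |>
      dplyr::inner_join(codes, by = "plot_id")
    purrr::map_dfr(dates, function(d) {
      fit <- fit_surface_model(phys, response, date = d)
      tidy.cue_rsm(fit) |>
        dplyr::mutate(date = d, replicate = r,
                      df = fit$df.residual)
    })
  })

  alpha <- 1 - level
  summary <- draws |>
    dplyr::mutate(date = date_factor(.data$date)) |>
    dplyr::left_join(truth, by = c("date", "term")) |>
    dplyr::mutate(
      covered = abs(.data$estimate - .data$truth) <=
        stats::qt(1 - alpha / 2, .data$df) * .data$std.error
    ) |>
    dplyr::group_by(.data$date, .data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$covered),
      mean_se = mean(.data$std.error),
      .groups = "drop"
    )
  structure(list(summary = summary, draws = draws, replicates = replicates,
                 response = response, level = level),
            class = "cue_recovery")
}

#' @export
print.cue_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s, %d replicates, %.0f%% intervals\n",
              x$response, x$replicates, 100 * x$level))
  print(x$summary)
  invisible(x)
}

#' Type-I error of the response-surface warming test
#'
#' Simulates studies under a null truth (all treatment terms zero) and
#' records how often the linear warming term of the per-date surface fit is
#' declared significant. For a correctly calibrated test the rejection rate
#' matches `alpha`.
#'
#' @param replicates Number of null simulations.
#' @param seed Integer root seed.
#' @param date Date fitted (default `"May"`).
#' @param alpha Test level, default 0.05.
#' @param sigma Per-date residual SDs of the null truth (defaults to the
#'   standard study conditions).
#' @param term Tested term, default `"eT"`.
#' @return A list with `rate`, `rejections`, `replicates`.
#' @export
null_rejection_rate <- function(replicates = 500L, seed = 1L, date = "May",
                                alpha = 0.05,
                                sigma = c(May = 0.45, July = 0.12,
                                          October = 0.10),
                                term = "eT") {
  surface_null <- default_surface_truth() |>
    dplyr::mutate(dplyr::across(c("eCO2", "eT", "eCO2_eT", "eCO2_sq", "eT_sq"),
                                ~0))
  params <- sim_params(surface = surface_null, sigma = sigma,
                       drought = tibble::tibble(climate = c("ambient", "future"),
                                                dG = 0, dR = 0))
  design <- build_design()
  codes <- design |>
    rsm_subset() |>
    add_coded_units() |>
    dplyr::select("plot_id", "eT", "eCO2")
  rejections <- 0L
  for (r in seq_len(replicates)) {
    latent <- simulate_latent(params, design, seed = seed + r) |>
      dplyr::semi_join(codes, by = "plot_id")
    fit <- fit_surface_model(latent, "G_m", date = date, qc_filter = FALSE)
    p <- fit$table$p.value[fit$table$term == term]
    rejections <- rejections + as.integer(p < alpha)
  }
  list(rate = rejections / replicates, rejections = rejections,
       replicates = replicates)
}
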