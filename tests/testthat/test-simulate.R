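test_that("the latent simulator is deterministic and respects a null surface", {
  params <- sim_params()
  expect_identical(simulate_latent(params, seed = 5),
                   simulate_latent(params, seed = 5))

  # flat surface with vanishing residuals: every plot shares one G_m per date
  flat <- default_surface_truth() |>
    dplyr::mutate(dplyr::across(c(eCO2, eT, eCO2_eT, eCO2_sq, eT_sq), ~0))
  params0 <- sim_params(surface = flat,
                        sigma = c(May = 0, July = 0, October = 0),
                        rho = 0,
                        drought = tibble::tibble(
                          climate = c("ambient", "future"), dG = 0, dR = 0))
  latent <- simulate_latent(params0, seed = 5)
  per_date <- latent |>
    dplyr::group_by(date) |>
    dplyr::summarise(spread = diff(range(G_m)), .groups = "drop")
  expect_true(all(per_date$spread == 0))
  expect_true(all(latent$CUE > 0 & latent$CUE < 1))
})

test_that("a noise-free surface is recovered exactly by the RSM fit", {
  params0 <- sim_params(sigma = c(May = 0, July = 0, October = 0), rho = 0)
  latent <- simulate_latent(params0, seed = 9) |>
    dplyr::filter(!drought)
  # lm warns about an essentially perfect fit on noise-free data; expected here
  fit <- suppressWarnings(
    fit_surface_model(latent, "G_m", date = "May", qc_filter = FALSE)
  )
  est <- tibble::deframe(fit$table[, c("term", "estimate")])
  truth <- dplyr::filter(default_surface_truth(),
                         response == "G_m", date == "May")
  expect_equal(est[["(Intercept)"]], truth$b0, tolerance = 1e-8)
  expect_equal(est[["eCO2"]], truth$eCO2, tolerance = 1e-8)
  expect_equal(est[["eT"]], truth$eT, tolerance = 1e-8)
  expect_equal(est[["eCO2:eT"]], truth$eCO2_eT, tolerance = 1e-8)
  expect_equal(est[["eCO2^2"]], truth$eCO2_sq, tolerance = 1e-8)
  expect_equal(est[["eT^2"]], truth$eT_sq, tolerance = 1e-8)
})

test_that("july drought effects shift only the sheltered plots at the drought date", {
  params0 <- sim_params(sigma = c(May = 0, July = 0, October = 0), rho = 0,
                        mbc_sdlog = 0, dna_sdlog = 0)
  latent <- simulate_latent(params0, seed = 3)
  july <- dplyr::filter(latent, date == "July",
                        warming_delta == 3, co2_delta == 300)
  dr <- dplyr::filter(july, drought)
  ctl <- dplyr::filter(july, !drought)
  expect_equal(log(dr$G_m) - log(ctl$G_m[1]), rep(0.6, nrow(dr)),
               tolerance = 1e-9)
  may <- dplyr::filter(latent, date == "May",
                       warming_delta == 3, co2_delta == 300)
  expect_equal(diff(range(may$G_m)), 0)
})

test_that("generate_study writes a reproducible, schema-valid study", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(seed = 42, dir = d1)
  generate_study(seed = 42, dir = d2)
  for (f in c("design.csv", "irms.csv", "dna.csv", "gc.csv", "cfe.csv",
              "gravimetry.csv", "truth.csv", "params.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  raw <- read_raw_tables(d1)
  phys <- compute_physiology(raw)
  expect_equal(nrow(phys), 102)
  truth <- readr::read_csv(file.path(d1, "truth.csv"), show_col_types = FALSE)
  expect_true(all(truth$CUE > 0 & truth$CUE < 1))
})

test_that("infeasible latent physiology is rejected by the raw inverter", {
  params <- sim_params()
  latent <- simulate_latent(params, seed = 2)
  # force a growth rate whose implied DNA enrichment exceeds the water pool
  latent$G[1] <- latent$MBC[1] * 10
  expect_error(latent_to_raw(latent, params, noise = FALSE), "infeasible")
})

test_that("instrument noise leaves recovered biomass-specific growth unbiased", {
  params <- sim_params()
  design <- build_design()
  rel_err <- purrr::map(1:100, function(r) {
    latent <- simulate_latent(params, design, seed = 7000 + r)
    raw <- latent_to_raw(latent, params, seed = 9000 + r, noise = TRUE)
    phys <- compute_physiology(raw)
    m <- dplyr::inner_join(latent, phys, by = c("plot_id", "date"),
                           suffix = c(".true", ".obs"))
    (m$G_m.obs - m$G_m.true) / m$G_m.true
  })
  expect_lt(abs(mean(unlist(rel_err))), 0.01)
})

test_that("recovery error grows with the instrument noise level", {
  design <- build_design()
  rmse_at <- purrr::map_dbl(c(0, 1, 4), function(mult) {
    params <- sim_params(noise = c(irms_at = 0.005 * mult, gc_rel = 0.01 * mult,
                                   eoc_rel = 0.05 * mult,
                                   dna_rel = 0.05 * mult))
    errs <- purrr::map(1:20, function(r) {
      latent <- simulate_latent(params, design, seed = 100 + r)
      raw <- latent_to_raw(latent, params, seed = 300 + r,
                          noise = TRUE)
      phys <- compute_physiology(raw)
      m <- dplyr::inner_join(latent, phys, by = c("plot_id", "date"),
                             suffix = c(".true", ".obs"))
      (m$G_m.obs - m$G_m.true) / m$G_m.true
    })
    sqrt(mean(unlist(errs)^2))
  })
  expect_true(all(diff(rmse_at) >= 0))
  expect_equal(rmse_at[1], 0, tolerance = 1e-12)
})
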