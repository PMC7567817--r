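test_that("pooled-variance FGLS without correlation is exactly OLS", {
  set.seed(51)
  n <- 60
  x <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(x %*% c(1, 0.5, -0.3)) + rnorm(n)
  group <- rep(c("May", "July", "October"), each = 20)
  fit <- fgls(y, x, group, heteroscedastic = FALSE, structure = "none")
  ols <- ols_oracle(x, y)
  expect_equal(unname(fit$coefficients), unname(ols$beta), tolerance = 1e-10)
})

test_that("two-group feasible GLS matches the hand fixed-point solution", {
  set.seed(52)
  y <- c(rnorm(15, 5, 0.5), rnorm(25, 7, 3))
  group <- rep(c("May", "July"), c(15, 25))
  x <- matrix(1, length(y), 1)
  fit <- fgls(y, x, group, structure = "none")

  # independent fixed-point iteration for the intercept-only weighted mean
  mu <- mean(y)
  for (i in 1:200) {
    s1 <- mean((y[group == "May"] - mu)^2)
    s2 <- mean((y[group == "July"] - mu)^2)
    w <- ifelse(group == "May", 1 / s1, 1 / s2)
    mu_new <- sum(w * y) / sum(w)
    if (abs(mu_new - mu) < 1e-12) break
    mu <- mu_new
  }
  expect_equal(unname(fit$coefficients), mu, tolerance = 1e-6)
  expect_equal(unname(fit$sigma[c("May", "July")]), sqrt(c(s1, s2)),
               tolerance = 1e-6)
})

test_that("the FGLS fixed point agrees with ML gls on heteroscedastic data", {
  set.seed(53)
  df <- tidyr::crossing(plot_id = sprintf("P%02d", 1:26),
                        date = c("May", "July", "October")) |>
    dplyr::mutate(
      x = rnorm(dplyr::n()),
      sd = c(May = 1.5, July = 0.4, October = 0.3)[date],
      y = 2 + 0.7 * x + rnorm(dplyr::n(), 0, sd)
    )
  x_mat <- cbind(1, df$x)
  fit <- fgls(df$y, x_mat, df$date, structure = "none")
  ref <- nlme::gls(y ~ x, data = df,
                   weights = nlme::varIdent(form = ~ 1 | date),
                   method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  # nlme reports SD multipliers relative to its reference stratum; rebuild
  # the absolute per-date SDs before comparing
  mult <- coef(ref$modelStruct$varStruct, unconstrained = FALSE)
  ref_stratum <- setdiff(c("May", "July", "October"), names(mult))
  ref_sigma <- ref$sigma * c(stats::setNames(1, ref_stratum), mult)
  expect_equal(unname(fit$sigma[names(ref_sigma)]), unname(ref_sigma),
               tolerance = 1e-4)
})

test_that("the seasonal model detects a date effect of realistic size", {
  params <- sim_params()
  design <- build_design()
  hits <- purrr::map_lgl(1:40, function(r) {
    latent <- simulate_latent(params, design, seed = 6000 + r) |>
      dplyr::filter(!drought)
    fit <- fit_seasonal_gls(latent, "G_m", correlation = "CS",
                            qc_filter = FALSE)
    p <- fit$anova$p.value[fit$anova$term == "date"]
    p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("structure selection compares none, CS and AR1 by AIC", {
  study <- generate_study(seed = 6, noise = FALSE)
  phys <- compute_physiology(study$raw)
  fit <- fit_seasonal_gls(phys, "G_m", design = study$design,
                          correlation = "AIC")
  expect_equal(fit$candidates$structure, c("none", "CS", "AR1"))
  expect_equal(glance(fit)$AIC, min(fit$candidates$AIC))
  expect_true(glance(fit)$converged)
  # per-term table covers the seasonal fixed effects
  expect_true(all(c("date", "eCO2", "eT", "eCO2^2", "date:eCO2", "date:eT",
                    "eCO2:eT", "date:eCO2:eT") %in% fit$anova$term))
  expect_true(all(fit$anova$statistic >= 0))
  expect_true(all(fit$anova$p.value >= 0 & fit$anova$p.value <= 1))
  td <- tidy(fit)
  expect_true(all(td$std.error > 0))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("singular designs and missing subjects are rejected", {
  y <- rnorm(9)
  x <- cbind(1, rep(1, 9))
  expect_error(fgls(y, x, rep(c("a", "b", "c"), 3)), "singular")
  x2 <- cbind(1, rnorm(9))
  expect_error(fgls(y, x2, rep(c("a", "b", "c"), 3), structure = "CS"),
               "subject")
})
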