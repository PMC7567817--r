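test_that("drought ANOVA sums of squares match a brute-force oracle", {
  # balanced 2x2 toy with integer cell means, 5 plots per cell
  cells <- list(
    ambient_control = c(10, 11, 9, 10, 10),
    ambient_drought = c(8, 7, 9, 8, 8),
    future_control = c(12, 13, 11, 12, 12),
    future_drought = c(18, 17, 19, 18, 18)
  )
  phys <- drought_toy_physiology(cells)
  design <- build_design()
  fit <- anova_drought(phys, design, date = "July", response = "value",
                       log_transform = FALSE)
  y <- phys$value
  sub <- dplyr::inner_join(phys, drought_subset(design), by = "plot_id")
  oracle <- anova_2x2_oracle(sub$value, sub$climate, sub$drought)
  tab <- fit$table
  expect_equal(tab$sumsq[tab$term == "climate"], oracle$climate,
               tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "drought"], oracle$drought,
               tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "climate:drought"], oracle$interaction,
               tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "Residuals"], oracle$residual,
               tolerance = 1e-10)
  # decomposition closes: component SS add to the total SS
  expect_equal(sum(tab$sumsq), oracle$total, tolerance = 1e-9)
  expect_equal(tab$meansq, tab$sumsq / tab$df)
  expect_equal(tab$df[1:3], c(1, 1, 1))
})

test_that("drought ANOVA flags empty factorial cells", {
  cells <- list(
    ambient_control = c(10, 11), ambient_drought = c(8, 7),
    future_control = c(12, 13), future_drought = c(18, 17)
  )
  phys <- drought_toy_physiology(cells) |>
    dplyr::filter(!(plot_id %in% drought_toy_physiology(cells)$plot_id[1:2]))
  design <- build_design()
  # removing both ambient controls empties a cell
  expect_error(
    anova_drought(phys, design, date = "July", response = "value",
                  log_transform = FALSE),
    "empty cell"
  )
})

test_that("two-group Tukey reduces to the unadjusted two-sample comparison", {
  set.seed(61)
  df <- tibble::tibble(
    g = rep(c("a", "b"), each = 8),
    y = c(rnorm(8, 0), rnorm(8, 1))
  )
  tk <- tukey_hsd(df, response = "y", group = "g")
  tt <- stats::t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(tk$comparisons$adj.p.value, tt$p.value, tolerance = 1e-10)
  # studentized-range statistic is |t| * sqrt(2)
  expect_equal(tk$comparisons$statistic,
               abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
})

test_that("Tukey letters separate exactly the distinguishable groups", {
  # equal group means: a single shared letter
  df_null <- tibble::tibble(
    g = rep(c("a", "b", "c", "d"), each = 3),
    y = rep(c(1, 2, 3), times = 4)
  )
  tk0 <- tukey_hsd(df_null, response = "y", group = "g")
  expect_true(all(tk0$comparisons$adj.p.value > 0.99))
  expect_equal(unique(tk0$letters$letters), "a")

  # one group shifted far beyond the noise gets a unique letter
  set.seed(62)
  df_shift <- tibble::tibble(
    g = rep(c("a", "b", "c", "d"), each = 6),
    y = c(rnorm(6, 0, 0.1), rnorm(6, 0, 0.1), rnorm(6, 0, 0.1),
          rnorm(6, 10, 0.1))
  )
  tks <- tukey_hsd(df_shift, response = "y", group = "g")
  lets <- tks$letters
  shifted <- lets$letters[lets$group == "d"]
  expect_false(shifted %in% lets$letters[lets$group != "d"])
  expect_equal(length(unique(lets$letters[lets$group != "d"])), 1)
})

test_that("Tukey adjustment never reports smaller p than the pairwise t test", {
  set.seed(63)
  for (i in 1:10) {
    df <- tibble::tibble(
      g = rep(letters[1:4], each = 6),
      y = rnorm(24, mean = rep(runif(4, 0, 1), each = 6))
    )
    tk <- tukey_hsd(df, response = "y", group = "g")
    fit <- stats::aov(y ~ g, data = df)
    mse <- stats::deviance(fit) / stats::df.residual(fit)
    for (j in seq_len(nrow(tk$comparisons))) {
      gs <- strsplit(tk$comparisons$contrast[j], " - ")[[1]]
      y1 <- df$y[df$g == gs[1]]; y2 <- df$y[df$g == gs[2]]
      t_stat <- abs(mean(y1) - mean(y2)) / sqrt(mse * (1 / 6 + 1 / 6))
      p_unadj <- 2 * stats::pt(t_stat, stats::df.residual(fit),
                               lower.tail = FALSE)
      expect_gte(tk$comparisons$adj.p.value[j] + 1e-12, p_unadj)
    }
  }
})

test_that("a built-in interaction surfaces in the synthetic drought factorial", {
  study <- generate_study(seed = 30)
  phys <- compute_physiology(study$raw)
  fit <- anova_drought(phys, study$design, date = "July", response = "G_m")
  tab <- fit$table
  expect_equal(tab$term[1:3], c("climate", "drought", "climate:drought"))
  # generating truth: drought raises growth under future climate only,
  # so the climate x drought interaction must dominate
  expect_lt(tab$p.value[tab$term == "climate:drought"], 0.05)
  tk <- tukey_hsd(fit)
  expect_equal(nrow(tk$comparisons), 6)
  expect_equal(nrow(tk$letters), 4)
  p <- autoplot(fit, tukey = tk)
  expect_s3_class(p, "ggplot")
})
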