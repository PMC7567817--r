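# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the code paths they check: explicit normal equations,
# brute-force sum-of-squares decompositions and hand fixed-point iterations.

# normal-equation OLS solved explicitly via (X'X)^-1 X'y
ols_oracle <- function(x, y) {
  xtx_inv <- solve(crossprod(x))
  beta <- drop(xtx_inv %*% crossprod(x, y))
  r <- y - drop(x %*% beta)
  s2 <- sum(r^2) / (length(y) - ncol(x))
  list(beta = beta, se = sqrt(diag(xtx_inv) * s2))
}

# random small response-surface dataset on coded factor levels
random_rsm_data <- function(n = NULL) {
  n <- n %||% sample(12:30, 1)
  tibble::tibble(
    eCO2 = sample(c(-1, 0, 1), n, replace = TRUE),
    eT = sample(c(-1, 0, 1), n, replace = TRUE),
    y = stats::rnorm(n)
  )
}

rsm_model_matrix <- function(df) {
  cbind(1, df$eCO2, df$eT, df$eCO2^2, df$eT^2, df$eCO2 * df$eT)
}

# brute-force sequential sum-of-squares decomposition for a balanced 2x2
# factorial, enumerating group means directly
anova_2x2_oracle <- function(y, f1, f2) {
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  m1 <- tapply(y, f1, mean)
  ss1 <- sum(tapply(y, f1, length) * (m1 - grand)^2)
  m2 <- tapply(y, f2, mean)
  ss2 <- sum(tapply(y, f2, length) * (m2 - grand)^2)
  cell <- tapply(y, list(f1, f2), mean)
  ncell <- tapply(y, list(f1, f2), length)
  ss_cells <- sum(ncell * (cell - grand)^2)
  ss_int <- ss_cells - ss1 - ss2
  ss_res <- ss_total - ss_cells
  list(climate = ss1, drought = ss2, interaction = ss_int,
       residual = ss_res, total = ss_total)
}

# physiology tibble wrapper for hand-built drought-factorial toys
drought_toy_physiology <- function(values, date = "July") {
  # values: named list ambient_control / ambient_drought / future_control /
  # future_drought, each a numeric vector of equal length
  design <- build_design()
  sub <- drought_subset(design)
  pick <- function(climate, drought, k) {
    ids <- sub$plot_id[sub$climate == climate & sub$drought == drought]
    ids[seq_len(k)]
  }
  rows <- purrr::imap_dfr(values, function(v, key) {
    climate <- sub("_(control|drought)$", "", key)
    drought <- grepl("_drought$", key)
    tibble::tibble(plot_id = pick(climate, drought, length(v)),
                   date = date, value = v)
  })
  dplyr::mutate(rows, qc_flags = "")
}

# single-sample raw bundle built by hand from instrument readings
hand_bundle <- function() {
  key <- tibble::tibble(plot_id = "P01", date = "May")
  list(
    irms = dplyr::bind_rows(
      dplyr::mutate(key, labeled = TRUE, dna_at_percent = 1.20,
                    total_oxygen_ug_per_gdm = 10),
      dplyr::mutate(key, labeled = FALSE, dna_at_percent = 0.20,
                    total_oxygen_ug_per_gdm = 10)
    ),
    dna = dplyr::mutate(key, dna_ug_per_gdm = 40),
    gc = dplyr::mutate(key, headspace_ml = 26, sampled_ml = 5,
                       co2_t0_ppm = 400, co2_repl_ppm = 400,
                       co2_tend_ppm = 1400, temp_c = 20, duration_h = 24,
                       dry_mass_g = 0.3),
    cfe = dplyr::mutate(key, eoc_fum = 145, eoc_unfum = 55),
    # 0.1 g native water at 0.20 at% + 0.04 g label at 87.7 at% -> 25.20 at%
    gravimetry = dplyr::mutate(key, fresh_soil_g = 0.4, gwc_g_per_g = 0.25,
                               label_water_g = 0.04, label_atpct = 87.7)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
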