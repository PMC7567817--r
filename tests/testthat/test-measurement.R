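test_that("soil-water mixing follows the isotope mass balance", {
  # degenerate mixing: label at natural abundance changes nothing
  expect_equal(soil_water_enrichment(0.4, 0.25, 0.05, 0.2005), 0.2005)
  # no native water: result is the pure label
  expect_equal(soil_water_enrichment(0.4, 0, 0.05, 97), 97)
  # hand mass balance: (0.1*0.20 + 0.04*97)/0.14
  expect_equal(
    soil_water_enrichment(0.4, 0.25, 0.04, 97, natural_abundance = 0.20),
    (0.1 * 0.20 + 0.04 * 97) / 0.14,
    tolerance = 1e-12
  )
  expect_equal(
    round(soil_water_enrichment(0.4, 0.25, 0.04, 97, natural_abundance = 0.20), 3),
    27.857
  )
  expect_error(soil_water_enrichment(0.4, 0, 0, 97), "water mass")
})

test_that("mixing is monotone and scale-invariant in the masses", {
  set.seed(11)
  for (i in 1:50) {
    fresh <- runif(1, 0.1, 1)
    gwc <- runif(1, 0.05, 0.5)
    label <- runif(1, 0.01, 0.2)
    a_label <- runif(1, 50, 99)
    base <- soil_water_enrichment(fresh, gwc, label, a_label)
    more_label <- soil_water_enrichment(fresh, gwc, label * 1.3, a_label)
    richer <- soil_water_enrichment(fresh, gwc, label, min(a_label * 1.01, 100))
    expect_gt(more_label, base)
    expect_gt(richer, base)
    expect_gt(base, 0.2005)
    expect_lt(base, a_label)
    # consistent unit change (g -> mg on every mass) leaves the at% unchanged
    mg <- soil_water_enrichment(fresh * 1000, gwc, label * 1000, a_label)
    expect_equal(mg, base, tolerance = 1e-12)
  }
})

test_that("label-enrichment targeting inverts the mixing model", {
  expect_equal(label_enrichment_for_target(0.1, 0.04, 0.2005), 0.2005)
  # hand inverse: solve (0.02 + 0.04 a)/0.14 = 25
  expect_equal(
    label_enrichment_for_target(0.1, 0.04, 25, natural_abundance = 0.20),
    (25 * 0.14 - 0.02) / 0.04,
    tolerance = 1e-12
  )
  expect_error(label_enrichment_for_target(1000, 0.01, 25), "exceeds 100")
  set.seed(12)
  for (i in 1:50) {
    m_native <- runif(1, 0.05, 1)
    m_label <- runif(1, 0.02, 0.5)
    a_true <- runif(1, 1, 99)
    target <- soil_water_enrichment(1, m_native, m_label, a_true)
    a <- label_enrichment_for_target(m_native, m_label, target)
    expect_lt(abs(a - a_true), 1e-9)
  }
})

test_that("fumigation-extraction MBC uses the efficiency correction", {
  expect_equal(mbc_from_cfe(100, 100), 0)
  expect_equal(mbc_from_cfe(145, 55), 90 / 0.45)
  expect_equal(round(mbc_from_cfe(50, 60), 2), -22.22)
  expect_error(mbc_from_cfe(100, 50, kec = 0), "kec")
  expect_error(mbc_from_cfe(100, 50, kec = -0.2), "kec")
})

test_that("DNA production follows the 18O tracer arithmetic", {
  expect_equal(dna_production(0.20, 0.20, 10, 25.2, 0.20), 0)
  # hand oracle: f = 1/25, (10 * 0.04 / 0.3121) / 24
  expect_equal(
    dna_production(1.20, 0.20, 10, 25.20, natural_abundance = 0.20),
    (10 * 0.04 / 0.3121) / 24,
    tolerance = 1e-12
  )
  # linear in total oxygen
  expect_equal(
    dna_production(1.20, 0.20, 20, 25.20, natural_abundance = 0.20),
    2 * dna_production(1.20, 0.20, 10, 25.20, natural_abundance = 0.20)
  )
  expect_error(dna_production(1.2, 0.2, 10, water_at = 0.1),
               "natural abundance")
})

test_that("growth scales DNA production by the biomass C : DNA ratio", {
  expect_equal(growth_rate(0, 200, 40), 0)
  expect_equal(growth_rate(0.0534, 200, 40), 0.0534 * 5)
  expect_equal(growth_rate(0.05, 400, 40), 2 * growth_rate(0.05, 200, 40))
  expect_error(growth_rate(0.05, 200, 0), "dna_total")
  expect_error(growth_rate(0.05, -1, 40), "mbc")
})

test_that("headspace respiration follows the ideal-gas mass balance", {
  # replacement air at the t0 concentration: C_start = co2_t0
  expect_equal(respiration_rate(26, 5, 400, 400, 400, 20, 24, 0.3), 0)
  # hand ideal-gas oracle for a 1000 ppm accumulation
  mol <- 1000e-6 * 0.026 / (0.082057 * 293.15)
  expect_equal(
    respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.3),
    mol * 12.011e6 / (24 * 0.3),
    tolerance = 1e-12
  )
  expect_equal(round(respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.3), 3),
               1.803)
  # halving dry mass doubles the per-gram rate
  expect_equal(respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.15),
               2 * respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.3))
  # replacement-air correction: diluting with CO2-free air lowers C_start
  expect_gt(respiration_rate(26, 5, 400, 0, 1400, 20, 24, 0.3),
            respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.3))
  expect_error(respiration_rate(26, 30, 400, 400, 1400, 20, 24, 0.3),
               "sampled volume")
  expect_error(respiration_rate(26, 5, 400, 400, 1400, -300, 24, 0.3),
               "absolute zero")
})

test_that("CUE is the growth fraction of uptake with guarded edge cases", {
  expect_equal(cue(1, 1), 0.5)
  expect_equal(cue(1, 0), 1)
  expect_equal(cue(2, 3), 0.4)
  expect_true(is.na(cue(0, 0)))
  expect_true(is.na(cue(-1, 2)))
  # scale invariance
  set.seed(13)
  g <- runif(20); r <- runif(20); c_scale <- runif(20, 0.1, 10)
  expect_equal(cue(c_scale * g, c_scale * r), cue(g, r))
})

test_that("biomass-specific rates are ratios in mg per g MBC", {
  expect_equal(biomass_specific(0, 200), 0)
  expect_equal(biomass_specific(0.267, 200), 1.335)
  expect_equal(biomass_specific(0.5, 100), biomass_specific(5, 1000))
  expect_error(biomass_specific(1, 0), "mbc")
})

test_that("aliquot oxygen scaling and dry mass helpers are consistent", {
  expect_equal(dry_mass(0.4, 0.25), 0.3)
  expect_equal(scale_aliquot_oxygen(2, 50, 100, 0.4), 2 * 2 / 0.4)
  expect_error(scale_aliquot_oxygen(2, 50, 10, 0.4), "extract_ul")
})
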