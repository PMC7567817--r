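# Physical constants used by the measurement model.
# DNA_O_FRACTION: proportional mass of oxygen in an average DNA formula
# (31.21 weight%). R_GAS_L_ATM: ideal gas constant in L atm mol^-1 K^-1.
DNA_O_FRACTION <- 0.3121
R_GAS_L_ATM <- 0.082057
C_MOLAR_MASS <- 12.011
NATURAL_ABUNDANCE_18O <- 0.2005

#' Soil-water 18O enrichment after label addition
#'
#' Isotope mass balance of mixing native soil water with a spike of
#' 18O-enriched water: the resulting atom fraction is the O-mass-weighted
#' mean of the two pools.
#'
#' @param fresh_soil_mass Fresh soil mass (g).
#' @param gravimetric_water_content Water mass per gram fresh soil (g/g).
#' @param label_water_mass Mass of labelled water added (g).
#' @param label_enrichment 18O enrichment of the label (at%).
#' @param natural_abundance Natural 18O abundance (at%), default 0.2005
#'   (VSMOW).
#' @return Soil-water 18O enrichment (at%) after mixing.
#' @export
#' @examples
#' # 0.10 g native water at 0.20 at% + 0.040 g label at 97.0 at%
#' soil_water_enrichment(0.4, 0.25, 0.040, 97, natural_abundance = 0.20)
soil_water_enrichment <- function(fresh_soil_mass, gravimetric_water_content,
                                  label_water_mass, label_enrichment,
                                  natural_abundance = NATURAL_ABUNDANCE_18O) {
  stopifnot(all(fresh_soil_mass >= 0), all(label_water_mass >= 0),
            all(gravimetric_water_content >= 0),
            all(gravimetric_water_content < 1))
  if (any(natural_abundance <= 0) || any(label_enrichment > 100) ||
      any(label_enrichment < natural_abundance)) {
    stop("enrichments must satisfy 0 < natural_abundance <= label_enrichment <= 100",
         call. = FALSE)
  }
  m_native <- fresh_soil_mass * gravimetric_water_content
  total <- m_native + label_water_mass
  if (any(total <= 0)) {
    stop("total water mass is zero: cannot form a soil solution", call. = FALSE)
  }
  (m_native * natural_abundance + label_water_mass * label_enrichment) / total
}

#' Label enrichment needed to hit a target soil-water enrichment
#'
#' Inverts [soil_water_enrichment()]: given the native water pool and the
#' label volume, returns the label at% that brings the mixed soil solution to
#' the target (the study aimed for approximately 25 at%).
#'
#' @param m_native Native soil water mass (g).
#' @param m_label Label water mass (g), > 0.
#' @param target Target soil-water enrichment (at%).
#' @param natural_abundance Natural 18O abundance (at%).
#' @return Required label enrichment (at%).
#' @export
label_enrichment_for_target <- function(m_native, m_label, target,
                                        natural_abundance = NATURAL_ABUNDANCE_18O) {
  stopifnot(all(m_label > 0), all(m_native >= 0))
  if (any(target < natural_abundance)) {
    stop("target enrichment below natural abundance", call. = FALSE)
  }
  req <- (target * (m_native + m_label) - m_native * natural_abundance) / m_label
  if (any(req > 100)) {
    stop(sprintf(
      "target unreachable: required label enrichment %.2f at%% exceeds 100 at%%",
      max(req)), call. = FALSE)
  }
  req
}

#' Microbial biomass carbon from chloroform fumigation-extraction
#'
#' MBC is the fumigation-induced increase in extractable organic carbon
#' divided by an extraction-efficiency factor (0.45). Negative differences
#' are returned as computed; downstream code flags them (`NEGATIVE_MBC`)
#' rather than censoring.
#'
#' @param eoc_fumigated Extractable organic C of the fumigated extract
#'   (ug C per g dry mass).
#' @param eoc_unfumigated Extractable organic C of the unfumigated extract.
#' @param kec Extraction efficiency factor in (0, 1], default 0.45.
#' @return MBC (ug C per g dry mass).
#' @export
#' @examples
#' mbc_from_cfe(145, 55)  # 200
mbc_from_cfe <- function(eoc_fumigated, eoc_unfumigated, kec = 0.45) {
  if (any(kec <= 0) || any(kec > 1)) {
    stop("kec must lie in (0, 1]", call. = FALSE)
  }
  (eoc_fumigated - eoc_unfumigated) / kec
}

#' DNA production rate from 18O incorporation
#'
#' The atom-percent excess of the labelled DNA over its natural-abundance
#' control, relative to the excess of the soil water, gives the fraction of
#' DNA oxygen that is newly synthesised. Dividing the new-DNA oxygen mass by
#' the oxygen weight fraction of DNA (31.21%) converts it to DNA mass, and
#' the incubation time normalises it to a rate.
#'
#' @param dna_at_labeled 18O abundance of the labelled DNA (at%).
#' @param dna_at_control 18O abundance of the natural-abundance control DNA
#'   (at%).
#' @param total_oxygen Total oxygen in the labelled sample's DNA, scaled to
#'   the whole extract (ug O per g dry mass).
#' @param water_at Realised soil-water enrichment (at%).
#' @param natural_abundance Natural 18O abundance (at%).
#' @param incubation_hours Incubation duration (h), default 24.
#' @return DNA production rate (ug DNA per h per g dry mass). Negative
#'   values (labelled below control) are returned as computed for downstream
#'   qc flagging.
#' @export
#' @examples
#' dna_production(1.20, 0.20, 10, 25.20, natural_abundance = 0.20) # 0.0534
dna_production <- function(dna_at_labeled, dna_at_control, total_oxygen,
                           water_at,
                           natural_abundance = NATURAL_ABUNDANCE_18O,
                           incubation_hours = 24) {
  stopifnot(all(incubation_hours > 0), all(total_oxygen >= 0))
  if (any(water_at <= natural_abundance)) {
    stop("soil-water enrichment must exceed natural abundance for a label signal",
         call. = FALSE)
  }
  f_new <- (dna_at_labeled - dna_at_control) / (water_at - natural_abundance)
  oxygen_new <- total_oxygen * f_new
  (oxygen_new / DNA_O_FRACTION) / incubation_hours
}

#' Microbial growth rate from DNA production
#'
#' Growth in carbon units scales the DNA production rate by the per-sample
#' carbon-to-DNA ratio of the standing microbial biomass:
#' `G = DNA_p * MBC / DNA_total`.
#'
#' @param dna_p DNA production rate (ug DNA per h per g dry mass).
#' @param mbc Microbial biomass carbon (ug C per g dry mass), > 0.
#' @param dna_total Soil DNA concentration (ug DNA per g dry mass), > 0.
#' @return Growth rate G (ug C per h per g dry mass).
#' @export
growth_rate <- function(dna_p, mbc, dna_total) {
  if (any(dna_total <= 0, na.rm = TRUE)) {
    stop("dna_total must be > 0", call. = FALSE)
  }
  if (any(mbc <= 0, na.rm = TRUE)) {
    stop("mbc must be > 0; qc-flag negative MBC upstream", call. = FALSE)
  }
  dna_p * mbc / dna_total
}

#' Respiration rate from a two-point headspace CO2 series
#'
#' The first 5 ml gas sample is replaced with air of known CO2 concentration,
#' so the start-of-incubation headspace concentration is the volume-weighted
#' mean of the remaining headspace and the replacement air. The accumulated
#' ppm difference is converted to moles by the ideal gas law at 1 atm and to
#' carbon mass per hour per gram soil dry mass.
#'
#' @param headspace_ml Headspace volume (ml).
#' @param sampled_ml Volume removed and replaced at the first sampling (ml),
#'   default 5.
#' @param co2_t0 CO2 concentration measured immediately after amendment (ppm).
#' @param co2_repl CO2 concentration of the replacement air (ppm).
#' @param co2_tend CO2 concentration at the end of the incubation (ppm).
#' @param temp_c Incubation temperature (degC).
#' @param duration_h Incubation duration (h), default 24.
#' @param dry_mass_g Soil dry mass (g).
#' @param pressure_atm Headspace pressure (atm), default 1.
#' @return Respiration rate R (ug C per h per g dry mass). Negative
#'   accumulations are returned as computed for qc flagging.
#' @export
#' @examples
#' respiration_rate(26, 5, 400, 400, 1400, 20, 24, 0.3)  # ~1.803
respiration_rate <- function(headspace_ml, sampled_ml = 5, co2_t0, co2_repl,
                             co2_tend, temp_c, duration_h = 24, dry_mass_g,
                             pressure_atm = 1) {
  stopifnot(all(duration_h > 0), all(dry_mass_g > 0))
  if (any(sampled_ml <= 0) || any(sampled_ml >= headspace_ml)) {
    stop("sampled volume must lie strictly between 0 and the headspace volume",
         call. = FALSE)
  }
  t_k <- temp_c + 273.15
  if (any(t_k <= 0)) stop("temperature below absolute zero", call. = FALSE)
  c_start <- (co2_t0 * (headspace_ml - sampled_ml) + co2_repl * sampled_ml) /
    headspace_ml
  delta_ppm <- co2_tend - c_start
  mol <- (delta_ppm * 1e-6) * pressure_atm * (headspace_ml / 1000) /
    (R_GAS_L_ATM * t_k)
  mol * C_MOLAR_MASS * 1e6 / (duration_h * dry_mass_g)
}

#' Carbon use efficiency
#'
#' The fraction of carbon uptake allocated to growth: `CUE = G / (G + R)`.
#' Defined only for non-negative G and R with positive uptake; other inputs
#' yield `NA` (the caller attaches qc flags).
#'
#' @param g Growth rate (ug C per h per g dry mass).
#' @param r Respiration rate (ug C per h per g dry mass).
#' @return CUE in [0, 1], or `NA` where undefined.
#' @export
#' @examples
#' cue(2, 3)  # 0.4
cue <- function(g, r) {
  u <- g + r
  out <- ifelse(!is.na(g) & !is.na(r) & g >= 0 & r >= 0 & u > 0, g / u, NA_real_)
  out
}

#' Biomass-specific rate
#'
#' Normalises a per-dry-mass carbon flux to the standing microbial biomass:
#' `1000 * rate / MBC`, in mg C per h per g MBC.
#'
#' @param rate Rate (ug C per h per g dry mass).
#' @param mbc Microbial biomass carbon (ug C per g dry mass), > 0.
#' @return Biomass-specific rate (mg C per h per g MBC).
#' @export
biomass_specific <- function(rate, mbc) {
  if (any(mbc <= 0, na.rm = TRUE)) stop("mbc must be > 0", call. = FALSE)
  1000 * rate / mbc
}

#' Soil dry mass from fresh mass and gravimetric water content
#'
#' @param fresh_soil_mass Fresh soil mass (g).
#' @param gravimetric_water_content Water mass per g fresh soil (g/g).
#' @return Dry mass (g).
#' @export
dry_mass <- function(fresh_soil_mass, gravimetric_water_content) {
  fresh_soil_mass * (1 - gravimetric_water_content)
}

#' Scale an IRMS aliquot oxygen reading to the whole extract
#'
#' 50 ul aliquots of the DNA extract are dried for IRMS; this helper scales
#' the aliquot oxygen mass to the whole extract and normalises per gram dry
#' soil.
#'
#' @param aliquot_oxygen_ug Oxygen in the dried aliquot (ug O).
#' @param aliquot_ul Aliquot volume (ul), default 50.
#' @param extract_ul Whole extract volume (ul).
#' @param dry_mass_g Soil dry mass extracted (g).
#' @return Total oxygen (ug O per g dry mass).
#' @export
scale_aliquot_oxygen <- function(aliquot_oxygen_ug, aliquot_ul = 50,
                                 extract_ul, dry_mass_g) {
  stopifnot(all(aliquot_ul > 0), all(extract_ul >= aliquot_ul),
            all(dry_mass_g > 0))
  aliquot_oxygen_ug * (extract_ul / aliquot_ul) / dry_mass_g
}
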