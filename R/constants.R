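# All physiological and analytical constants live here, in one defaults
# table.  No other file hard-codes a scoring or kinetics constant: every
# operation takes a `constants` argument defaulting to ee_constants(), so a
# cohort-specific recalibration is a single modifyList away and is visible
# in the run log.

#' Default constants for energy-expenditure scoring and DLW kinetics
#'
#' Returns the full table of numeric constants used across the package,
#' optionally overriding individual entries.  Every downstream function
#' (diary and recall scoring, indirect calorimetry, the DLW chain, the
#' method-comparison statistics) reads its constants from this table and
#' nowhere else.
#'
#' @details
#' The scoring constants are:
#' \describe{
#'   \item{sitting_factor (1.1)}{ratio of sitting resting metabolic rate to
#'     supine fasting BMR; multiplies the MET-weighted BMR.}
#'   \item{dit_divisor (0.9)}{accounts for diet-induced thermogenesis of
#'     about 10\% of intake: TEE = MET-weighted resting expenditure / 0.9.}
#'   \item{kcal_to_mj (4.184e-3)}{kilocalories to megajoules.}
#' }
#' The DLW constants follow the standard two-point/intercept framework with
#' the revised dilution-space proportions: \code{nd_space_factor} (1.041)
#' and \code{no_space_factor} (1.007) scale the deuterium and oxygen-18
#' dilution spaces to total body water, and \code{rco2_factor} (0.4554)
#' converts body water and the fractionation-corrected difference in
#' elimination rates into CO2 production (mol/day).  \code{weir_vo2} and
#' \code{weir_vco2} (3.941, 1.106 kcal/L) are the protein-free abbreviated
#' Weir coefficients, used both for calorimetric BMR and for DLW TEE at the
#' assumed respiratory quotient \code{rq} (0.85). \code{molar_volume_l}
#' (22.414 L/mol) converts CO2 moles to litres; the real-gas alternative
#' 22.26 may be substituted.
#'
#' Isotope bookkeeping uses the VSMOW absolute ratios (2H/1H = 155.76 ppm,
#' 18O/16O = 2005.20 ppm) to convert delta-permil enrichments to mole
#' fractions, and exact atomic masses to convert dose grams to tracer
#' moles.
#'
#' @param ... named overrides, e.g. \code{ee_constants(rq = 0.80)}.
#' @return A named list of constants.
#' @examples
#' cst <- ee_constants()
#' cst$sitting_factor
#' ee_constants(molar_volume_l = 22.26)$molar_volume_l
#' @export
ee_constants <- function(...) {
  defaults <- list(
    # diary / recall scoring
    sitting_factor   = 1.1,
    dit_divisor      = 0.9,
    kcal_to_mj       = 4.184e-3,
    very_light_mets  = 1.3,
    sleep_mets       = 0.9,
    # indirect calorimetry
    weir_vo2         = 3.941,   # kcal per L O2
    weir_vco2        = 1.106,   # kcal per L CO2
    vo2_steady_ml    = 25,      # max VO2 range (mL/min) for an acceptable collection
    # DLW kinetics
    nd_space_factor  = 1.041,
    no_space_factor  = 1.007,
    rco2_factor      = 0.4554,
    rq               = 0.85,
    molar_volume_l   = 22.414,  # L per mol CO2 (ideal gas, STP)
    ndno_band        = c(1.000, 1.070),
    # isotope bookkeeping (VSMOW absolute ratios, atomic masses in g/mol)
    r_vsmow_2h       = 155.76e-6,
    r_vsmow_18o      = 2005.20e-6,
    mass_1h          = 1.0078250319,
    mass_2h          = 2.0141017779,
    mass_h_natural   = 1.00794,
    mass_16o         = 15.9949146221,
    mass_18o         = 17.9991604,
    mass_o_natural   = 15.9994,
    # statistics
    loa_multiplier   = 1.96,
    alpha            = 0.01,
    outlier_k_sd     = 3
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("constant overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    defaults <- utils::modifyList(defaults, overrides)
  }
  defaults
}

# natural-abundance mole fractions implied by the VSMOW ratios
natural_mole_fraction <- function(ratio) ratio / (1 + ratio)
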