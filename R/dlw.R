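# Doubly-labeled-water calculator.  The chain is: dose grams -> moles of
# excess tracer; urine delta-permil series -> mole-fraction excess above
# the pre-dose baseline -> log-linear elimination rates and time-zero
# intercepts (the intercept method); dose / intercept -> dilution spaces
# -> total body water; rate difference -> CO2 production -> TEE by the
# abbreviated Weir equation at an assumed respiratory quotient.
#
# All enrichment arithmetic (baseline subtraction, averaging of duplicate
# samples) happens in mole-fraction space, not delta space: delta is a
# ratio relative to VSMOW and subtracting deltas is only approximate.

#' Construct a DLW dosing record
#'
#' Administered masses of the two labeled waters.  Typical dosing is
#' 0.12 g/kg predicted total body water of 2H2O at 99.8 atom% and
#' 2.5 g/kg of H2-18O at 10.0 atom%.
#'
#' @param mass_2h2o_g grams of deuterated water administered.
#' @param atom_pct_2h atom percent 2H of that water (default 99.8).
#' @param mass_h218o_g grams of 18O-labeled water administered.
#' @param atom_pct_18o atom percent 18O of that water (default 10.0).
#' @return An object of class `dosing_record`.
#' @export
dosing_record <- function(mass_2h2o_g, atom_pct_2h = 99.8,
                          mass_h218o_g, atom_pct_18o = 10.0) {
  if (!is.finite(mass_2h2o_g) || mass_2h2o_g <= 0 ||
      !is.finite(mass_h218o_g) || mass_h218o_g <= 0)
    stop("dose masses must be positive", call. = FALSE)
  if (atom_pct_2h <= 0 || atom_pct_2h > 100 ||
      atom_pct_18o <= 0 || atom_pct_18o > 100)
    stop("atom percents must lie in (0, 100]", call. = FALSE)
  structure(list(mass_2h2o_g = mass_2h2o_g, atom_pct_2h = atom_pct_2h,
                 mass_h218o_g = mass_h218o_g, atom_pct_18o = atom_pct_18o),
            class = "dosing_record")
}

#' Construct an isotope-enrichment series
#'
#' Urine delta-permil enrichments versus VSMOW.  The row at
#' `time_days == 0` is the pre-dose baseline; the standard sampling
#' design takes duplicate post-dose samples on the mornings of days 1, 8
#' and 15.
#'
#' @param time_days days since dose (0 = baseline), non-negative.
#' @param delta_2h_permil,delta_18o_permil enrichments in permil vs
#'   VSMOW.
#' @return A data frame of class `isotope_samples`.
#' @export
isotope_samples <- function(time_days, delta_2h_permil, delta_18o_permil) {
  n <- length(time_days)
  if (length(delta_2h_permil) != n || length(delta_18o_permil) != n)
    stop("time and delta vectors must have equal length", call. = FALSE)
  if (any(time_days < 0))
    stop("time_days must be non-negative", call. = FALSE)
  if (!any(time_days == 0))
    stop("a pre-dose baseline sample (time_days = 0) is required",
         call. = FALSE)
  out <- data.frame(time_days = as.numeric(time_days),
                    delta_2h_permil = as.numeric(delta_2h_permil),
                    delta_18o_permil = as.numeric(delta_18o_permil))
  out <- out[order(out$time_days), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("isotope_samples", "data.frame")
  out
}

# delta (permil vs VSMOW) <-> isotope mole fraction of the element pool
delta_to_mole_fraction <- function(delta_permil, r_standard) {
  r <- r_standard * (1 + delta_permil / 1000)
  r / (1 + r)
}

mole_fraction_to_delta <- function(x, r_standard) {
  r <- x / (1 - x)
  (r / r_standard - 1) * 1000
}

#' Moles of excess tracer in a DLW dose
#'
#' For each labeled water: grams / molar mass of that water (computed
#' from its isotopic composition) gives moles of water; times the number
#' of atoms of the traced element per molecule (2 for H, 1 for O); times
#' the excess atom fraction (dose atom fraction minus natural abundance)
#' gives moles of excess tracer atoms delivered.
#'
#' @param dose a [dosing_record()].
#' @param constants see [ee_constants()] (atomic masses, VSMOW ratios).
#' @return A list with `mol_2h` and `mol_18o`, moles of excess tracer
#'   atoms.
#' @export
tracer_moles <- function(dose, constants = ee_constants()) {
  stopifnot(inherits(dose, "dosing_record"))
  a_2h <- dose$atom_pct_2h / 100
  a_18o <- dose$atom_pct_18o / 100
  molar_2h2o <- 2 * (a_2h * constants$mass_2h +
                       (1 - a_2h) * constants$mass_1h) +
    constants$mass_o_natural
  molar_h218o <- 2 * constants$mass_h_natural +
    (a_18o * constants$mass_18o + (1 - a_18o) * constants$mass_16o)
  nat_2h <- natural_mole_fraction(constants$r_vsmow_2h)
  nat_18o <- natural_mole_fraction(constants$r_vsmow_18o)
  list(mol_2h = dose$mass_2h2o_g / molar_2h2o * 2 * (a_2h - nat_2h),
       mol_18o = dose$mass_h218o_g / molar_h218o * 1 * (a_18o - nat_18o))
}

# post-dose mole-fraction excess above the pre-dose baseline, per isotope
excess_table <- function(samples, constants) {
  stopifnot(inherits(samples, "isotope_samples"))
  base <- samples[samples$time_days == 0, , drop = FALSE]
  post <- samples[samples$time_days > 0, , drop = FALSE]
  x_base_2h <- mean(delta_to_mole_fraction(base$delta_2h_permil,
                                           constants$r_vsmow_2h))
  x_base_18o <- mean(delta_to_mole_fraction(base$delta_18o_permil,
                                            constants$r_vsmow_18o))
  data.frame(
    time_days = post$time_days,
    excess_2h = delta_to_mole_fraction(post$delta_2h_permil,
                                       constants$r_vsmow_2h) - x_base_2h,
    excess_18o = delta_to_mole_fraction(post$delta_18o_permil,
                                        constants$r_vsmow_18o) - x_base_18o
  )
}

#' Fit an isotope elimination curve (intercept method)
#'
#' Ordinary least squares of log mole-fraction excess on time over the
#' post-dose samples in `window`.  The elimination rate is minus the
#' slope; back-extrapolating to dose time gives the time-zero excess used
#' for the dilution space.  Duplicate samples at one time point enter as
#' separate observations.
#'
#' @param samples an [isotope_samples()] series.
#' @param isotope `"2H"` or `"18O"`.
#' @param window numeric `c(t_start, t_end)` in days; post-dose samples
#'   with `t_start <= t <= t_end` are used (default: all).
#' @param constants see [ee_constants()].
#' @return A list: `k_perday` (elimination rate), `excess0` (time-zero
#'   mole-fraction excess), `n` (points used), `fit` (the `lm` object, or
#'   NULL for the two-point case).
#' @export
fit_elimination <- function(samples, isotope = c("2H", "18O"),
                            window = c(0, Inf),
                            constants = ee_constants()) {
  isotope <- match.arg(isotope)
  ex <- excess_table(samples, constants)
  ex <- ex[ex$time_days >= window[1] & ex$time_days <= window[2], ,
           drop = FALSE]
  y <- if (isotope == "2H") ex$excess_2h else ex$excess_18o
  t <- ex$time_days
  if (length(t) < 2)
    stop("need at least 2 post-dose samples in the window", call. = FALSE)
  if (any(y <= 0))
    stop("post-dose ", isotope, " enrichment at or below baseline; ",
         "cannot fit elimination", call. = FALSE)
  fit <- stats::lm(log(y) ~ t)
  coefs <- stats::coef(fit)
  list(k_perday = -unname(coefs[2]),
       excess0 = exp(unname(coefs[1])),
       n = length(t),
       fit = fit)
}

# combine already-computed dilution spaces into TBW with QC on the ratio
combine_dilution_spaces <- function(n_d_mol, n_o_mol,
                                    constants = ee_constants()) {
  ratio <- n_d_mol / n_o_mol
  qc_pass <- ratio >= constants$ndno_band[1] & ratio <= constants$ndno_band[2]
  if (!qc_pass)
    warning(sprintf(
      "dilution-space ratio Nd/No = %.4f outside plausibility band [%.3f, %.3f]",
      ratio, constants$ndno_band[1], constants$ndno_band[2]), call. = FALSE)
  list(tbw_mol = mean(c(n_d_mol / constants$nd_space_factor,
                        n_o_mol / constants$no_space_factor)),
       nd_no_ratio = ratio, qc_pass = qc_pass)
}

#' Dilution spaces and total body water
#'
#' Each dilution space is the administered excess tracer divided by the
#' time-zero excess per atom of the element pool: for deuterium the dose
#' spreads over two hydrogen sites per water molecule, so
#' `N_d = mol_2h / (2 x excess0_2h)`; for 18O, `N_O = mol_18o /
#' excess0_18o`.  Total body water is the mean of `N_d / 1.041` and
#' `N_O / 1.007` (the dilution spaces exceed body water by isotope
#' exchange, more so for 2H).  A dilution-space ratio outside the
#' plausibility band raises a QC warning but the result is still
#' returned, flagged.
#'
#' @param dose a [dosing_record()].
#' @param excess0_2h,excess0_18o time-zero mole-fraction excesses from
#'   [fit_elimination()].
#' @param constants see [ee_constants()].
#' @return A list: `n_d_mol`, `n_o_mol`, `tbw_mol`, `nd_no_ratio`,
#'   `qc_pass`.
#' @export
dilution_spaces <- function(dose, excess0_2h, excess0_18o,
                            constants = ee_constants()) {
  if (excess0_2h <= 0 || excess0_18o <= 0)
    stop("time-zero excesses must be positive", call. = FALSE)
  moles <- tracer_moles(dose, constants)
  n_d <- moles$mol_2h / (2 * excess0_2h)
  n_o <- moles$mol_18o / excess0_18o
  c(list(n_d_mol = n_d, n_o_mol = n_o),
    combine_dilution_spaces(n_d, n_o, constants))
}

#' CO2 production rate from DLW kinetics
#'
#' `rCO2 (mol/day) = 0.4554 x TBW x (1.007 k_O - 1.041 k_D)`: the 18O
#' tracer leaves body water through both water and CO2 while 2H leaves
#' through water only, so the fractionation-corrected rate difference
#' isolates CO2 production.  The constants embody breath-water isotope
#' fractionation with the revised dilution-space proportions.
#'
#' @param tbw_mol total body water, mol.
#' @param k_o_perday,k_d_perday elimination rates, 1/day.
#' @param constants see [ee_constants()].
#' @return CO2 production in mol/day.
#' @examples
#' rco2(2000, k_o_perday = 0.12, k_d_perday = 0.10)  # 15.246 mol/day
#' @export
rco2 <- function(tbw_mol, k_o_perday, k_d_perday,
                 constants = ee_constants()) {
  if (tbw_mol <= 0 || k_o_perday <= 0 || k_d_perday < 0)
    stop("tbw and elimination rates must be positive", call. = FALSE)
  bracket <- constants$no_space_factor * k_o_perday -
    constants$nd_space_factor * k_d_perday
  # tolerate rounding at the null-production boundary
  if (abs(bracket) < 1e-12 * k_o_perday) bracket <- 0
  if (bracket < 0)
    stop("negative CO2 production: 1.007 k_O < 1.041 k_D ",
         "(swapped isotopes or a failed fit?)", call. = FALSE)
  constants$rco2_factor * tbw_mol * bracket
}

#' TEE from CO2 production (modified Weir at assumed RQ)
#'
#' CO2 moles are converted to daily litres by the molar volume, oxygen
#' consumption follows from the assumed respiratory quotient
#' (`VO2 = VCO2 / RQ`), and the abbreviated Weir equation gives
#' kcal/day, converted to MJ/day.
#'
#' @param rco2_mol_day CO2 production, mol/day.
#' @param rq assumed respiratory quotient, in (0.6, 1.1); default 0.85.
#' @param constants see [ee_constants()].
#' @return TEE in MJ/day.
#' @export
tee_from_rco2 <- function(rco2_mol_day, rq = ee_constants()$rq,
                          constants = ee_constants()) {
  if (rco2_mol_day < 0)
    stop("CO2 production must be non-negative", call. = FALSE)
  if (rq <= 0.6 || rq >= 1.1)
    stop("respiratory quotient must lie in (0.6, 1.1)", call. = FALSE)
  vco2_l_day <- rco2_mol_day * constants$molar_volume_l
  vo2_l_day <- vco2_l_day / rq
  weir_ee_kcal_per_day(vo2_l_day, vco2_l_day, constants) *
    constants$kcal_to_mj
}

# day-binned mean log excess for the two-point weekly slopes; duplicates
# within a morning are averaged in mole-fraction space first
day_bin_excess <- function(ex, isotope) {
  day <- round(ex$time_days)
  y <- if (isotope == "2H") ex$excess_2h else ex$excess_18o
  agg <- stats::aggregate(cbind(t = ex$time_days, y = y),
                          by = list(day = day), FUN = mean)
  agg
}

two_point_k <- function(agg, day_a, day_b) {
  ia <- match(day_a, agg$day); ib <- match(day_b, agg$day)
  if (is.na(ia) || is.na(ib))
    stop("missing endpoint sampling day ", if (is.na(ia)) day_a else day_b,
         call. = FALSE)
  if (agg$y[ia] <= 0 || agg$y[ib] <= 0)
    stop("non-positive excess at an endpoint day", call. = FALSE)
  (log(agg$y[ia]) - log(agg$y[ib])) / (agg$t[ib] - agg$t[ia])
}

#' Full DLW computation for one study week
#'
#' Assembles the whole chain for a 14-day protocol sampled at baseline
#' and on the mornings of days 1, 8 and 15 (duplicates welcome):
#' dilution spaces come from the full-period intercept fits (all
#' post-dose points), while the elimination rates for the requested week
#' are two-point log slopes between that week's endpoint days (1 to 8, or
#' 8 to 15), with same-morning duplicates averaged.  CO2 production, TEE
#' and PAL (= TEE / BMR) follow.
#'
#' @param samples an [isotope_samples()] series covering the protocol.
#' @param dose a [dosing_record()].
#' @param bmr_mj_day measured BMR in MJ/day (for PAL).
#' @param week 1 (days 1-8) or 2 (days 8-15).
#' @param constants see [ee_constants()].
#' @return An object of class `dlw_result`: `n_d_mol`, `n_o_mol`,
#'   `tbw_mol`, `k_d_perday`, `k_o_perday`, `rco2_mol_day`, `tee_mj_day`,
#'   `pal`, `nd_no_ratio`, `qc_pass`, `week`.
#' @export
dlw_week <- function(samples, dose, bmr_mj_day, week = 1,
                     constants = ee_constants()) {
  if (!week %in% c(1, 2))
    stop("week must be 1 or 2", call. = FALSE)
  if (!is.finite(bmr_mj_day) || bmr_mj_day <= 0)
    stop("bmr_mj_day must be positive", call. = FALSE)
  fit_d <- fit_elimination(samples, "2H", constants = constants)
  fit_o <- fit_elimination(samples, "18O", constants = constants)
  spaces <- dilution_spaces(dose, fit_d$excess0, fit_o$excess0, constants)

  ex <- excess_table(samples, constants)
  endpoints <- if (week == 1) c(1, 8) else c(8, 15)
  k_d <- two_point_k(day_bin_excess(ex, "2H"), endpoints[1], endpoints[2])
  k_o <- two_point_k(day_bin_excess(ex, "18O"), endpoints[1], endpoints[2])

  r <- rco2(spaces$tbw_mol, k_o, k_d, constants)
  tee <- tee_from_rco2(r, constants$rq, constants)
  structure(list(n_d_mol = spaces$n_d_mol, n_o_mol = spaces$n_o_mol,
                 tbw_mol = spaces$tbw_mol,
                 k_d_perday = k_d, k_o_perday = k_o,
                 rco2_mol_day = r, tee_mj_day = tee,
                 pal = tee / bmr_mj_day,
                 nd_no_ratio = spaces$nd_no_ratio,
                 qc_pass = spaces$qc_pass, week = week),
            class = "dlw_result")
}

#' @export
print.dlw_result <- function(x, ...) {
  cat(sprintf("DLW week %d: TEE %.2f MJ/d | PAL %.2f | rCO2 %.2f mol/d\n",
              x$week, x$tee_mj_day, x$pal, x$rco2_mol_day))
  cat(sprintf("  TBW %.0f mol | kO %.4f /d | kD %.4f /d | Nd/No %.4f%s\n",
              x$tbw_mol, x$k_o_perday, x$k_d_perday, x$nd_no_ratio,
              if (x$qc_pass) "" else " [QC FLAG]"))
  invisible(x)
}
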