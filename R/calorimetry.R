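# Basal metabolic rate from fasting indirect calorimetry.  Gas exchange
# is screened for steadiness (VO2 range < 25 mL/min) and converted to
# kcal/day by the protein-free abbreviated Weir equation.

#' Construct a gas-exchange series
#'
#' Minute-resolution VO2 / VCO2 from a fasted, rested indirect-calorimetry
#' collection.
#'
#' @param participant_id identifier.
#' @param minute integer minute indices, strictly increasing.
#' @param vo2_ml_min oxygen consumption, mL/min, positive.
#' @param vco2_ml_min carbon-dioxide production, mL/min, positive.
#' @return An object of class `gas_series`.
#' @export
gas_series <- function(participant_id, minute, vo2_ml_min, vco2_ml_min) {
  n <- length(minute)
  if (n < 5)
    stop("a gas-exchange series needs at least 5 samples", call. = FALSE)
  if (length(vo2_ml_min) != n || length(vco2_ml_min) != n)
    stop("minute, vo2_ml_min and vco2_ml_min must have equal length",
         call. = FALSE)
  if (is.unsorted(minute, strictly = TRUE))
    stop("minute indices must be strictly increasing", call. = FALSE)
  if (any(vo2_ml_min <= 0) || any(vco2_ml_min <= 0))
    stop("gas-exchange volumes must be positive", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 minute = as.numeric(minute),
                 vo2_ml_min = as.numeric(vo2_ml_min),
                 vco2_ml_min = as.numeric(vco2_ml_min)),
            class = "gas_series")
}

#' Abbreviated Weir equation
#'
#' Energy expenditure from daily gas volumes:
#' `EE (kcal/day) = 3.941 VO2 + 1.106 VCO2` with volumes in L/day
#' (protein-free form; urinary nitrogen neglected).  The same equation
#' converts DLW CO2 production to TEE at an assumed respiratory quotient.
#'
#' @param vo2_l_day,vco2_l_day non-negative daily gas volumes, L/day.
#' @param constants see [ee_constants()] (`weir_vo2`, `weir_vco2`).
#' @return Energy expenditure in kcal/day.
#' @examples
#' weir_ee_kcal_per_day(360, 306)  # RQ 0.85 -> 1757.2 kcal/day
#' @export
weir_ee_kcal_per_day <- function(vo2_l_day, vco2_l_day,
                                 constants = ee_constants()) {
  if (any(vo2_l_day < 0) || any(vco2_l_day < 0))
    stop("gas volumes must be non-negative", call. = FALSE)
  constants$weir_vo2 * vo2_l_day + constants$weir_vco2 * vco2_l_day
}

#' BMR from a gas-exchange series with steadiness acceptance
#'
#' A collection is acceptable when VO2 varies by less than 25 mL/min
#' (max - min) over the averaging window.  When `steady_window_min` is
#' given, the last contiguous window of that many samples meeting the
#' criterion is used (the end of a rest period is the steadiest); if none
#' meets it, the final window is used and the result is flagged
#' unaccepted.  With `steady_window_min = NULL` the whole series is the
#' window.  Mean VO2/VCO2 over the window are scaled to daily litres and
#' converted by [weir_ee_kcal_per_day()].
#'
#' @param series a [gas_series()].
#' @param steady_window_min window length in samples, or NULL for the
#'   whole series.
#' @param constants see [ee_constants()] (`vo2_steady_ml` threshold).
#' @return A list: `bmr_kcal_day`, `bmr_mj_day`, `accepted`,
#'   `vo2_range_ml`, `window` (indices used).
#' @export
bmr_from_series <- function(series, steady_window_min = NULL,
                            constants = ee_constants()) {
  stopifnot(inherits(series, "gas_series"))
  n <- length(series$minute)
  if (is.null(steady_window_min)) {
    window <- seq_len(n)
  } else {
    w <- as.integer(steady_window_min)
    if (w < 2 || w > n)
      stop("steady window of ", w, " samples needs a series of at least ",
           "that length (have ", n, ")", call. = FALSE)
    starts <- seq_len(n - w + 1L)
    ok <- vapply(starts, function(s) {
      v <- series$vo2_ml_min[s:(s + w - 1L)]
      (max(v) - min(v)) < constants$vo2_steady_ml
    }, logical(1))
    start <- if (any(ok)) max(starts[ok]) else max(starts)
    window <- start:(start + w - 1L)
  }
  vo2 <- series$vo2_ml_min[window]
  vco2 <- series$vco2_ml_min[window]
  vo2_range <- max(vo2) - min(vo2)
  bmr_kcal <- weir_ee_kcal_per_day(mean(vo2) * 1440 / 1000,
                                   mean(vco2) * 1440 / 1000,
                                   constants)
  list(bmr_kcal_day = bmr_kcal,
       bmr_mj_day = bmr_kcal * constants$kcal_to_mj,
       accepted = vo2_range < constants$vo2_steady_ml,
       vo2_range_ml = vo2_range,
       window = window)
}
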