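# 24-hour activity record scoring: a day is a 96-slot grid of 15-minute
# activity codes; scoring converts the time-weighted mean MET into TEE,
# AEE and PAL via the measured BMR.

N_SLOTS <- 96L

#' Construct a diary day
#'
#' One participant-day of the 24-hour activity record: exactly 96 activity
#' codes, slot i (0-based) covering local time \[15i, 15(i+1)) minutes from
#' midnight.  Days crossing a clock change (92 or 100 slots) are rejected
#' as malformed; the instrument assumes exact 24-hour days.
#'
#' @param participant_id identifier.
#' @param date the calendar day (coerced with [as.Date()]).
#' @param slots character vector of exactly 96 activity codes.
#' @return An object of class `diary_day`.
#' @export
diary_day <- function(participant_id, date, slots) {
  slots <- as.character(slots)
  if (length(slots) != N_SLOTS)
    stop("a diary day needs exactly ", N_SLOTS, " slots, got ",
         length(slots), call. = FALSE)
  if (anyNA(slots) || any(!nzchar(slots)))
    stop("diary day has missing slots; day is non-compliant", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 date = as.Date(date), slots = slots),
            class = "diary_day")
}

#' @export
print.diary_day <- function(x, ...) {
  cat("Diary day:", x$participant_id, "on", format(x$date), "-",
      length(unique(x$slots)), "distinct activities\n")
  invisible(x)
}

#' 24-hour average MET of a diary day
#'
#' Each 15-minute slot carries equal weight, so the time-weighted mean is
#' the plain mean of the per-slot MET values resolved against the
#' compendium.
#'
#' @param day a [diary_day()].
#' @param compendium a [compendium()]; defaults to the shipped table.
#' @return The 24-hour average MET (positive scalar).
#' @export
average_mets <- function(day, compendium = default_compendium()) {
  stopifnot(inherits(day, "diary_day"))
  mean(lookup_mets(compendium, day$slots))
}

# shared TEE/AEE/PAL assembly used by both instruments
ee_outcome <- function(avg_mets, bmr_kcal, constants) {
  if (!is.finite(bmr_kcal) || bmr_kcal <= 0)
    stop("BMR must be a positive number of kcal/day", call. = FALSE)
  bmr_mj <- bmr_kcal * constants$kcal_to_mj
  tee_mj <- bmr_kcal * avg_mets * constants$sitting_factor /
    constants$dit_divisor * constants$kcal_to_mj
  structure(list(avg_mets = avg_mets,
                 tee_mj   = tee_mj,
                 aee_mj   = constants$dit_divisor * tee_mj - bmr_mj,
                 pal      = tee_mj / bmr_mj,
                 bmr_mj   = bmr_mj),
            class = "ee_outcome")
}

#' @export
print.ee_outcome <- function(x, ...) {
  cat(sprintf(
    "Energy expenditure: avg %.2f METs | TEE %.2f MJ/d | AEE %.2f MJ/d | PAL %.2f\n",
    x$avg_mets, x$tee_mj, x$aee_mj, x$pal))
  invisible(x)
}

#' @export
as.data.frame.ee_outcome <- function(x, ...) {
  data.frame(avg_mets = x$avg_mets, tee_mj = x$tee_mj, aee_mj = x$aee_mj,
             pal = x$pal, bmr_mj = x$bmr_mj)
}

#' Score one diary day into energy expenditure
#'
#' Converts the 24-hour average MET into total energy expenditure with
#' `TEE (MJ) = BMR (kcal) x avgMET x 1.1 / 0.9 x 4.184e-3`: the 1.1
#' raises supine fasting BMR to the sitting resting rate that defines
#' 1 MET, the division by 0.9 adds diet-induced thermogenesis of ~10%,
#' and 4.184e-3 converts kcal to MJ.  Activity energy expenditure removes
#' both again: `AEE = 0.9 x TEE - BMR`; `PAL = TEE / BMR`.  No rounding
#' is applied; round only when reporting.
#'
#' @param day a [diary_day()].
#' @param bmr_kcal measured basal metabolic rate in kcal/day.
#' @param compendium a [compendium()].
#' @param constants see [ee_constants()].
#' @return An `ee_outcome`: `avg_mets`, `tee_mj`, `aee_mj`, `pal`,
#'   `bmr_mj`.
#' @examples
#' day <- diary_day("p1", "2024-01-01", rep("sleep", 96))
#' score_day(day, bmr_kcal = 1400)
#' @export
score_day <- function(day, bmr_kcal, compendium = default_compendium(),
                      constants = ee_constants()) {
  ee_outcome(average_mets(day, compendium), bmr_kcal, constants)
}

#' Score a week of diary days
#'
#' Weekly summaries are arithmetic means of the daily average METs, TEE
#' and AEE; PAL is recomputed from the mean TEE so that the affine
#' identity `AEE = 0.9 TEE - BMR` carries over exactly to the weekly
#' means.
#'
#' @param days list of [diary_day()] objects (1-7 compliant days).
#' @inheritParams score_day
#' @return An `ee_outcome` of weekly means.
#' @export
score_week <- function(days, bmr_kcal, compendium = default_compendium(),
                       constants = ee_constants()) {
  if (length(days) == 0)
    stop("no compliant diary days to score", call. = FALSE)
  daily <- vapply(days, average_mets, numeric(1), compendium = compendium)
  ee_outcome(mean(daily), bmr_kcal, constants)
}
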