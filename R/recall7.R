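# 7-day recall scoring: sleep hours plus per-period (morning / afternoon
# / evening) intensity-class durations.  Very-light time (reading,
# television, ...) is never entered directly; whatever part of the 24 h is
# unaccounted for is scored at 1.3 METs.

RECALL_PERIODS <- c("morning", "afternoon", "evening")

#' Construct a recall day
#'
#' One participant-day of the 7-day recall: total sleep hours plus
#' entries of (period, intensity class, hours).  Entered classes are the
#' five selectable ones (light ... very_high); sleep and very-light time
#' are handled by the instrument itself.  Accounted time may not exceed
#' 24 hours - over-allocation is an error, never silently clipped.
#'
#' @param participant_id identifier.
#' @param date the calendar day.
#' @param sleep_hours hours asleep, in \[0, 24\].
#' @param entries data frame with columns `period` (morning / afternoon /
#'   evening), `class` (an [intensity_classes()] name other than sleep or
#'   very_light) and `hours` (non-negative decimal hours).  May be empty.
#' @return An object of class `recall_day`.
#' @export
recall_day <- function(participant_id, date, sleep_hours,
                       entries = data.frame(period = character(),
                                            class = character(),
                                            hours = numeric())) {
  if (!is.finite(sleep_hours) || sleep_hours < 0 || sleep_hours > 24)
    stop("sleep_hours must lie in [0, 24]", call. = FALSE)
  entries <- as.data.frame(entries)
  required <- c("period", "class", "hours")
  if (!all(required %in% names(entries)))
    stop("entries need columns period, class, hours", call. = FALSE)
  entries <- entries[required]
  entries$period <- as.character(entries$period)
  entries$class <- as.character(entries$class)
  entries$hours <- as.numeric(entries$hours)
  bad_period <- setdiff(unique(entries$period), RECALL_PERIODS)
  if (length(bad_period))
    stop("unknown recall period(s): ", paste(bad_period, collapse = ", "),
         call. = FALSE)
  selectable <- setdiff(intensity_classes()$name, c("sleep", "very_light"))
  bad_class <- setdiff(unique(entries$class), selectable)
  if (length(bad_class))
    stop("entries must use selectable classes (",
         paste(selectable, collapse = ", "), "); found: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  if (any(!is.finite(entries$hours) | entries$hours < 0))
    stop("entry hours must be non-negative", call. = FALSE)
  accounted <- sleep_hours + sum(entries$hours)
  if (accounted > 24 + 1e-9)
    stop(sprintf("accounted time %.2f h exceeds 24 h for %s on %s",
                 accounted, participant_id, date), call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 date = as.Date(date), sleep_hours = sleep_hours,
                 entries = entries),
            class = "recall_day")
}

#' @export
print.recall_day <- function(x, ...) {
  cat("Recall day:", x$participant_id, "on", format(x$date), "-",
      sprintf("%.1f h sleep, %d entries, %.1f h unaccounted (very light)\n",
              x$sleep_hours, nrow(x$entries),
              24 - x$sleep_hours - sum(x$entries$hours)))
  invisible(x)
}

#' 24-hour average MET of a recall day
#'
#' Sleep hours are weighted at 0.9 METs, each entry at its class scoring
#' MET, and the unaccounted remainder of the day
#' (24 - sleep - entered hours) at the very-light 1.3 METs:
#' `avg = (0.9 sleep + sum(class_mets x hours) + 1.3 x unaccounted) / 24`.
#'
#' @param day a [recall_day()].
#' @param constants see [ee_constants()].
#' @return The 24-hour average MET, bounded in \[0.9, 10\].
#' @examples
#' d <- recall_day("p1", "2024-01-01", sleep_hours = 8,
#'                 entries = data.frame(period = c("morning", "evening"),
#'                                      class = c("moderate", "light"),
#'                                      hours = c(2, 4)))
#' average_mets_recall(d)  # 1.5
#' @export
average_mets_recall <- function(day, constants = ee_constants()) {
  stopifnot(inherits(day, "recall_day"))
  unaccounted <- 24 - day$sleep_hours - sum(day$entries$hours)
  met_hours <- constants$sleep_mets * day$sleep_hours +
    sum(mets_for_class(day$entries$class) * day$entries$hours) +
    constants$very_light_mets * unaccounted
  met_hours / 24
}

#' Score one recall day into energy expenditure
#'
#' Applies the same TEE conversion as [score_day()] (documented
#' assumption: the instrument restates a single kcal-to-MJ conversion for
#' both systems, including the 1.1 sitting factor and the 0.9
#' diet-induced-thermogenesis divisor) to the recall average MET.
#'
#' @param day a [recall_day()].
#' @inheritParams score_day
#' @return An `ee_outcome`.
#' @export
score_recall_day <- function(day, bmr_kcal, constants = ee_constants()) {
  ee_outcome(average_mets_recall(day, constants), bmr_kcal, constants)
}

#' Score a week of recall days
#'
#' Arithmetic mean of daily values, PAL recomputed from the mean TEE, as
#' in [score_week()].
#'
#' @param days list of [recall_day()] objects.
#' @inheritParams score_day
#' @return An `ee_outcome` of weekly means.
#' @export
score_recall_week <- function(days, bmr_kcal, constants = ee_constants()) {
  if (length(days) == 0)
    stop("no compliant recall days to score", call. = FALSE)
  daily <- vapply(days, average_mets_recall, numeric(1),
                  constants = constants)
  ee_outcome(mean(daily), bmr_kcal, constants)
}

#' Intensity-quiz pass rule
#'
#' The recall instrument opens with a quiz matching activities to
#' intensity classes; the quiz ends as soon as the respondent answers two
#' questions correctly in a row.  Given the asked and answered classes in
#' submission order, returns whether the run-of-two was achieved and how
#' many trials it took (the index of the second correct answer, or the
#' full length if never achieved).
#'
#' @param asked character vector of the classes asked about.
#' @param answered character vector of the classes answered, same length.
#' @return A list with `passed` (logical) and `trials` (integer).
#' @examples
#' quiz_gate(c("light", "high"), c("light", "high"))        # passed in 2
#' quiz_gate(rep("light", 5), rep("moderate", 5))           # never passed
#' @export
quiz_gate <- function(asked, answered) {
  if (length(asked) != length(answered))
    stop("asked and answered must have the same length", call. = FALSE)
  correct <- asked == answered
  n <- length(correct)
  if (n >= 2) {
    run2 <- which(correct[-n] & correct[-1])
    if (length(run2))
      return(list(passed = TRUE, trials = min(run2) + 1L))
  }
  list(passed = FALSE, trials = n)
}
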