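# CSV readers for the study's file formats.  All files are UTF-8,
# comma-delimited, header required; dates ISO-8601.  Readers validate
# schema per file and report problems per row rather than silently
# dropping data.

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Read a 24-hour diary CSV
#'
#' Expects columns `participant_id,date,slot_index,activity_code`, one
#' row per 15-minute slot with `slot_index` 0-95.  Days with missing or
#' duplicated slots are not scored: they are returned separately as
#' non-compliant, per the instrument's compliance rule.
#'
#' @param path CSV path.
#' @return A list: `days` (list of [diary_day()]), `noncompliant` (data
#'   frame of participant-days that could not be assembled, with a
#'   reason).
#' @export
read_diary_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "date", "slot_index",
                                 "activity_code"), "diary")
  days <- list()
  bad <- list()
  for (key in unique(paste(df$participant_id, df$date, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- df[df$participant_id == parts[1] & df$date == parts[2], ]
    if (nrow(rows) != N_SLOTS ||
        !setequal(rows$slot_index, 0:(N_SLOTS - 1))) {
      bad[[length(bad) + 1]] <- data.frame(
        participant_id = parts[1], date = parts[2],
        reason = sprintf("%d of %d slots present", nrow(rows), N_SLOTS),
        stringsAsFactors = FALSE)
      next
    }
    rows <- rows[order(rows$slot_index), ]
    days[[length(days) + 1]] <- diary_day(parts[1], parts[2],
                                          rows$activity_code)
  }
  list(days = days,
       noncompliant = if (length(bad)) do.call(rbind, bad) else
         data.frame(participant_id = character(), date = character(),
                    reason = character()))
}

#' Read a 7-day recall CSV
#'
#' Expects columns
#' `participant_id,date,sleep_hours,period,intensity_class,hours`; the
#' sleep hours are repeated on each of a day's entry rows, and a day with
#' no entries is a single row with empty period/class/hours.
#'
#' @param path CSV path.
#' @return A list of [recall_day()] objects.
#' @export
read_recall_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "date", "sleep_hours",
                                 "period", "intensity_class", "hours"),
                         "recall")
  out <- list()
  for (key in unique(paste(df$participant_id, df$date, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- df[df$participant_id == parts[1] & df$date == parts[2], ]
    sleep <- unique(rows$sleep_hours)
    if (length(sleep) != 1)
      stop("inconsistent sleep_hours for ", parts[1], " on ", parts[2],
           call. = FALSE)
    has_entry <- !is.na(rows$period) & nzchar(rows$period)
    entries <- data.frame(period = rows$period[has_entry],
                          class = rows$intensity_class[has_entry],
                          hours = rows$hours[has_entry],
                          stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- recall_day(parts[1], parts[2], sleep, entries)
  }
  out
}

#' Read a gas-exchange CSV
#'
#' Columns `participant_id,minute,vo2_ml_min,vco2_ml_min`.
#'
#' @param path CSV path.
#' @return Named list of [gas_series()], one per participant.
#' @export
read_gas_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "minute", "vo2_ml_min",
                                 "vco2_ml_min"), "gas-exchange")
  ids <- unique(df$participant_id)
  stats::setNames(lapply(ids, function(id) {
    rows <- df[df$participant_id == id, ]
    rows <- rows[order(rows$minute), ]
    gas_series(id, rows$minute, rows$vo2_ml_min, rows$vco2_ml_min)
  }), ids)
}

#' Read an isotope-enrichment CSV
#'
#' Columns `participant_id,time_days,delta_2h_permil,delta_18o_permil`;
#' the `time_days == 0` row is the pre-dose baseline.
#'
#' @param path CSV path.
#' @return Named list of [isotope_samples()], one per participant.
#' @export
read_isotope_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "time_days",
                                 "delta_2h_permil", "delta_18o_permil"),
                         "isotope")
  ids <- unique(df$participant_id)
  stats::setNames(lapply(ids, function(id) {
    rows <- df[df$participant_id == id, ]
    isotope_samples(rows$time_days, rows$delta_2h_permil,
                    rows$delta_18o_permil)
  }), ids)
}

#' Read a dosing-record CSV
#'
#' Columns
#' `participant_id,mass_2h2o_g,atom_pct_2h,mass_h218o_g,atom_pct_18o`.
#'
#' @param path CSV path.
#' @return Named list of [dosing_record()] objects.
#' @export
read_dose_csv <- function(path) {
  df <- read_checked_csv(path, c("participant_id", "mass_2h2o_g",
                                 "atom_pct_2h", "mass_h218o_g",
                                 "atom_pct_18o"), "dose")
  stats::setNames(lapply(seq_len(nrow(df)), function(i)
    dosing_record(df$mass_2h2o_g[i], df$atom_pct_2h[i],
                  df$mass_h218o_g[i], df$atom_pct_18o[i])),
    df$participant_id)
}

#' Read a BMR CSV
#'
#' Columns `participant_id` plus `bmr_kcal_day` and/or `bmr_mj_day`;
#' whichever is absent is derived from the other.
#'
#' @param path CSV path.
#' @param constants see [ee_constants()].
#' @return Data frame with `participant_id`, `bmr_kcal_day`,
#'   `bmr_mj_day`.
#' @export
read_bmr_csv <- function(path, constants = ee_constants()) {
  df <- read_checked_csv(path, "participant_id", "BMR")
  if (!"bmr_kcal_day" %in% names(df) && !"bmr_mj_day" %in% names(df))
    stop("BMR file needs bmr_kcal_day or bmr_mj_day", call. = FALSE)
  if (!"bmr_kcal_day" %in% names(df))
    df$bmr_kcal_day <- df$bmr_mj_day / constants$kcal_to_mj
  if (!"bmr_mj_day" %in% names(df))
    df$bmr_mj_day <- df$bmr_kcal_day * constants$kcal_to_mj
  df[c("participant_id", "bmr_kcal_day", "bmr_mj_day")]
}

#' Read a run configuration from YAML
#'
#' The YAML may hold input paths (`diary`, `recall`, `iso`, `dose`,
#' `gas` or `bmr`, `assignment`, `compendium`), a `constants` block of
#' [ee_constants()] overrides, a `seed` and an `outdir`.
#'
#' @param path YAML path.
#' @return A named list suitable for [run_study()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
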