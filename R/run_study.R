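# Top-level orchestration: score both instruments per assigned week, run
# the DLW reference per week, and compute the full method-comparison
# battery per instrument.  Every constant used comes from one
# ee_constants() table and is echoed into the report.

`%||%` <- function(a, b) if (is.null(a)) b else a

round_mj <- function(x) round(x, 2)

#' Run the full validation study pipeline
#'
#' Reads all study inputs, computes each participant's BMR (from gas
#' exchange if a `gas` path is given, else from a `bmr` file), scores the
#' diary and recall instruments on their assigned weeks, runs the DLW
#' chain for weeks 1 and 2, and assembles the validation battery per
#' instrument: Pearson correlations and Bland-Altman agreement for AEE,
#' TEE and PAL against DLW, compliance accounting, and a 3-SD outlier
#' sensitivity reanalysis of the instrument AEE.  Writes a
#' machine-readable JSON report and a human-readable text report when
#' `outdir` is set.  The run is deterministic: the same configuration
#' produces byte-identical reports.
#'
#' @param config a named list (or a YAML path readable by
#'   [read_run_config()]): input paths `diary`, `recall`, `iso`, `dose`,
#'   and `gas` or `bmr`; optional `assignment` (CSV with
#'   `participant_id,week1_instrument,week2_instrument`; inferred from
#'   the input dates when absent), optional `compendium` CSV, optional
#'   `constants` overrides, optional `outdir`.
#' @return The study report (a nested list), invisibly when `outdir` is
#'   written.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  constants <- do.call(ee_constants, as.list(config$constants %||% list()))
  cmp <- if (!is.null(config$compendium))
    read_compendium_csv(config$compendium) else default_compendium()

  diary <- read_diary_csv(config$diary)
  recall_days <- read_recall_csv(config$recall)
  iso <- read_isotope_csv(config$iso)
  dose <- read_dose_csv(config$dose)

  if (!is.null(config$gas)) {
    gas <- read_gas_csv(config$gas)
    bmr <- do.call(rbind, lapply(names(gas), function(id) {
      b <- bmr_from_series(gas[[id]], constants = constants)
      data.frame(participant_id = id, bmr_kcal_day = b$bmr_kcal_day,
                 bmr_mj_day = b$bmr_mj_day, bmr_accepted = b$accepted,
                 stringsAsFactors = FALSE)
    }))
  } else if (!is.null(config$bmr)) {
    bmr <- read_bmr_csv(config$bmr, constants)
    bmr$bmr_accepted <- TRUE
  } else stop("config needs a 'gas' or a 'bmr' input", call. = FALSE)

  diary_by_id <- split(diary$days,
                       vapply(diary$days, `[[`, "", "participant_id"))
  recall_by_id <- split(recall_days,
                        vapply(recall_days, `[[`, "", "participant_id"))

  all_dates <- c(as.Date(unlist(lapply(diary$days, function(d)
                   format(d$date)))),
                 as.Date(unlist(lapply(recall_days, function(d)
                   format(d$date)))))
  study_start <- min(all_dates)

  assignment <- if (!is.null(config$assignment)) {
    read_checked_csv(config$assignment,
                     c("participant_id", "week1_instrument",
                       "week2_instrument"), "assignment")
  } else {
    # infer: the instrument whose dates fall in the first 7 days was used
    # in week 1
    ids <- sort(unique(c(names(diary_by_id), names(recall_by_id))))
    do.call(rbind, lapply(ids, function(id) {
      ddates <- as.Date(vapply(diary_by_id[[id]] %||% list(),
                               function(d) format(d$date), ""))
      w1 <- if (length(ddates) &&
                stats::median(as.numeric(ddates - study_start)) < 7)
        "par24" else "recall7"
      data.frame(participant_id = id, week1_instrument = w1,
                 week2_instrument = if (w1 == "par24") "recall7" else "par24",
                 stringsAsFactors = FALSE)
    }))
  }

  paired <- list()
  for (i in seq_len(nrow(assignment))) {
    id <- assignment$participant_id[i]
    brow <- bmr[bmr$participant_id == id, ]
    if (nrow(brow) != 1 || is.null(iso[[id]]) || is.null(dose[[id]])) next
    dlw <- lapply(1:2, function(w)
      withCallingHandlers(
        dlw_week(iso[[id]], dose[[id]], brow$bmr_mj_day, week = w,
                 constants = constants),
        warning = function(cond) invokeRestart("muffleWarning")))
    for (inst in c("par24", "recall7")) {
      week <- if (assignment$week1_instrument[i] == inst) 1L else 2L
      score <- if (inst == "par24") {
        days <- diary_by_id[[id]]
        if (is.null(days) || !length(days)) next
        score_week(days, brow$bmr_kcal_day, cmp, constants)
      } else {
        days <- recall_by_id[[id]]
        if (is.null(days) || !length(days)) next
        score_recall_week(days, brow$bmr_kcal_day, constants)
      }
      d <- dlw[[week]]
      paired[[length(paired) + 1]] <- data.frame(
        participant_id = id, instrument = inst, week = week,
        inst_tee_mj = score$tee_mj, inst_aee_mj = score$aee_mj,
        inst_pal = score$pal,
        dlw_tee_mj = d$tee_mj_day,
        dlw_aee_mj = constants$dit_divisor * d$tee_mj_day - brow$bmr_mj_day,
        dlw_pal = d$pal, nd_no_ratio = d$nd_no_ratio,
        dlw_qc_pass = d$qc_pass, stringsAsFactors = FALSE)
    }
  }
  paired <- do.call(rbind, paired)
  if (is.null(paired) || nrow(paired) < 3)
    stop("fewer than 3 paired instrument/DLW measurements; ",
         "cannot run the validation battery", call. = FALSE)

  metric_stats <- function(sub, inst_col, dlw_col) {
    r <- pearson(sub[[inst_col]], sub[[dlw_col]])
    ba <- bland_altman(sub[[inst_col]], sub[[dlw_col]], constants)
    list(n = r$n, r = round(r$r, 3), p = signif(r$p, 3),
         mean_instrument = round_mj(mean(sub[[inst_col]])),
         sd_instrument = round_mj(stats::sd(sub[[inst_col]])),
         mean_dlw = round_mj(mean(sub[[dlw_col]])),
         sd_dlw = round_mj(stats::sd(sub[[dlw_col]])),
         bland_altman = list(
           mean_diff = round_mj(ba$mean_diff),
           sd_diff = round_mj(ba$sd_diff),
           loa_low = round_mj(ba$loa_low),
           loa_high = round_mj(ba$loa_high),
           trend_slope = round(ba$trend_slope, 3),
           trend_r = round(ba$trend_r, 3),
           trend_p = signif(ba$trend_p, 3)))
  }

  instruments <- list()
  for (inst in c("par24", "recall7")) {
    sub <- paired[paired$instrument == inst, ]
    if (nrow(sub) < 3) next
    stats_by_metric <- list(
      aee = metric_stats(sub, "inst_aee_mj", "dlw_aee_mj"),
      tee = metric_stats(sub, "inst_tee_mj", "dlw_tee_mj"),
      pal = metric_stats(sub, "inst_pal", "dlw_pal"))
    flagged <- flag_outliers(sub$inst_aee_mj, constants$outlier_k_sd)
    sensitivity <- NULL
    if (length(flagged) && nrow(sub) - length(flagged) >= 3) {
      kept <- sub[-flagged, ]
      sensitivity <- list(
        excluded = sub$participant_id[flagged],
        aee = metric_stats(kept, "inst_aee_mj", "dlw_aee_mj"),
        tee = metric_stats(kept, "inst_tee_mj", "dlw_tee_mj"))
    }
    instruments[[inst]] <- c(stats_by_metric,
                             list(outlier_sensitivity = sensitivity))
  }

  n_diary_expected <- 7 * length(unique(c(
    names(diary_by_id), diary$noncompliant$participant_id)))
  diary_compliance <- compliance(length(diary$days),
                                 max(n_diary_expected, 1))
  recall_compliance <- compliance(length(recall_days),
                                  max(7 * length(recall_by_id), 1))

  report <- list(
    constants = constants,
    n_participants = nrow(assignment),
    compliance = list(par24 = diary_compliance,
                      recall7 = recall_compliance),
    instruments = instruments,
    dlw_qc = list(
      mean_nd_no = round(mean(paired$nd_no_ratio), 3),
      n_flagged = sum(!paired$dlw_qc_pass) / 2L),
    paired = paired)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "paired")],
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    utils::write.csv(paired, file.path(config$outdir, "paired.csv"),
                     row.names = FALSE)
    writeLines(format_report(report), file.path(config$outdir, "report.txt"))
    return(invisible(report))
  }
  report
}

# human-readable summary of a run_study() report
format_report <- function(report) {
  lines <- c(
    sprintf("Validation study report (n = %d participants)",
            report$n_participants),
    sprintf("Compliance: diary %s/%s days (%.1f%%); recall %s/%s days (%.1f%%)",
            report$compliance$par24$completed, report$compliance$par24$total,
            report$compliance$par24$pct,
            report$compliance$recall7$completed,
            report$compliance$recall7$total, report$compliance$recall7$pct),
    sprintf("Mean dilution-space ratio Nd/No: %.3f",
            report$dlw_qc$mean_nd_no), "")
  for (inst in names(report$instruments)) {
    s <- report$instruments[[inst]]
    lines <- c(lines, sprintf("== %s vs DLW ==", inst))
    for (m in c("aee", "tee", "pal")) {
      x <- s[[m]]
      lines <- c(lines, sprintf(
        "  %s: instrument %.2f (SD %.2f) vs DLW %.2f (SD %.2f); r = %.3f (P = %.3g); bias %.2f, LoA %.2f to %.2f",
        toupper(m), x$mean_instrument, x$sd_instrument, x$mean_dlw,
        x$sd_dlw, x$r, x$p, x$bland_altman$mean_diff,
        x$bland_altman$loa_low, x$bland_altman$loa_high))
    }
    if (!is.null(s$outlier_sensitivity))
      lines <- c(lines, sprintf(
        "  outlier reanalysis excluding %s: AEE r = %.3f",
        paste(s$outlier_sensitivity$excluded, collapse = ", "),
        s$outlier_sensitivity$aee$r))
    lines <- c(lines, "")
  }
  lines
}
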