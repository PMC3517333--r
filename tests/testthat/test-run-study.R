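sim_dir <- function(n = 8, seed = 12, noise = noise_config(),
                    dir = withr::local_tempdir(.local_envir = parent.frame())) {
  simulate_study(n = n, seed = seed, noise = noise, outdir = dir)
  dir
}

study_config <- function(dir, ...) {
  c(list(diary = file.path(dir, "diary.csv"),
         recall = file.path(dir, "recall.csv"),
         iso = file.path(dir, "iso.csv"),
         dose = file.path(dir, "dose.csv"),
         gas = file.path(dir, "gas.csv"),
         assignment = file.path(dir, "assignment.csv")),
    list(...))
}

test_that("simulator output round-trips through the file readers", {
  dir <- sim_dir(n = 4)
  diary <- read_diary_csv(file.path(dir, "diary.csv"))
  expect_length(diary$days, 4 * 7)
  expect_equal(nrow(diary$noncompliant), 0)
  recall <- read_recall_csv(file.path(dir, "recall.csv"))
  expect_length(recall, 4 * 7)
  gas <- read_gas_csv(file.path(dir, "gas.csv"))
  expect_length(gas, 4)
  expect_s3_class(gas[[1]], "gas_series")
  iso <- read_isotope_csv(file.path(dir, "iso.csv"))
  expect_length(iso, 4)
  expect_true(all(vapply(iso, function(s) any(s$time_days == 0),
                         logical(1))))
  dose <- read_dose_csv(file.path(dir, "dose.csv"))
  expect_s3_class(dose[[1]], "dosing_record")
})

test_that("a noiseless end-to-end study shows near-perfect diary validity", {
  quiet <- noise_config(sd_delta2h_permil = 0, sd_delta18o_permil = 0,
                        diary_misclass_prob = 0, recall_hours_cv = 0,
                        gross_overestimator_prob = 0)
  dir <- sim_dir(n = 10, seed = 4, noise = quiet)
  report <- run_study(study_config(dir))
  expect_gt(report$instruments$par24$tee$r, 0.99)
  expect_gt(report$instruments$par24$aee$r, 0.99)
  expect_lt(abs(report$instruments$par24$aee$bland_altman$mean_diff), 0.1)
  expect_equal(report$compliance$par24$pct, 100.0)
})

test_that("the same configuration yields byte-identical reports", {
  dir <- sim_dir(n = 6, seed = 31)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  run_study(study_config(dir, outdir = out1))
  run_study(study_config(dir, outdir = out2))
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_identical(readLines(file.path(out1, "paired.csv")),
                   readLines(file.path(out2, "paired.csv")))
})

test_that("a missing input file is a single actionable error", {
  dir <- sim_dir(n = 4, seed = 8)
  cfg <- study_config(dir)
  cfg$iso <- file.path(dir, "nonexistent.csv")
  expect_error(run_study(cfg), "nonexistent.csv")
})

test_that("incomplete diary days are counted non-compliant, not dropped silently", {
  dir <- sim_dir(n = 4, seed = 21)
  diary <- utils::read.csv(file.path(dir, "diary.csv"))
  first_id <- diary$participant_id[1]
  first_date <- diary$date[1]
  # delete one slot from one participant-day
  drop <- which(diary$participant_id == first_id &
                  diary$date == first_date & diary$slot_index == 40)
  utils::write.csv(diary[-drop, ], file.path(dir, "diary.csv"),
                   row.names = FALSE)
  parsed <- read_diary_csv(file.path(dir, "diary.csv"))
  expect_equal(nrow(parsed$noncompliant), 1)
  expect_equal(parsed$noncompliant$participant_id, first_id)
  report <- run_study(study_config(dir))
  expect_equal(report$compliance$par24$completed, 4 * 7 - 1)
  expect_equal(report$compliance$par24$pct,
               round(100 * 27 / 28, 1))
})

test_that("constants flow from the configuration into the report", {
  dir <- sim_dir(n = 4, seed = 3)
  report <- run_study(study_config(dir,
                                   constants = list(molar_volume_l = 22.26)))
  expect_equal(report$constants$molar_volume_l, 22.26)
  expect_equal(report$constants$sitting_factor, 1.1)
})
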