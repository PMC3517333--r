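# Synthetic crossover cohort with a ground-truth layer.  Truth comes
# first: per-participant physiology and a 96-slot true activity grid are
# generated, then both instrument reports (with reporting error) and the
# isotope enrichment series (with analytic noise) are derived from that
# truth, so parameter recovery is well-defined at every pipeline stage.

# inverse-CDF truncated normal: deterministic under the active RNG stream
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Reporting- and analytic-noise configuration for the simulator
#'
#' @param sd_delta2h_permil analytic SD of the 2H delta measurement
#'   (permil); default 0.7, the routine mass-spectrometry precision.
#' @param sd_delta18o_permil analytic SD of the 18O delta (permil);
#'   default 0.05.
#' @param diary_misclass_prob per-slot probability that the diary records
#'   a uniformly random wrong activity; default 0.05.
#' @param recall_hours_cv coefficient of variation of recalled entry
#'   hours; default 0.2.
#' @param gross_overestimator_prob per-participant probability of the
#'   constant-class corruption (all waking time reported in one elevated
#'   class, regardless of behavior); default 0.05.
#' @param female_overreport_frac optional sex-linked positive bias:
#'   fractional inflation of recalled hours for women; default 0.
#' @param seed integer RNG seed used by the rendering operations.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(sd_delta2h_permil = 0.7,
                         sd_delta18o_permil = 0.05,
                         diary_misclass_prob = 0.05,
                         recall_hours_cv = 0.2,
                         gross_overestimator_prob = 0.05,
                         female_overreport_frac = 0,
                         seed = 1L) {
  probs <- c(diary_misclass_prob, gross_overestimator_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (sd_delta2h_permil < 0 || sd_delta18o_permil < 0 || recall_hours_cv < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  structure(list(sd_delta2h_permil = sd_delta2h_permil,
                 sd_delta18o_permil = sd_delta18o_permil,
                 diary_misclass_prob = diary_misclass_prob,
                 recall_hours_cv = recall_hours_cv,
                 gross_overestimator_prob = gross_overestimator_prob,
                 female_overreport_frac = female_overreport_frac,
                 seed = as.integer(seed)),
            class = "noise_config")
}

# sex-stratified physiology: mean, SD and admissible range per trait,
# matching the characteristics of a middle-aged mixed-weight volunteer
# cohort (10 men / 10 women archetype)
cohort_physiology <- function() {
  list(
    male = list(age = c(45.2, 12.3, 26, 61),
                weight = c(79.2, 13.9, 57.5, 108.5),
                height = c(172.6, 7.3, 161.9, 185.4),
                bmr = c(6.50, 0.89, 4.77, 8.00),
                pal = c(1.90, 0.12, 1.68, 2.09),
                tbw_frac = 0.60),
    female = list(age = c(40.0, 9.1, 25, 51),
                  weight = c(54.0, 3.6, 48.7, 58.0),
                  height = c(159.0, 8.5, 141.8, 171.0),
                  bmr = c(4.87, 0.57, 4.40, 6.24),
                  pal = c(1.76, 0.22, 1.42, 2.14),
                  tbw_frac = 0.50),
    ndno = c(1.027, 0.007, 1.011, 1.043),
    k_d = c(0.10, 0.010, 0.07, 0.13),
    occupations = c(fulltime = 0.5, parttime = 0.1,
                    selfemployed = 0.2, homemaker = 0.2)
  )
}

#' Generate a synthetic crossover cohort
#'
#' Sex-stratified physiology (age, weight, height, BMR, true PAL, total
#' body water) drawn from truncated normals; a per-participant
#' dilution-space ratio Nd/No ~ N(1.027, 0.007) truncated to
#' \[1.011, 1.043\]; a deuterium elimination rate reflecting normal water
#' turnover; and a balanced crossover assignment (half the cohort starts
#' on the diary instrument, half on the recall, swapping in week 2).
#'
#' @param n cohort size (>= 2; split half male, half female).
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   exactly.
#' @return A list: `participants` (data frame), `assignment` (data frame
#'   with `participant_id`, `week1_instrument`, `week2_instrument`).
#' @examples
#' cohort <- generate_cohort(20, seed = 42)
#' table(cohort$participants$sex)
#' @export
generate_cohort <- function(n, seed) {
  if (n < 2) stop("cohort size must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  phys <- cohort_physiology()
  n_male <- n %/% 2L
  sex <- c(rep("male", n_male), rep("female", n - n_male))
  draw <- function(spec_by_sex, trait) {
    vapply(sex, function(s) {
      p <- phys[[s]][[trait]]
      rtrunc_norm(1, p[1], p[2], p[3], p[4])
    }, numeric(1), USE.NAMES = FALSE)
  }
  mass_h2o <- 2 * 1.00794 + 15.9994  # g/mol, natural water
  weight <- draw(phys, "weight")
  tbw_kg <- weight * vapply(sex, function(s) phys[[s]]$tbw_frac,
                            numeric(1), USE.NAMES = FALSE) *
    exp(stats::rnorm(n, 0, 0.03))
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    sex = sex,
    age = round(draw(phys, "age")),
    weight_kg = weight,
    height_cm = draw(phys, "height"),
    bmr_mj_day = draw(phys, "bmr"),
    tbw_mol = tbw_kg * 1000 / mass_h2o,
    true_pal = draw(phys, "pal"),
    nd_no_ratio = rtrunc_norm(n, phys$ndno[1], phys$ndno[2],
                              phys$ndno[3], phys$ndno[4]),
    k_d_perday = rtrunc_norm(n, phys$k_d[1], phys$k_d[2],
                             phys$k_d[3], phys$k_d[4]),
    occupation_class = sample(names(phys$occupations), n, replace = TRUE,
                              prob = phys$occupations),
    stringsAsFactors = FALSE
  )
  # balanced instrument order: half start on the diary, half on the recall
  starters <- sample(seq_len(n), n %/% 2L)
  week1 <- ifelse(seq_len(n) %in% starters, "par24", "recall7")
  assignment <- data.frame(
    participant_id = participants$participant_id,
    week1_instrument = week1,
    week2_instrument = ifelse(week1 == "par24", "recall7", "par24"),
    stringsAsFactors = FALSE
  )
  list(participants = participants, assignment = assignment)
}

# slot layout: 0-based 15-min slots; sleep 23:00-07:00 (32 slots)
SLEEP_SLOTS <- c(93:96, 1:28)          # 1-based indices into the 96 grid
WORK_SLOTS <- 37:68                    # 09:00-17:00
COMMUTE_SLOTS <- c(35:36, 69:70)       # 08:30-09:00 and 17:00-17:30

# base day template by occupation; the sedentary variant (quiet desk
# work, seated commute) is used when a low-PAL target leaves too little
# MET budget for the standard template
base_day_codes <- function(occupation, workday, sedentary = FALSE) {
  codes <- rep("watching_tv", 96)
  codes[SLEEP_SLOTS] <- "sleep"
  if (workday && occupation != "homemaker") {
    work_len <- switch(occupation, fulltime = 32L, parttime = 16L,
                       selfemployed = 24L)
    codes[WORK_SLOTS[seq_len(work_len)]] <-
      if (sedentary) "writing_desk" else "office_desk_work"
    codes[COMMUTE_SLOTS] <-
      if (sedentary) "riding_bus_sitting" else "walking_commute"
  }
  codes
}

FIXED_CODES <- c("sleep", "office_desk_work", "walking_commute",
                 "writing_desk", "riding_bus_sitting")

# palette of substitutable codes spanning the full MET range, used to
# steer a day's average MET onto its target
adjust_palette <- function(compendium) {
  codes <- c("watching_tv", "sitting_quietly", "reading", "talking_sitting",
             "standing_light", "cooking_home", "shopping_grocery",
             "child_care", "strolling", "walking_dog", "house_cleaning",
             "walking_leisure", "gardening", "walking_exercise",
             "brisk_walking_exercise", "hiking", "jogging", "running")
  codes <- codes[codes %in% compendium$code]
  data.frame(code = codes, mets = lookup_mets(compendium, codes),
             stringsAsFactors = FALSE)
}

# steer the adjustable (non-sleep, non-work, non-commute) slots so the
# day's mean MET hits `target_avg`: coarse two-level fill plus one
# fine-tuning slot
calibrate_day <- function(codes, target_avg, compendium) {
  pal <- adjust_palette(compendium)
  pal <- pal[order(pal$mets), , drop = FALSE]
  fixed <- codes %in% FIXED_CODES
  adj <- which(!fixed)
  m <- length(adj)
  mets <- lookup_mets(compendium, codes)
  need <- target_avg * 96 - sum(mets[fixed])      # MET-sum the free slots owe
  r <- need / m                                    # per-slot target
  r <- min(max(r, min(pal$mets)), max(pal$mets))   # clamp to palette span
  lo <- max(which(pal$mets <= r))
  hi <- min(which(pal$mets >= r))
  if (lo == hi) {
    codes[adj] <- pal$code[lo]
  } else {
    x <- round((need - m * pal$mets[lo]) / (pal$mets[hi] - pal$mets[lo]))
    x <- min(max(x, 0L), m)
    hi_slots <- sample(adj, x)
    codes[adj] <- pal$code[lo]
    codes[hi_slots] <- pal$code[hi]
  }
  # fine-tune one slot to absorb the rounding residual
  mets <- lookup_mets(compendium, codes)
  resid <- target_avg * 96 - sum(mets)
  slot <- adj[1]
  want <- mets[slot] + resid
  best <- which.min(abs(pal$mets - want))
  codes[slot] <- pal$code[best]
  codes
}

#' Generate a participant's true activity schedule
#'
#' Builds `days` daily 96-slot grids of activity codes: a 23:00-07:00
#' sleep block, an occupation-dependent work/commute structure on
#' weekdays, and free time steered so that each day's implied PAL
#' (average MET x 1.1 / 0.9) matches the participant's true PAL within
#' 1%.  Slot placement of the steering activities is randomized, so two
#' seeds give different grids with the same implied PAL.
#'
#' @param participant one row of `generate_cohort()$participants` (data
#'   frame or list).
#' @param days number of days (14 for the full crossover protocol).
#' @param seed integer RNG seed.
#' @param compendium a [compendium()].
#' @param constants see [ee_constants()].
#' @return A `days` x 96 character matrix of activity codes with
#'   attribute `target_avg_mets`.
#' @export
generate_true_schedule <- function(participant, days = 14, seed = 1L,
                                   compendium = default_compendium(),
                                   constants = ee_constants()) {
  set.seed(as.integer(seed))
  target_avg <- participant$true_pal * constants$dit_divisor /
    constants$sitting_factor
  grid <- matrix("", nrow = days, ncol = 96)
  pal_min <- min(adjust_palette(compendium)$mets)
  free_budget <- function(codes) {
    mets <- lookup_mets(compendium, codes)
    fixed <- codes %in% FIXED_CODES
    (target_avg * 96 - sum(mets[fixed])) / sum(!fixed)
  }
  for (d in seq_len(days)) {
    workday <- (d - 1) %% 7 < 5
    codes <- base_day_codes(participant$occupation_class, workday)
    if (free_budget(codes) < pal_min)
      codes <- base_day_codes(participant$occupation_class, workday,
                              sedentary = TRUE)
    grid[d, ] <- calibrate_day(codes, target_avg, compendium)
  }
  attr(grid, "target_avg_mets") <- target_avg
  grid
}

#' Render instrument reports from a truth schedule
#'
#' Derives both instruments' reports for the same block of truth days.
#' The diary copies the true activity codes, misclassifying each slot
#' with probability `diary_misclass_prob` (replaced by a uniformly random
#' other activity).  The recall aggregates each day to sleep hours plus
#' period x intensity-class durations (sub-light waking time is left
#' unaccounted, to be filled at 1.3 METs by the scorer), perturbs entry
#' hours multiplicatively at `recall_hours_cv`, optionally inflates
#' women's hours by `female_overreport_frac`, and - for participants
#' drawn as gross over-estimators - replaces all waking time with a
#' single elevated class regardless of true behavior.
#'
#' @param grid truth matrix from [generate_true_schedule()].
#' @param participant the matching cohort row.
#' @param dates Date vector, one per grid row.
#' @param noise a [noise_config()].
#' @param compendium a [compendium()].
#' @param seed integer RNG seed (default: `noise$seed`).
#' @return A list: `diary` (list of [diary_day()]), `recall` (list of
#'   [recall_day()]), `gross_overestimator` (logical).
#' @export
render_reports <- function(grid, participant, dates = NULL,
                           noise = noise_config(),
                           compendium = default_compendium(),
                           seed = noise$seed) {
  set.seed(as.integer(seed))
  days <- nrow(grid)
  if (is.null(dates)) dates <- as.Date("2024-04-01") + seq_len(days) - 1
  gross <- stats::runif(1) < noise$gross_overestimator_prob
  diary <- vector("list", days)
  recall <- vector("list", days)
  for (d in seq_len(days)) {
    codes <- grid[d, ]
    # diary channel: per-slot misclassification
    flip <- stats::runif(96) < noise$diary_misclass_prob
    if (any(flip))
      codes[flip] <- vapply(codes[flip], function(cur)
        sample(setdiff(compendium$code, cur), 1), character(1))
    diary[[d]] <- diary_day(participant$participant_id, dates[d], codes)
    # recall channel: aggregate truth to period x class hours
    true_codes <- grid[d, ]
    sleep_hours <- sum(true_codes == "sleep") / 4
    waking <- which(true_codes != "sleep")
    if (gross) {
      per_period <- (24 - sleep_hours) / 3
      entries <- data.frame(period = RECALL_PERIODS,
                            class = "moderate_high",
                            hours = per_period)
    } else {
      mets <- lookup_mets(compendium, true_codes[waking])
      cls <- class_for_mets(mets)
      hour_of_day <- (waking - 1) / 4
      period <- ifelse(hour_of_day >= 4 & hour_of_day < 12, "morning",
                       ifelse(hour_of_day >= 12 & hour_of_day < 18,
                              "afternoon", "evening"))
      keep <- cls != "very_light"   # sub-light time stays unaccounted
      entries <- if (any(keep)) {
        agg <- stats::aggregate(list(hours = rep(0.25, sum(keep))),
                                by = list(period = period[keep],
                                          class = cls[keep]),
                                FUN = sum)
        agg
      } else {
        data.frame(period = character(), class = character(),
                   hours = numeric())
      }
      if (nrow(entries)) {
        scale <- 1 + noise$female_overreport_frac *
          (participant$sex == "female")
        jitter <- exp(stats::rnorm(nrow(entries), 0, noise$recall_hours_cv))
        entries$hours <- entries$hours * jitter * scale
        total <- sum(entries$hours)
        budget <- 24 - sleep_hours
        if (total > budget) entries$hours <- entries$hours * budget / total
      }
    }
    recall[[d]] <- recall_day(participant$participant_id, dates[d],
                              sleep_hours, entries)
  }
  list(diary = diary, recall = recall, gross_overestimator = gross)
}

#' Render a DLW isotope series from true weekly TEE
#'
#' Inverts the DLW chain: each week's true TEE is converted to CO2
#' production via the Weir equation at the assumed RQ, then - given the
#' participant's body water, dilution-space ratio and deuterium
#' elimination rate - to the 18O elimination rate for that week.  The
#' resulting piecewise-exponential enrichment curves are sampled at
#' baseline and in duplicate on the mornings of days 1, 8 and 15, with
#' Gaussian analytic noise on the delta values.  Dosing follows the
#' standard 0.12 / 2.5 g per kg predicted body water.
#'
#' @param participant one cohort row.
#' @param tee_week1_mj,tee_week2_mj true weekly TEE, MJ/day.
#' @param noise a [noise_config()].
#' @param seed integer RNG seed.
#' @param constants see [ee_constants()].
#' @return A list: `samples` ([isotope_samples()]), `dose`
#'   ([dosing_record()]), `truth` (the generating `n_d_mol`, `n_o_mol`,
#'   `k_d`, `k_o_week1`, `k_o_week2`).
#' @export
render_isotopes <- function(participant, tee_week1_mj, tee_week2_mj,
                            noise = noise_config(), seed = noise$seed,
                            constants = ee_constants()) {
  if (tee_week1_mj <= 0 || tee_week2_mj <= 0)
    stop("true TEE must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  tbw <- participant$tbw_mol
  rho <- participant$nd_no_ratio
  k_d <- participant$k_d_perday
  mass_h2o <- 2 * constants$mass_h_natural + constants$mass_o_natural
  tbw_kg <- tbw * mass_h2o / 1000
  dose <- dosing_record(mass_2h2o_g = 0.12 * tbw_kg,
                        mass_h218o_g = 2.5 * tbw_kg)
  moles <- tracer_moles(dose, constants)
  n_o <- 2 * tbw / (rho / constants$nd_space_factor +
                      1 / constants$no_space_factor)
  n_d <- rho * n_o
  e0_2h <- moles$mol_2h / (2 * n_d)
  e0_18o <- moles$mol_18o / n_o

  mj_per_mol_co2 <- tee_from_rco2(1, constants$rq, constants)
  k_o_for <- function(tee) {
    r <- tee / mj_per_mol_co2
    k_o <- (r / (constants$rco2_factor * tbw) +
              constants$nd_space_factor * k_d) / constants$no_space_factor
    if (constants$no_space_factor * k_o <= constants$nd_space_factor * k_d)
      stop("infeasible kinetics: implied k_O does not exceed k_D",
           call. = FALSE)
    k_o
  }
  k_o1 <- k_o_for(tee_week1_mj)
  k_o2 <- k_o_for(tee_week2_mj)

  decay <- function(e0, k1, k2, t) {
    ifelse(t <= 8, e0 * exp(-k1 * t),
           e0 * exp(-k1 * 8) * exp(-k2 * (t - 8)))
  }
  t_post <- c(1.0, 1.04, 8.0, 8.04, 15.0, 15.04)
  base_2h <- -50   # typical body-water delta vs VSMOW, permil
  base_18o <- -8
  x_base_2h <- delta_to_mole_fraction(base_2h, constants$r_vsmow_2h)
  x_base_18o <- delta_to_mole_fraction(base_18o, constants$r_vsmow_18o)
  d2h <- mole_fraction_to_delta(x_base_2h + decay(e0_2h, k_d, k_d, t_post),
                                constants$r_vsmow_2h)
  d18o <- mole_fraction_to_delta(x_base_18o + decay(e0_18o, k_o1, k_o2, t_post),
                                 constants$r_vsmow_18o)
  times <- c(0, t_post)
  deltas_2h <- c(base_2h, d2h) +
    stats::rnorm(7, 0, noise$sd_delta2h_permil)
  deltas_18o <- c(base_18o, d18o) +
    stats::rnorm(7, 0, noise$sd_delta18o_permil)
  list(samples = isotope_samples(times, deltas_2h, deltas_18o),
       dose = dose,
       truth = list(n_d_mol = n_d, n_o_mol = n_o, k_d = k_d,
                    k_o_week1 = k_o1, k_o_week2 = k_o2))
}

#' Simulate a complete crossover validation study
#'
#' Generates a cohort, 14 days of truth per participant, both
#' instruments' reports for their assigned weeks, the DLW isotope series
#' and dosing records, and an indirect-calorimetry gas series consistent
#' with each participant's BMR.  Returns all study tables as data frames
#' and optionally writes them as CSV files readable by the scoring,
#' calorimetry and DLW readers.
#'
#' @param n cohort size (default 20: the archetypal 10 + 10 crossover).
#' @param seed integer master seed; everything is reproducible from it.
#' @param noise a [noise_config()].
#' @param compendium a [compendium()].
#' @param constants see [ee_constants()].
#' @param outdir optional directory; when given, writes `diary.csv`,
#'   `recall.csv`, `iso.csv`, `dose.csv`, `gas.csv`, `bmr.csv`,
#'   `truth.csv`, `assignment.csv`.
#' @return A named list of data frames (`diary`, `recall`, `iso`, `dose`,
#'   `gas`, `bmr`, `truth`, `assignment`).
#' @export
simulate_study <- function(n = 20, seed = 42L, noise = noise_config(),
                           compendium = default_compendium(),
                           constants = ee_constants(), outdir = NULL) {
  cohort <- generate_cohort(n, seed)
  participants <- cohort$participants
  assignment <- cohort$assignment
  start_date <- as.Date("2024-04-01")
  dates <- start_date + 0:13

  diary_rows <- list(); recall_rows <- list(); iso_rows <- list()
  dose_rows <- list(); gas_rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    p <- participants[i, ]
    sub_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    grid <- generate_true_schedule(p, days = 14, seed = sub_seed,
                                   compendium = compendium,
                                   constants = constants)
    bmr_kcal <- p$bmr_mj_day / constants$kcal_to_mj
    avg_by_day <- vapply(seq_len(14), function(d)
      mean(lookup_mets(compendium, grid[d, ])), numeric(1))
    tee_week <- vapply(list(1:7, 8:14), function(ix)
      bmr_kcal * mean(avg_by_day[ix]) * constants$sitting_factor /
        constants$dit_divisor * constants$kcal_to_mj, numeric(1))

    reports <- render_reports(grid, p, dates = dates, noise = noise,
                              compendium = compendium,
                              seed = sub_seed + 1L)
    # each instrument contributes only its assigned week
    par24_week <- if (assignment$week1_instrument[i] == "par24") 1:7 else 8:14
    recall_week <- setdiff(1:14, par24_week)
    diary_rows[[i]] <- do.call(rbind, lapply(par24_week, function(d) {
      dd <- reports$diary[[d]]
      data.frame(participant_id = dd$participant_id,
                 date = format(dd$date),
                 slot_index = 0:95, activity_code = dd$slots,
                 stringsAsFactors = FALSE)
    }))
    recall_rows[[i]] <- do.call(rbind, lapply(recall_week, function(d) {
      rd <- reports$recall[[d]]
      ent <- rd$entries
      if (nrow(ent) == 0)
        ent <- data.frame(period = NA_character_, class = NA_character_,
                          hours = NA_real_)
      data.frame(participant_id = rd$participant_id,
                 date = format(rd$date), sleep_hours = rd$sleep_hours,
                 period = ent$period, intensity_class = ent$class,
                 hours = ent$hours, stringsAsFactors = FALSE)
    }))

    iso <- render_isotopes(p, tee_week[1], tee_week[2], noise = noise,
                           seed = sub_seed + 2L, constants = constants)
    iso_rows[[i]] <- data.frame(participant_id = p$participant_id,
                                iso$samples, stringsAsFactors = FALSE)
    dose_rows[[i]] <- data.frame(participant_id = p$participant_id,
                                 as.data.frame(unclass(iso$dose)),
                                 stringsAsFactors = FALSE)

    # gas exchange consistent with true BMR at RQ 0.85; jitter well
    # inside the 25 mL/min acceptance band
    set.seed(sub_seed + 3L)
    vo2_l_day <- bmr_kcal / (constants$weir_vo2 +
                               constants$weir_vco2 * constants$rq)
    vo2_ml_min <- vo2_l_day * 1000 / 1440
    jitter <- stats::runif(30, -5, 5)
    gas_rows[[i]] <- data.frame(
      participant_id = p$participant_id, minute = 1:30,
      vo2_ml_min = vo2_ml_min + jitter,
      vco2_ml_min = constants$rq * (vo2_ml_min + jitter),
      stringsAsFactors = FALSE)

    truth_rows[[i]] <- cbind(p,
                             data.frame(tee_true_week1_mj = tee_week[1],
                                        tee_true_week2_mj = tee_week[2],
                                        gross_overestimator =
                                          reports$gross_overestimator))
  }
  out <- list(diary = do.call(rbind, diary_rows),
              recall = do.call(rbind, recall_rows),
              iso = do.call(rbind, iso_rows),
              dose = do.call(rbind, dose_rows),
              gas = do.call(rbind, gas_rows),
              bmr = data.frame(
                participant_id = participants$participant_id,
                bmr_mj_day = participants$bmr_mj_day,
                bmr_kcal_day = participants$bmr_mj_day / constants$kcal_to_mj,
                stringsAsFactors = FALSE),
              truth = do.call(rbind, truth_rows),
              assignment = assignment)
  rownames(out$truth) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(diary = "diary.csv", recall = "recall.csv", iso = "iso.csv",
               dose = "dose.csv", gas = "gas.csv", bmr = "bmr.csv",
               truth = "truth.csv", assignment = "assignment.csv")
    for (nm in names(files))
      utils::write.csv(out[[nm]], file.path(outdir, files[nm]),
                       row.names = FALSE)
  }
  out
}
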