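test_that("cohort generation is reproducible and balanced", {
  a <- generate_cohort(20, seed = 42)
  b <- generate_cohort(20, seed = 42)
  expect_identical(a, b)
  expect_equal(unname(table(a$participants$sex)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_equal(sum(a$assignment$week1_instrument == "par24"), 10)
  # every participant uses both instruments, one per week
  expect_true(all(a$assignment$week1_instrument !=
                    a$assignment$week2_instrument))
  expect_error(generate_cohort(1, 1), "at least 2")
})

test_that("cohort physiology matches its configured distributions", {
  big <- generate_cohort(2000, seed = 314)$participants
  males <- big[big$sex == "male", ]
  # truncated-normal mean for BMR ~ N(6.50, 0.89) on [4.77, 8.00]
  a <- (4.77 - 6.50) / 0.89; b <- (8.00 - 6.50) / 0.89
  mu_trunc <- 6.50 + 0.89 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(males$bmr_mj_day) / sqrt(nrow(males))
  expect_lt(abs(mean(males$bmr_mj_day) - mu_trunc), 3 * se)
  expect_true(all(males$bmr_mj_day >= 4.77 & males$bmr_mj_day <= 8.00))
  expect_true(all(big$nd_no_ratio >= 1.011 & big$nd_no_ratio <= 1.043))
  expect_true(all(big$true_pal > 1.3 & big$true_pal < 2.2))
})

test_that("true schedules hit the target PAL within 1% across occupations", {
  cmp <- default_compendium()
  for (case in list(list(pal = 1.42, occ = "fulltime"),
                    list(pal = 2.09, occ = "fulltime"),
                    list(pal = 1.45, occ = "homemaker"),
                    list(pal = 2.14, occ = "parttime"),
                    list(pal = 1.83, occ = "selfemployed"))) {
    p <- list(true_pal = case$pal, occupation_class = case$occ)
    grid <- generate_true_schedule(p, days = 7, seed = 5)
    expect_equal(dim(grid), c(7, 96))
    avg <- rowMeans(matrix(lookup_mets(cmp, grid), nrow = 7))
    implied_pal <- avg * 1.1 / 0.9
    expect_true(all(abs(implied_pal / case$pal - 1) < 0.01),
                label = sprintf("PAL %.2f / %s within 1%%",
                                case$pal, case$occ))
  }
})

test_that("different seeds give different grids with the same implied PAL", {
  cmp <- default_compendium()
  p <- list(true_pal = 1.8, occupation_class = "fulltime")
  g1 <- generate_true_schedule(p, days = 2, seed = 1)
  g2 <- generate_true_schedule(p, days = 2, seed = 2)
  expect_false(identical(g1, g2))
  for (g in list(g1, g2)) {
    avg <- mean(lookup_mets(cmp, g[1, ]))
    expect_equal(avg * 1.1 / 0.9, 1.8, tolerance = 0.01)
  }
})

test_that("a noiseless diary channel scores back to truth exactly", {
  cohort <- generate_cohort(4, seed = 9)
  p <- cohort$participants[1, ]
  grid <- generate_true_schedule(p, days = 7, seed = 10)
  quiet <- noise_config(sd_delta2h_permil = 0, sd_delta18o_permil = 0,
                        diary_misclass_prob = 0, recall_hours_cv = 0,
                        gross_overestimator_prob = 0)
  rep <- render_reports(grid, p, noise = quiet, seed = 11)
  cmp <- default_compendium()
  bmr_kcal <- p$bmr_mj_day / 4.184e-3
  truth_avg <- mean(lookup_mets(cmp, grid))
  wk <- score_week(rep$diary, bmr_kcal, cmp)
  expect_equal(wk$avg_mets, truth_avg)
  # recall matches truth up to intensity-class quantization
  wk_r <- score_recall_week(rep$recall, bmr_kcal)
  expect_equal(wk_r$avg_mets, truth_avg, tolerance = 0.2)
})

test_that("a degenerate two-activity channel with certain misclassification swaps codes", {
  cmp2 <- compendium(data.frame(code = c("a", "b"), label = c("A", "B"),
                                category = "leisure", mets = c(1.0, 3.5)))
  grid <- matrix("a", nrow = 1, ncol = 96)
  p <- list(participant_id = "p1", sex = "male")
  rep <- render_reports(grid, p, noise = noise_config(
    diary_misclass_prob = 1, gross_overestimator_prob = 0),
    compendium = cmp2, seed = 2)
  expect_true(all(rep$diary[[1]]$slots == "b"))
  expect_equal(average_mets(rep$diary[[1]], cmp2), 3.5)
})

test_that("a gross over-estimator stands out at 3 SD in the cohort", {
  cohort <- generate_cohort(20, seed = 77)
  cmp <- default_compendium()
  quiet <- noise_config(diary_misclass_prob = 0, recall_hours_cv = 0,
                        gross_overestimator_prob = 0)
  loud <- noise_config(diary_misclass_prob = 0, recall_hours_cv = 0,
                       gross_overestimator_prob = 1)
  aee <- sapply(seq_len(20), function(i) {
    p <- cohort$participants[i, ]
    grid <- generate_true_schedule(p, days = 7, seed = 100 + i,
                                   compendium = cmp)
    noise <- if (i == 20) loud else quiet
    rep <- render_reports(grid, p, noise = noise, compendium = cmp,
                          seed = 200 + i)
    score_recall_week(rep$recall, p$bmr_mj_day / 4.184e-3)$aee_mj
  })
  expect_equal(flag_outliers(aee, k_sd = 3), 20L)
})

test_that("isotope rendering inverts the kinetics consistently", {
  p <- generate_cohort(2, seed = 55)$participants[1, ]
  quiet <- noise_config(sd_delta2h_permil = 0, sd_delta18o_permil = 0)
  tee <- p$true_pal * p$bmr_mj_day
  iso <- render_isotopes(p, tee, tee, noise = quiet, seed = 3)
  # k_O rises with TEE at fixed TBW and k_D
  iso_hi <- render_isotopes(p, 2 * tee, 2 * tee, noise = quiet, seed = 3)
  expect_gt(iso_hi$truth$k_o_week1, iso$truth$k_o_week1)
  # zero-noise round trip through the analysis chain
  for (w in 1:2) {
    res <- dlw_week(iso$samples, iso$dose, p$bmr_mj_day, week = w)
    expect_equal(res$tee_mj_day, tee, tolerance = 1e-3)
    expect_equal(res$nd_no_ratio, p$nd_no_ratio, tolerance = 1e-6)
  }
})

test_that("TEE recovery is unbiased under analytic noise", {
  set.seed(99)
  cohort <- generate_cohort(200, seed = 99)
  errs <- vapply(seq_len(200), function(i) {
    p <- cohort$participants[i, ]
    tee <- p$true_pal * p$bmr_mj_day
    iso <- render_isotopes(p, tee, tee, noise = noise_config(),
                           seed = 1000 + i)
    dlw_week(iso$samples, iso$dose, p$bmr_mj_day, 1)$tee_mj_day / tee - 1
  }, numeric(1))
  ci <- t.test(errs)$conf.int
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("full study simulation is reproducible and self-consistent", {
  s1 <- simulate_study(n = 6, seed = 12)
  s2 <- simulate_study(n = 6, seed = 12)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$diary), 6 * 7 * 96)
  expect_equal(nrow(s1$iso), 6 * 7)
  # each participant's diary belongs to the week their assignment says
  first_diary_dates <- tapply(as.Date(s1$diary$date),
                              s1$diary$participant_id, min)
  w1 <- s1$assignment$week1_instrument[
    match(names(first_diary_dates), s1$assignment$participant_id)]
  expect_true(all((first_diary_dates == as.Date("2024-04-01")) ==
                    (w1 == "par24")))
})
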