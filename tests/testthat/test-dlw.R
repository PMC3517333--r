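cst <- ee_constants()

test_that("tracer moles follow mass balance on the dose", {
  dose <- dosing_record(mass_2h2o_g = 4.8, mass_h218o_g = 100)
  m <- tracer_moles(dose)
  # independent mass balance written out from first principles
  a2 <- 0.998; a18 <- 0.10
  molar_2h2o <- 2 * (a2 * 2.0141017779 + (1 - a2) * 1.0078250319) + 15.9994
  molar_h218o <- 2 * 1.00794 + a18 * 17.9991604 + (1 - a18) * 15.9949146221
  nat2 <- 155.76e-6 / (1 + 155.76e-6)
  nat18 <- 2005.20e-6 / (1 + 2005.20e-6)
  expect_equal(m$mol_2h, 4.8 / molar_2h2o * 2 * (a2 - nat2))
  expect_equal(m$mol_18o, 100 / molar_h218o * (a18 - nat18))
  # linearity in mass
  half <- tracer_moles(dosing_record(2.4, mass_h218o_g = 50))
  expect_equal(half$mol_2h, m$mol_2h / 2)
  expect_equal(half$mol_18o, m$mol_18o / 2)
})

test_that("pure tracer with zero natural abundance gives mass over molar mass", {
  pure <- ee_constants(r_vsmow_2h = 0, r_vsmow_18o = 0)
  dose <- dosing_record(20.0276, atom_pct_2h = 100, mass_h218o_g = 20.015,
                        atom_pct_18o = 100)
  m <- tracer_moles(dose, pure)
  expect_equal(m$mol_2h, 20.0276 / (2 * 2.0141017779 + 15.9994) * 2,
               tolerance = 1e-6)
  expect_equal(m$mol_18o, 20.015 / (2 * 1.00794 + 17.9991604),
               tolerance = 1e-6)
})

test_that("elimination fits recover exact exponentials to machine precision", {
  s <- hand_isotope_series(e0_2h = 1.1e-4, e0_18o = 2.4e-4,
                           k_d = 0.10, k_o = 0.12)
  f2 <- fit_elimination(s, "2H")
  f18 <- fit_elimination(s, "18O")
  expect_equal(f2$k_perday, 0.10, tolerance = 1e-9)
  expect_equal(f2$excess0, 1.1e-4, tolerance = 1e-9)
  expect_equal(f18$k_perday, 0.12, tolerance = 1e-9)
  expect_equal(f18$excess0, 2.4e-4, tolerance = 1e-9)
  expect_equal(f2$n, 6)  # duplicates enter as separate observations
})

test_that("two post-dose points reduce to the two-point slope formula", {
  s <- hand_isotope_series(1.1e-4, 2.4e-4, k_d = 0.09, k_o = 0.11,
                           times = c(1, 15))
  f <- fit_elimination(s, "2H", window = c(1, 15))
  e1 <- 1.1e-4 * exp(-0.09 * 1)
  e15 <- 1.1e-4 * exp(-0.09 * 15)
  expect_equal(f$k_perday, (log(e1) - log(e15)) / (15 - 1),
               tolerance = 1e-9)
  expect_error(fit_elimination(s, "2H", window = c(0, 2)), "at least 2")
})

test_that("noisy elimination fits agree with a grid-search least-squares oracle", {
  set.seed(42)
  times <- c(1, 1.04, 8, 8.04, 15, 15.04)
  k_true <- 0.115; e0_true <- 2.2e-4
  noisy_delta <- function() {
    x_base <- cst$r_vsmow_18o / (1 + cst$r_vsmow_18o)
    x <- x_base + e0_true * exp(-k_true * times) * exp(rnorm(6, 0, 0.01))
    r <- x / (1 - x)
    (r / cst$r_vsmow_18o - 1) * 1000
  }
  s <- isotope_samples(c(0, times), rep(0, 7), c(0, noisy_delta()))
  f <- fit_elimination(s, "18O")
  # oracle: exhaustive grid over k, closed-form intercept given k
  ex <- log(sapply(times, function(t) {
    row <- s[abs(s$time_days - t) < 1e-9, ]
    r <- cst$r_vsmow_18o * (1 + row$delta_18o_permil / 1000)
    r / (1 + r) - cst$r_vsmow_18o / (1 + cst$r_vsmow_18o)
  }))
  ks <- seq(0.05, 0.20, by = 1e-5)
  sse <- sapply(ks, function(k) {
    b0 <- mean(ex) + k * mean(times)
    sum((ex - (b0 - k * times))^2)
  })
  k_grid <- ks[which.min(sse)]
  expect_lt(abs(f$k_perday - k_grid), 1e-5)  # within one grid step
})

test_that("baseline violations are reported, not fitted", {
  s <- isotope_samples(c(0, 1, 8), c(-50, -50, -60), c(-8, 10, 5))
  expect_error(fit_elimination(s, "2H"), "baseline")
})

test_that("dilution spaces combine to TBW with the 1.041/1.007 proportions", {
  dose <- dosing_record(mass_2h2o_g = 4.8, mass_h218o_g = 100)
  m <- tracer_moles(dose)
  x <- 2000
  sp <- dilution_spaces(dose,
                        excess0_2h = m$mol_2h / (2 * 1.041 * x),
                        excess0_18o = m$mol_18o / (1.007 * x))
  expect_equal(sp$n_d_mol, 1.041 * x)
  expect_equal(sp$n_o_mol, 1.007 * x)
  expect_equal(sp$tbw_mol, x)   # consistent spaces recover TBW exactly
  expect_equal(sp$nd_no_ratio, 1.041 / 1.007)
  expect_true(sp$qc_pass)
  # the 2082 / 2014 arithmetic: TBW 2000, ratio 1.0338
  sp2 <- dilution_spaces(dose, excess0_2h = m$mol_2h / (2 * 2082),
                         excess0_18o = m$mol_18o / 2014)
  expect_equal(sp2$tbw_mol, mean(c(2082 / 1.041, 2014 / 1.007)))
  expect_equal(round(sp2$nd_no_ratio, 4), 1.0338)
})

test_that("an implausible dilution-space ratio raises a QC flag", {
  dose <- dosing_record(mass_2h2o_g = 4.8, mass_h218o_g = 100)
  m <- tracer_moles(dose)
  expect_warning(
    sp <- dilution_spaces(dose, excess0_2h = m$mol_2h / (2 * 1.09 * 2000),
                          excess0_18o = m$mol_18o / 2000),
    "plausibility")
  expect_false(sp$qc_pass)
})

test_that("CO2 production follows the fractionation-corrected rate difference", {
  expect_equal(rco2(2000, 0.12, 0.10),
               0.4554 * 2000 * (1.007 * 0.12 - 1.041 * 0.10))
  expect_equal(round(rco2(2000, 0.12, 0.10), 3), 15.247)
  expect_equal(rco2(2000, 1.041 * 0.1 / 1.007, 0.1), 0)  # null production
  expect_equal(rco2(4000, 0.12, 0.10), 2 * rco2(2000, 0.12, 0.10))
  expect_error(rco2(2000, 0.08, 0.10), "negative CO2")
})

test_that("TEE from CO2 production chains molar volume, RQ and Weir", {
  expect_equal(tee_from_rco2(0), 0)
  r <- 15.246
  vco2 <- r * 22.414
  vo2 <- vco2 / 0.85
  expect_equal(tee_from_rco2(r),
               (3.941 * vo2 + 1.106 * vco2) * 4.184e-3)
  expect_equal(2 * tee_from_rco2(r), tee_from_rco2(2 * r))
  expect_gt(tee_from_rco2(r, rq = 0.80), tee_from_rco2(r, rq = 0.90))
  expect_error(tee_from_rco2(r, rq = 1.2), "respiratory quotient")
})

test_that("the full weekly chain round-trips noise-free kinetics", {
  tbw <- 2200; rho <- 1.027; k_d <- 0.10; k_o <- 0.125
  n_o <- 2 * tbw / (rho / 1.041 + 1 / 1.007)
  n_d <- rho * n_o
  tbw_kg <- tbw * (2 * 1.00794 + 15.9994) / 1000
  dose <- dosing_record(0.12 * tbw_kg, mass_h218o_g = 2.5 * tbw_kg)
  m <- tracer_moles(dose)
  s <- hand_isotope_series(e0_2h = m$mol_2h / (2 * n_d),
                           e0_18o = m$mol_18o / n_o,
                           k_d = k_d, k_o = k_o)
  truth_tee <- tee_from_rco2(rco2(tbw, k_o, k_d))
  for (w in 1:2) {
    res <- dlw_week(s, dose, bmr_mj_day = 6.0, week = w)
    expect_equal(res$tee_mj_day, truth_tee, tolerance = 1e-6)
    expect_equal(res$tbw_mol, tbw, tolerance = 1e-6)
    expect_equal(res$nd_no_ratio, rho, tolerance = 1e-9)
    expect_equal(res$k_d_perday, k_d, tolerance = 1e-9)
    expect_equal(res$k_o_perday, k_o, tolerance = 1e-9)
    expect_gt(res$k_o_perday, res$k_d_perday)
    expect_equal(res$pal, res$tee_mj_day / 6.0)
  }
  # identical kinetics both weeks: identical weekly TEE; PAL 1 when BMR = TEE
  expect_equal(dlw_week(s, dose, 6, week = 1)$tee_mj_day,
               dlw_week(s, dose, 6, week = 2)$tee_mj_day)
  expect_equal(dlw_week(s, dose, truth_tee, week = 1)$pal, 1,
               tolerance = 1e-6)
})

test_that("missing endpoint days are an explicit error", {
  s <- hand_isotope_series(1.1e-4, 2.54e-4, 0.1, 0.12, times = c(1, 8))
  expect_error(dlw_week(s, dosing_record(4.8, mass_h218o_g = 100), 6,
                        week = 2), "endpoint")
})
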