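# Shared fixtures, all built in code.

# tiny hand-made compendium with round MET values for arithmetic tests
toy_compendium <- function() {
  compendium(data.frame(
    code = c("rest", "low", "mid", "high", "sleep"),
    label = c("Resting", "Low", "Mid", "High", "Sleeping"),
    category = c("leisure", "leisure", "work", "sports", "leisure"),
    mets = c(1.0, 2.1, 3.5, 7.0, 0.9)), version = "toy")
}

# a diary day over a given code vector, recycled to 96 slots
toy_day <- function(codes, id = "p1", date = "2024-01-01") {
  diary_day(id, date, rep_len(codes, 96))
}

# noiseless isotope series from explicit kinetics, built with hand
# formulas independent of the simulator (constant k both weeks)
hand_isotope_series <- function(e0_2h, e0_18o, k_d, k_o,
                                times = c(1, 1.04, 8, 8.04, 15, 15.04),
                                base_2h = -50, base_18o = -8,
                                cst = ee_constants()) {
  to_x <- function(delta, r) { rr <- r * (1 + delta / 1000); rr / (1 + rr) }
  to_d <- function(x, r) { rr <- x / (1 - x); (rr / r - 1) * 1000 }
  x2 <- to_x(base_2h, cst$r_vsmow_2h) + e0_2h * exp(-k_d * times)
  x18 <- to_x(base_18o, cst$r_vsmow_18o) + e0_18o * exp(-k_o * times)
  isotope_samples(c(0, times),
                  c(base_2h, to_d(x2, cst$r_vsmow_2h)),
                  c(base_18o, to_d(x18, cst$r_vsmow_18o)))
}
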