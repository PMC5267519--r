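# six synthetic compounds whose true RIS spans ~0.08-20, covering the
# calibration curve from foot to plateau (cmax_ub back-derived from the
# target RIS via C = EC50 * RIS / (Emax - RIS))
test_compounds <- function() {
  tibble::tibble(
    compound = c("A", "B", "C", "D", "E", "F"),
    e_max = c(22, 30, 15, 25, 18, 40),
    ec50_um = c(0.36, 12, 80, 3, 2.5, 5),
    slope = c(1, 1.5, 1, 2, 0.8, 1.2),
    conc_low_um = c(0.01, 0.1, 0.5, 0.02, 0.02, 0.05),
    conc_high_um = c(50, 2000, 10000, 400, 300, 600),
    cmax_ub_um = c(3.6, 2.4, 8.889, 0.036437, 0.021008, 0.010020)
  )
}

# reference calibration truth used by the generator round-trip tests
test_calibration <- function() {
  calibration_model(a = 98, b_slope = 2, c_half = 0.4)
}

# QC-ready fold-increase points sampled exactly from a Hill-4 curve
exact_hill_points <- function(e_max = 22, ec50 = 0.36, slope = 1,
                              conc = 10^seq(log10(0.01), log10(50),
                                            length.out = 8),
                              n_rep = 3, vehicle_mean = 100) {
  fi <- hill4(conc, e_min = 0, e_max = e_max, ec50 = ec50, slope = slope)
  wells <- data.frame(
    concentration_um = rep(conc, each = n_rep),
    value = rep(vehicle_mean * (1 + fi), each = n_rep)
  )
  pts <- fold_increase_points(wells, vehicle = rep(vehicle_mean, n_rep))
  apply_replicate_qc(pts)
}
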