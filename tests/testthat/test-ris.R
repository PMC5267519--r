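test_that("RIS follows the saturation formula", {
  fit <- list(e_max = 24, ec50 = 5, accepted = TRUE)
  expect_equal(compute_ris(fit, cmax_ub = 5), 12)          # half-saturation
  expect_equal(compute_ris(fit, cmax_ub = 1e12), 24, tolerance = 1e-9)
  # reference-style evaluation: Emax 25, EC50 187 uM, Cmax,ub 28 uM
  expect_equal(
    round(compute_ris(list(e_max = 25, ec50 = 187, accepted = TRUE), 28), 2),
    3.26)
  expect_error(compute_ris(fit, cmax_ub = NA), "missing")
  expect_error(compute_ris(fit, cmax_ub = -1), "positive")
  expect_error(compute_ris(list(e_max = 2, ec50 = 1, accepted = FALSE), 1),
               "not accepted")
})

test_that("RIS is monotone in Emax and Cmax, antitone in EC50", {
  base <- compute_ris(list(e_max = 20, ec50 = 5, accepted = TRUE), 2)
  expect_gt(compute_ris(list(e_max = 25, ec50 = 5, accepted = TRUE), 2), base)
  expect_gt(compute_ris(list(e_max = 20, ec50 = 5, accepted = TRUE), 3), base)
  expect_lt(compute_ris(list(e_max = 20, ec50 = 8, accepted = TRUE), 2), base)
})

test_that("cross-lot RIS summaries match hand-computed values", {
  ris <- data.frame(
    compound = rep(c("Rifampicin", "X", "Y"), each = 3),
    endpoint = "mRNA",
    lot = rep(c("2B", "3A", "3B"), 3),
    ris = c(19.1, 24.8, 21.5,  2, 2, 2,  1, NA, NA))
  expect_error(summarize_ris(ris), "at least 2 lots")
  ris$ris[8:9] <- 3  # refill Y's missing lots -> (1, 3, 3)
  s <- summarize_ris(ris)$per_compound
  rif <- s[s$compound == "Rifampicin", ]
  expect_equal(round(rif$mean_ris, 1), 21.8)
  expect_equal(round(rif$cv_pct), 13)
  expect_equal(s$cv_pct[s$compound == "X"], 0)
  # two-lot case: (1, 3) has CV sqrt(2)/2 * 100
  two <- summarize_ris(data.frame(compound = "Z", endpoint = "mRNA",
                                  lot = c("a", "b"), ris = c(1, 3)))
  expect_equal(two$per_compound$mean_ris, 2)
  expect_equal(two$per_compound$cv_pct, 100 * sqrt(2) / 2, tolerance = 1e-9)
})

test_that("calibration fitting recovers exact Hill-3 points", {
  truth <- calibration_model(a = 95, b_slope = 1.7, c_half = 0.35)
  x <- c(0.05, 0.15, 0.4, 1.2, 5, 20)
  y <- predict_auc_change(truth, x)
  m <- fit_calibration(x, y)
  expect_equal(m$a, truth$a, tolerance = 1e-6)
  expect_equal(m$b_slope, truth$b_slope, tolerance = 1e-6)
  expect_equal(m$c_half, truth$c_half, tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_calibration(x[1:3], y[1:3]), "at least 4")
  expect_error(fit_calibration(x, y[1:3]), "lengths differ")
})

test_that("reference calibration sets reproduce the printed correlations", {
  ris <- load_fixtures("table3_ris")
  meta <- load_fixtures("compounds")
  cal <- meta[meta$in_calibration_set, ]
  r2 <- vapply(c("2B", "3A", "3B"), function(lot) {
    sub <- ris[ris$endpoint == "mRNA" & ris$lot == lot &
                 ris$compound %in% cal$compound, ]
    obs <- cal$observed_auc_pct[match(sub$compound, cal$compound)]
    fit_calibration(sub$ris, obs, lot = lot, endpoint = "mRNA")$r_squared
  }, numeric(1))
  expect_equal(round(unname(r2), 2), c(0.95, 0.97, 0.99))
})

test_that("prediction is increasing, bounded, and zero at zero RIS", {
  m <- calibration_model(a = 98, b_slope = 2, c_half = 0.4)
  expect_equal(predict_auc_change(m, 0), 0)
  expect_equal(predict_auc_change(m, 0.4), 49)            # half-max at c
  expect_equal(predict_auc_change(m, NA), 0)              # no induction
  x <- seq(0, 50, length.out = 200)
  y <- predict_auc_change(m, x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < m$a))
  expect_error(predict_auc_change(m, -1), "non-negative")
})

test_that("the RIS cutoff inverts the calibration curve in closed form", {
  m <- calibration_model(a = 98, b_slope = 2, c_half = 0.4)
  expect_equal(ris_cutoff(m, 20), 0.4 * sqrt(20 / 78))  # 0.2025

  expect_equal(ris_cutoff(m, m$a / 2), m$c_half)          # half-max identity
  low <- calibration_model(a = 25, b_slope = 2, c_half = 0.4)
  expect_error(ris_cutoff(low, 30), "never reaches")
  # predict-cutoff round trip across many models
  set.seed(12)
  for (i in 1:25) {
    mi <- calibration_model(a = runif(1, 30, 110), b_slope = runif(1, 0.3, 6),
                            c_half = 10^runif(1, -3, 1))
    t <- runif(1, 1, mi$a - 1)
    expect_equal(predict_auc_change(mi, ris_cutoff(mi, t)), t,
                 tolerance = 1e-9)
  }
})

test_that("cutoff summaries aggregate across lots", {
  models <- list(
    calibration_model(98, 2, 0.4, lot = "2B", endpoint = "mRNA"),
    calibration_model(95, 3, 0.3, lot = "3A", endpoint = "mRNA"),
    calibration_model(97, 2.5, 0.35, lot = "3B", endpoint = "mRNA"))
  s <- ris_cutoff_summary(models, 20)
  expect_equal(nrow(s$per_lot), 3)
  expect_equal(s$mean, mean(s$per_lot$cutoff))
  expect_equal(s$cv_pct,
               100 * sd(s$per_lot$cutoff) / mean(s$per_lot$cutoff))
})
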