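test_that("the Hill-4 curve has its defining landmarks", {
  expect_equal(hill4(0.36, 0, 22, 0.36, 1), 11)         # half-max at EC50
  expect_equal(hill4(1, 2, 10, 1, 3), 6)                # (Emin + Emax)/2
  expect_equal(hill4(1e9, 0, 22, 0.36, 1), 22, tolerance = 1e-6)  # plateau
  # monotone and bounded for positive slope
  x <- 10^seq(-3, 3, length.out = 50)
  y <- hill4(x, 0.5, 22, 0.36, 1.7)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0.5 & y <= 22))
})

test_that("noise-free Hill data are recovered to high precision", {
  for (i in seq_len(nrow(test_compounds()))) {
    cmp <- test_compounds()[i, ]
    pts <- exact_hill_points(cmp$e_max, cmp$ec50_um, cmp$slope,
                             conc = 10^seq(log10(cmp$conc_low_um),
                                           log10(cmp$conc_high_um),
                                           length.out = 8))
    fit <- fit_hill4(pts)
    expect_equal(fit$method, "full_fit")
    expect_true(fit$accepted)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
    expect_equal(fit$e_max, cmp$e_max, tolerance = 1e-4)
    expect_equal(fit$ec50, cmp$ec50_um, tolerance = 1e-4)
    expect_equal(fit$slope, cmp$slope, tolerance = 1e-4)
    expect_lt(abs(fit$e_min), 1e-4)
  }
})

test_that("data without a plateau fall back to the observed maximum", {
  # strictly linear in log-dose, never flattening
  conc <- 10^seq(-1, 2, length.out = 8)
  fi <- seq(0.5, 12.5, length.out = 8)
  pts <- apply_replicate_qc(fold_increase_points(
    data.frame(concentration_um = rep(conc, each = 3),
               value = rep(100 * (1 + fi), each = 3)),
    vehicle = rep(100, 3)))
  fit <- fit_hill4(pts)
  expect_equal(fit$method, "observed_max_fallback")
  expect_equal(fit$e_max, 12.5)
  expect_gt(fit$ec50, 0)
})

test_that("a wild outlier drives the fit below the acceptance threshold", {
  pts <- exact_hill_points(22, 0.36, 1)
  # corrupt one mid-curve point enough that SS_res/SS_tot > 0.15
  idx <- 5
  pts$fold_increase[idx] <- pts$fold_increase[idx] + 40
  fit <- fit_hill4(pts)
  expect_lt(fit$r_squared, 0.85)
  expect_false(fit$accepted)
})

test_that("fitting fails informatively on degenerate input", {
  flat <- apply_replicate_qc(fold_increase_points(
    data.frame(concentration_um = rep(10^(0:7), each = 3),
               value = rep(150, 24)),
    vehicle = rep(100, 3)))
  expect_error(fit_hill4(flat), "degenerate")
  few <- exact_hill_points(conc = c(0.1, 1, 10))
  expect_error(fit_hill4(few), "at least 4")
})

test_that("the fit is equivariant under concentration rescaling", {
  pts_um <- exact_hill_points(22, 0.36, 1)
  pts_nm <- pts_um
  pts_nm$concentration_um <- pts_nm$concentration_um * 1000
  fit_um <- fit_hill4(pts_um)
  fit_nm <- fit_hill4(pts_nm)
  expect_equal(fit_nm$ec50, fit_um$ec50 * 1000, tolerance = 1e-4)
  expect_equal(fit_nm$e_max, fit_um$e_max, tolerance = 1e-6)
  expect_equal(fit_nm$slope, fit_um$slope, tolerance = 1e-4)
})

test_that("recovered slopes stay inside the realistic 0.4-4.2 envelope", {
  set.seed(31)
  slopes <- runif(8, 0.4, 4.2)
  recovered <- vapply(slopes, function(b) {
    cmp <- tibble::tibble(compound = "X", e_max = 20, ec50_um = 2,
                          slope = b, conc_low_um = 0.01,
                          conc_high_um = 200)
    spec <- panel_spec(cmp, n_lots = 1, noise_cv = 0.1,
                       endpoints = "mRNA", seed = round(b * 1000))
    wells <- generate_panel(spec)$wells
    pts <- apply_replicate_qc(fold_increase_points(
      wells[!wells$is_vehicle, ], wells$value[wells$is_vehicle]))
    fit_hill4(pts)$slope
  }, numeric(1))
  expect_true(all(recovered >= 0.1 & recovered <= 10))
  expect_true(all(abs(recovered - slopes) / slopes < 0.6))
})

test_that("the fit table carries NI/NA sentinels and numeric fits", {
  fit <- fit_hill4(exact_hill_points(22, 0.36, 1))
  tab <- collect_fit_table(list(
    list(compound = "Rifampicin", lot = "2B", endpoint = "mRNA", fit = fit,
         max_fold_induction = 23),
    list(compound = "Flumazenil", lot = "2B", endpoint = "mRNA",
         status = "NI"),
    list(compound = "Quinidine", lot = "2B", endpoint = "mRNA",
         status = "NA", max_fold_induction = 1.0)
  ))
  expect_equal(tab$status, c("fit", "NI", "NA"))
  expect_equal(tab$e_max[1], 22, tolerance = 1e-4)
  expect_true(all(is.na(tab$e_max[2:3])))
  expect_equal(tab$max_fold_induction[3], 1.0)
})
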