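test_that("fold induction normalizes treated means to the vehicle mean", {
  expect_equal(fold_induction_activity(c(10, 10, 10), c(10, 10, 10)), 1)
  expect_equal(fold_induction_activity(c(20, 20, 20), c(10, 10, 10)), 2)
  expect_equal(fold_induction_activity(c(9, 10, 11), c(4, 5, 6)), 2)
  expect_error(fold_induction_activity(c(1, 2), c(0, 0)), "vehicle mean")
  expect_error(fold_induction_activity(c(1, 2), c(-3, 1)), "vehicle mean")
})

test_that("2^-ddCt fold change behaves as an exponential homomorphism", {
  expect_equal(fold_induction_mrna(0), 1)
  expect_equal(fold_induction_mrna(-3), 8)
  expect_equal(fold_induction_mrna(1), 0.5)
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(fold_induction_mrna(a + b),
               fold_induction_mrna(a) * fold_induction_mrna(b))
  expect_error(fold_induction_mrna(NaN), "finite")
})

test_that("replicate QC applies the 40% CV rule on raw replicate values", {
  wells <- data.frame(
    concentration_um = rep(c(0.1, 1, 10), each = 3),
    value = c(10, 10, 10,   # CV 0 -> accepted
              1, 2, 3,      # CV 0.50 -> rejected
              30, 30, 30)
  )
  pts <- fold_increase_points(wells, vehicle = c(5, 5, 5))
  pts <- apply_replicate_qc(pts)
  expect_equal(pts$replicate_cv[pts$concentration_um == 1], 0.5)
  expect_false(pts$accepted[pts$concentration_um == 1])
  expect_equal(pts$exclusion_reason[pts$concentration_um == 1], "cv")
  expect_true(all(pts$accepted[pts$concentration_um != 1]))

  # two replicates are explicitly allowed: (9, 11) has CV ~ 0.141
  two_rep <- fold_increase_points(
    data.frame(concentration_um = c(1, 1), value = c(9, 11)),
    vehicle = c(5, 5))
  two_rep <- apply_replicate_qc(two_rep)
  expect_equal(two_rep$replicate_cv, sd(c(9, 11)) / 10)
  expect_true(two_rep$accepted)
})

test_that("QC is monotone in the CV threshold", {
  set.seed(7)
  wells <- data.frame(
    concentration_um = rep(10^(0:7), each = 3),
    value = abs(rnorm(24, mean = 50, sd = 25))
  )
  pts <- fold_increase_points(wells, vehicle = c(50, 50, 50))
  thresholds <- seq(0.05, 0.95, by = 0.05)
  accepted <- lapply(thresholds, function(th) {
    apply_replicate_qc(pts, cv_threshold = th)$accepted
  })
  for (i in seq_along(thresholds)[-1]) {
    # raising the threshold never rejects a previously accepted point
    expect_true(all(accepted[[i]] >= accepted[[i - 1]]))
  }
})

test_that("upstream toxicity flags survive QC with their reason", {
  wells <- data.frame(concentration_um = rep(c(1, 100), each = 3),
                      value = c(20, 20, 20, 19, 20, 21))
  pts <- fold_increase_points(
    wells, vehicle = c(10, 10, 10),
    exclusions = data.frame(concentration_um = 100, reason = "toxicity"))
  pts <- apply_replicate_qc(pts)
  expect_false(pts$accepted[pts$concentration_um == 100])
  expect_equal(pts$exclusion_reason[pts$concentration_um == 100], "toxicity")
  expect_true(pts$accepted[pts$concentration_um == 1])
})

test_that("induction classification separates the canonical patterns", {
  conc <- 10^seq(-2, log10(50), length.out = 8)
  make_pts <- function(fold_induction) {
    apply_replicate_qc(fold_increase_points(
      data.frame(concentration_um = rep(conc, each = 3),
                 value = rep(100 * fold_induction, each = 3)),
      vehicle = rep(100, 3)))
  }
  strong <- make_pts(1 + hill4(conc, 0, 22, 0.36, 1))  # reaches 22-fold
  flat <- make_pts(rep(1.02, 8))
  # positive on both endpoints
  both_pos <- classify_induction(list(activity = strong, mRNA = strong))
  expect_equal(both_pos$combined, "positive")
  expect_true(all(both_pos$per_endpoint$fit_eligible))
  # flat everywhere: negative, not fit-eligible
  both_neg <- classify_induction(list(activity = flat, mRNA = flat))
  expect_equal(both_neg$combined, "negative")
  expect_false(any(both_neg$per_endpoint$fit_eligible))
  # mRNA-only response (enzyme inhibition masking activity): indeterminate
  mixed <- classify_induction(list(activity = flat, mRNA = strong))
  expect_equal(mixed$combined, "indeterminate")
  expect_equal(
    mixed$per_endpoint$verdict[mixed$per_endpoint$endpoint == "mRNA"],
    "positive")
})

test_that("fit eligibility needs both dose dependence and a 1.4-fold max", {
  conc <- 10^seq(-2, 2, length.out = 8)
  # dose-dependent but shallow: max fold induction 1.3 < 1.4
  shallow <- apply_replicate_qc(fold_increase_points(
    data.frame(concentration_um = rep(conc, each = 3),
               value = rep(100 * (1 + hill4(conc, 0, 0.3, 1, 1)), each = 3)),
    vehicle = rep(100, 3)))
  cls <- classify_induction(list(mRNA = shallow))
  expect_false(cls$per_endpoint$fit_eligible)
  # non-monotone scatter around 2-fold with the max at the lowest
  # concentration: not concentration dependent
  scatter <- apply_replicate_qc(fold_increase_points(
    data.frame(concentration_um = rep(conc, each = 3),
               value = rep(c(210, 120, 150, 110, 160, 130, 140, 120),
                           each = 3)),
    vehicle = rep(100, 3)))
  cls2 <- classify_induction(list(mRNA = scatter))
  expect_false(cls2$per_endpoint$fit_eligible)
})
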