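#' Relative induction score
#'
#' `RIS = Emax * Cmax,ub / (EC50 + Cmax,ub)`: the in vitro induction potency
#' weighted by the clinical unbound plasma exposure of the inducer. Only
#' accepted induction-curve fits yield a RIS.
#'
#' @param fit An accepted `induction_curve_fit` (or any list with `e_max`
#'   and `ec50`).
#' @param cmax_ub Unbound plasma Cmax of the inducer (uM, positive).
#' @return The RIS (dimensionless, in `[0, Emax)`).
#' @examples
#' compute_ris(list(e_max = 25, ec50 = 187, accepted = TRUE), cmax_ub = 28)
#' @export
compute_ris <- function(fit, cmax_ub) {
  if (is.null(cmax_ub) || length(cmax_ub) != 1L || is.na(cmax_ub)) {
    stop("compute_ris: missing unbound Cmax", call. = FALSE)
  }
  if (cmax_ub <= 0) {
    stop("compute_ris: 'cmax_ub' must be positive", call. = FALSE)
  }
  if (!is.null(fit$accepted) && !isTRUE(fit$accepted)) {
    stop("compute_ris: curve fit was not accepted; RIS is undefined",
         call. = FALSE)
  }
  fit$e_max * cmax_ub / (fit$ec50 + cmax_ub)
}

#' Cross-lot RIS summary
#'
#' Per compound and endpoint: arithmetic mean RIS across lots and the
#' percent coefficient of variation (sample SD over mean, x100). The grand
#' mean %CV per endpoint — the average of the per-compound %CV values — is
#' the headline lot-to-lot reproducibility figure.
#'
#' @param ris_values A data frame with columns `compound`, `endpoint`,
#'   `lot`, `ris`.
#' @return A list with `per_compound` (tibble: `compound`, `endpoint`,
#'   `n_lots`, `mean_ris`, `cv_pct`) and `grand_mean_cv` (tibble:
#'   `endpoint`, `mean_cv_pct`, `n_compounds`). Values are full precision;
#'   round for display (%CV to integer percent).
#' @examples
#' ris <- data.frame(compound = "rifampicin", endpoint = "mRNA",
#'                   lot = c("2B", "3A", "3B"), ris = c(19.1, 24.8, 21.5))
#' summarize_ris(ris)$per_compound
#' @export
summarize_ris <- function(ris_values) {
  ris_values <- tibble::as_tibble(ris_values)
  per_compound <- ris_values |>
    dplyr::filter(!is.na(.data$ris)) |>
    dplyr::group_by(.data$compound, .data$endpoint) |>
    dplyr::summarise(
      n_lots = dplyr::n(),
      mean_ris = mean(.data$ris),
      cv_pct = 100 * sd(.data$ris) / mean(.data$ris),
      .groups = "drop"
    )
  if (any(per_compound$n_lots < 2)) {
    stop("summarize_ris: need RIS from at least 2 lots per compound",
         call. = FALSE)
  }
  grand <- per_compound |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::summarise(mean_cv_pct = mean(.data$cv_pct),
                     n_compounds = dplyr::n(), .groups = "drop")
  list(per_compound = per_compound, grand_mean_cv = grand)
}

#' Construct a Hill 3-parameter calibration model
#'
#' The calibration curve `f = a * x^b / (c^b + x^b)` maps RIS (`x`) to the
#' predicted percent decrease in victim-drug AUC: `a` is the maximum AUC
#' change (%), `b` the slope, `c` the RIS achieving half the maximum AUC
#' change.
#'
#' @param a Maximum AUC change (%), positive.
#' @param b_slope Hill slope, positive.
#' @param c_half RIS at half-maximal AUC change, positive.
#' @param r_squared Optional fit R-squared.
#' @param lot,endpoint Optional provenance labels.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(a, b_slope, c_half, r_squared = NA_real_,
                              lot = NA_character_, endpoint = NA_character_) {
  stopifnot(a > 0, b_slope > 0, c_half > 0)
  structure(
    list(a = a, b_slope = b_slope, c_half = c_half, r_squared = r_squared,
         lot = lot, endpoint = endpoint),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Hill-3 RIS calibration (%s/%s): a = %.3g%%, b = %.3g, c = %.4g, R2 = %.3f\n",
    x$lot, x$endpoint, x$a, x$b_slope, x$c_half, x$r_squared))
  invisible(x)
}

#' Fit the RIS calibration curve
#'
#' Least-squares fit of the Hill 3-parameter function to (RIS, observed %
#' midazolam AUC change) pairs for the calibration compounds. Multi-start
#' nonlinear least squares on the untransformed pairs: `a` starts at the
#' maximum observed AUC change, `c` at the median RIS, slope at 1/2/4, with
#' bounds `a` in (20, 120], `b` in (0.1, 10], `c > 0`.
#'
#' @param ris Numeric vector of RIS values (calibration compounds).
#' @param observed_auc Numeric vector of observed percent midazolam AUC
#'   changes, same length.
#' @param lot,endpoint Optional provenance labels stored on the model.
#' @return A [calibration_model()] with `r_squared` filled in.
#' @examples
#' ris <- c(19.1, 7.5, 0.76, 0.28, 0.13, 0.10)
#' obs <- c(97, 94, 94, 26, 25, 4)
#' fit_calibration(ris, obs, lot = "2B", endpoint = "mRNA")
#' @export
fit_calibration <- function(ris, observed_auc, lot = NA_character_,
                            endpoint = NA_character_) {
  if (length(ris) != length(observed_auc)) {
    stop("fit_calibration: 'ris' and 'observed_auc' lengths differ",
         call. = FALSE)
  }
  if (length(ris) < 4) {
    stop("fit_calibration: need at least 4 calibration points (got ",
         length(ris), ")", call. = FALSE)
  }
  if (any(!is.finite(ris)) || any(!is.finite(observed_auc))) {
    stop("fit_calibration: inputs must be finite", call. = FALSE)
  }
  dat <- data.frame(x = ris, y = observed_auc)
  best <- NULL
  for (b0 in c(1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * x^b / (c^b + x^b), data = dat,
        start = list(a = min(max(max(dat$y), 25), 120), b = b0,
                     c = max(median(dat$x), 1e-6)),
        lower = c(a = 20 + 1e-6, b = 0.1, c = 1e-12),
        upper = c(a = 120, b = 10, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(resid(fit)^2)
      if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
    }
  }
  if (is.null(best)) {
    stop("fit_calibration: nonlinear least squares failed to converge from ",
         "any start", call. = FALSE)
  }
  p <- coef(best$fit)
  calibration_model(
    a = unname(p["a"]), b_slope = unname(p["b"]), c_half = unname(p["c"]),
    r_squared = r_squared(dat$y, stats::fitted(best$fit)),
    lot = lot, endpoint = endpoint
  )
}

#' Predict percent AUC change from RIS
#'
#' Evaluates the calibration curve `a * ris^b / (c^b + ris^b)`. A RIS of 0 —
#' including compounds with no induction response, conventionally given
#' `NA` RIS — predicts a 0% AUC change.
#'
#' @param model A [calibration_model()].
#' @param ris RIS value(s), non-negative; `NA` is treated as no induction.
#' @return Predicted percent AUC change, vectorized over `ris`.
#' @export
predict_auc_change <- function(model, ris) {
  stopifnot(inherits(model, "calibration_model"))
  ris <- ifelse(is.na(ris), 0, ris)
  if (any(ris < 0)) {
    stop("predict_auc_change: 'ris' must be non-negative", call. = FALSE)
  }
  ifelse(ris == 0, 0,
         model$a * ris^model$b_slope /
           (model$c_half^model$b_slope + ris^model$b_slope))
}

#' RIS cutoff at a given AUC-change threshold
#'
#' Inverts the calibration curve in closed form at a predicted AUC change
#' `t`: `x = c * (t / (a - t))^(1/b)`. With the default 20% threshold this
#' is the boundary above which a compound is flagged as a clinically
#' relevant inducer.
#'
#' @param model A [calibration_model()].
#' @param auc_threshold Percent AUC change to invert at (default 20).
#' @return The RIS cutoff (dimensionless).
#' @examples
#' m <- calibration_model(a = 98, b_slope = 2, c_half = 0.4)
#' ris_cutoff(m)  # 0.2026
#' @export
ris_cutoff <- function(model, auc_threshold = 20) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$a <= auc_threshold) {
    stop("ris_cutoff: calibration maximum (a = ", signif(model$a, 3),
         "%) never reaches the ", auc_threshold, "% threshold",
         call. = FALSE)
  }
  model$c_half * (auc_threshold / (model$a - auc_threshold))^(1 / model$b_slope)
}

#' Cross-lot RIS cutoff summary
#'
#' Inverts each lot's calibration model at the threshold and reports the
#' per-lot cutoffs with their mean and percent CV.
#'
#' @param models A list of [calibration_model()]s (one per lot).
#' @param auc_threshold Percent AUC change (default 20).
#' @return A list with `per_lot` (tibble: `lot`, `endpoint`, `cutoff`),
#'   `mean`, and `cv_pct`.
#' @export
ris_cutoff_summary <- function(models, auc_threshold = 20) {
  cutoffs <- vapply(models, ris_cutoff, numeric(1),
                    auc_threshold = auc_threshold)
  per_lot <- tibble::tibble(
    lot = vapply(models, function(m) m$lot, character(1)),
    endpoint = vapply(models, function(m) m$endpoint, character(1)),
    cutoff = cutoffs
  )
  list(per_lot = per_lot, mean = mean(cutoffs),
       cv_pct = 100 * sd(cutoffs) / mean(cutoffs))
}
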