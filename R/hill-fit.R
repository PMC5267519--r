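#' Sigmoidal Hill 4-parameter induction response
#'
#' `y = Emin + (Emax - Emin) / (1 + (EC50/x)^b)`: the induction response
#' (fold increase) at concentration `x`, with background `Emin`, maximum
#' response `Emax`, half-maximal concentration `EC50` (uM), and slope `b`.
#'
#' @param x Concentration(s), uM, strictly positive.
#' @param e_min Background response (fold increase).
#' @param e_max Maximum response (fold increase).
#' @param ec50 Concentration at half-maximal response (uM, positive).
#' @param slope Hill slope.
#' @return Fold increase, vectorized over `x`.
#' @examples
#' hill4(0.36, e_min = 0, e_max = 22, ec50 = 0.36, slope = 1)  # 11
#' @export
hill4 <- function(x, e_min, e_max, ec50, slope) {
  stopifnot(all(x > 0), ec50 > 0)
  e_min + (e_max - e_min) / (1 + (ec50 / x)^slope)
}

# r-squared as coefficient of determination
r_squared <- function(observed, fitted_vals) {
  ss_res <- sum((observed - fitted_vals)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

# one nlsLM attempt for the Hill-4 model on log10-concentration scale;
# the (EC50/x)^b term becomes 10^(b * (lec50 - log10(x)))
hill4_nls <- function(lx, y, start, lower, upper, fixed_e_max = NULL) {
  if (is.null(fixed_e_max)) {
    form <- y ~ e_min + (e_max - e_min) / (1 + 10^(slope * (lec50 - lx)))
  } else {
    e_max <- fixed_e_max
    form <- y ~ e_min + (e_max - e_min) / (1 + 10^(slope * (lec50 - lx)))
  }
  tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(lx = lx, y = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL
  )
}

# multi-start nonlinear least squares for the Hill-4 curve
fit_hill4_nls <- function(conc, y, fixed_e_max = NULL) {
  lx <- log10(conc)
  obs_max <- max(y)
  lec50_starts <- log10(c(
    exp(mean(log(conc))),
    quantile(conc, 0.25, names = FALSE),
    quantile(conc, 0.75, names = FALSE)
  ))
  lec50_bounds <- c(log10(min(conc) / 100), log10(max(conc) * 100))
  best <- NULL
  for (b0 in c(0.5, 1, 2, 4)) {
    for (l0 in lec50_starts) {
      if (is.null(fixed_e_max)) {
        start <- list(e_min = 0, e_max = obs_max, lec50 = l0, slope = b0)
        lower <- c(e_min = 0, e_max = 1e-8, lec50 = lec50_bounds[1],
                   slope = 0.1)
        upper <- c(e_min = max(obs_max, 1e-6), e_max = 5 * max(obs_max, 1e-6),
                   lec50 = lec50_bounds[2], slope = 10)
      } else {
        start <- list(e_min = 0, lec50 = l0, slope = b0)
        lower <- c(e_min = 0, lec50 = lec50_bounds[1], slope = 0.1)
        upper <- c(e_min = max(obs_max, 1e-6), lec50 = lec50_bounds[2],
                   slope = 10)
      }
      fit <- hill4_nls(lx, y, start, lower, upper, fixed_e_max)
      if (!is.null(fit)) {
        ss <- sum(resid(fit)^2)
        if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
        # an essentially perfect fit cannot be improved; skip remaining starts
        if (r_squared(y, stats::fitted(fit)) > 0.9999) return(best)
      }
    }
  }
  best
}

#' Fit the Hill 4-parameter induction curve
#'
#' Nonlinear least squares on the fold-increase scale with multi-start
#' initialization (slope in 0.5/1/2/4; EC50 at the geometric mean and
#' quartiles of the tested range; Emax at the observed maximum; Emin at 0)
#' and box constraints (Emin in \[0, observed max\], Emax up to 5x the
#' observed max, slope in (0.1, 10\], EC50 within two orders of magnitude of
#' the tested range). Fitting is done on log10-concentration, which is
#' equivalent to the natural parametrization but much better conditioned.
#'
#' After the fit, a plateau check decides how Emax is reported: a plateau
#' exists when fitted Emax is at most `plateau_emax_ratio` times the
#' observed maximum fold increase *and* the fitted response at the top
#' tested concentration reaches at least `plateau_top_fraction` of fitted
#' Emax. When there is no plateau, extrapolation beyond the data is avoided:
#' the observed maximum fold increase is taken as Emax and EC50 is
#' re-derived by refitting the curve with Emax fixed at that value
#' (`method = "observed_max_fallback"`).
#'
#' The fit is accepted only when its coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` exceeds `r2_min` (default 0.85).
#'
#' @param points A QC-applied tibble from [apply_replicate_qc()]; only
#'   accepted points are used.
#' @param r2_min Minimum accepted R-squared.
#' @param plateau_emax_ratio,plateau_top_fraction Plateau criterion
#'   constants (see [pipeline_config()]).
#' @return An object of class `induction_curve_fit`: a list with `e_min`,
#'   `e_max`, `ec50`, `slope`, `r_squared`, `method` (`"full_fit"` or
#'   `"observed_max_fallback"`), `n_points_used`, `accepted`, and the
#'   per-point `residuals`.
#' @examples
#' conc <- 10^seq(log10(0.01), log10(50), length.out = 8)
#' pts <- fold_increase_points(
#'   data.frame(concentration_um = rep(conc, each = 3),
#'              value = rep(100 * (1 + hill4(conc, 0, 22, 0.36, 1)), each = 3)),
#'   vehicle = c(100, 100, 100))
#' fit <- fit_hill4(apply_replicate_qc(pts))
#' c(fit$e_max, fit$ec50)
#' @export
fit_hill4 <- function(points, r2_min = 0.85,
                      plateau_emax_ratio = 1.2,
                      plateau_top_fraction = 0.9) {
  pts <- points[points$accepted %in% TRUE, ]
  if (nrow(pts) < 4) {
    stop("fit_hill4: need at least 4 accepted points (got ", nrow(pts), ")",
         call. = FALSE)
  }
  conc <- pts$concentration_um
  y <- pts$fold_increase
  if (diff(range(y)) < sqrt(.Machine$double.eps)) {
    stop("fit_hill4: degenerate response (all fold increases equal)",
         call. = FALSE)
  }
  best <- fit_hill4_nls(conc, y)
  if (is.null(best)) {
    stop("fit_hill4: nonlinear least squares failed to converge from any ",
         "start (", length(conc), " points, concentrations ",
         signif(min(conc), 3), "-", signif(max(conc), 3), " uM)",
         call. = FALSE)
  }
  p <- coef(best$fit)
  obs_max <- max(y)
  method <- "full_fit"
  pred_top <- hill4(max(conc), p["e_min"], p["e_max"], 10^p["lec50"],
                    p["slope"])
  plateau <- p["e_max"] <= plateau_emax_ratio * obs_max &&
    pred_top >= plateau_top_fraction * p["e_max"]
  if (!plateau) {
    refit <- fit_hill4_nls(conc, y, fixed_e_max = obs_max)
    if (!is.null(refit)) {
      method <- "observed_max_fallback"
      best <- refit
      p <- coef(best$fit)
      p <- c(p[1], e_max = unname(obs_max), p[2:3])
    }
  }
  fitted_vals <- stats::fitted(best$fit)
  r2 <- r_squared(y, fitted_vals)
  structure(
    list(
      e_min = unname(p["e_min"]),
      e_max = unname(p["e_max"]),
      ec50 = unname(10^p["lec50"]),
      slope = unname(p["slope"]),
      r_squared = r2,
      method = method,
      n_points_used = nrow(pts),
      accepted = r2 > r2_min,
      residuals = unname(y - fitted_vals)
    ),
    class = "induction_curve_fit"
  )
}

#' @export
print.induction_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Hill-4 induction fit (%s): Emax = %.3g, EC50 = %.3g uM, slope = %.3g, R2 = %.3f%s\n",
    x$method, x$e_max, x$ec50, x$slope, x$r_squared,
    if (x$accepted) "" else " [rejected]"))
  invisible(x)
}

#' Summarize induction-curve fits across compounds and lots
#'
#' Builds a reference-style fit table: one row per compound x lot x
#' endpoint. Compounds with no induction response are marked `status =
#' "NI"`; fit-eligible responders carry their `r_squared`, `e_max`, and
#' `ec50_um`; responders without a concentration-dependent pattern are
#' marked `status = "NA"` with only the observed maximum fold induction
#' reported.
#'
#' @param fits A list of entries, each a list with `compound`, `lot`,
#'   `endpoint`, and either `fit` (an `induction_curve_fit`) or `status`
#'   (`"NI"` or `"NA"`) plus optionally `max_fold_induction`.
#' @return A tibble with columns `compound`, `lot`, `endpoint`, `status`,
#'   `r_squared`, `e_max`, `ec50_um`, `slope`, `method`,
#'   `max_fold_induction`.
#' @export
collect_fit_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (!is.null(f$fit)) {
      tibble::tibble(
        compound = f$compound, lot = f$lot, endpoint = f$endpoint,
        status = if (f$fit$accepted) "fit" else "rejected",
        r_squared = f$fit$r_squared, e_max = f$fit$e_max,
        ec50_um = f$fit$ec50, slope = f$fit$slope, method = f$fit$method,
        max_fold_induction = f$max_fold_induction %||% NA_real_
      )
    } else {
      tibble::tibble(
        compound = f$compound, lot = f$lot, endpoint = f$endpoint,
        status = f$status, r_squared = NA_real_, e_max = NA_real_,
        ec50_um = NA_real_, slope = NA_real_, method = NA_character_,
        max_fold_induction = f$max_fold_induction %||% NA_real_
      )
    }
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
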