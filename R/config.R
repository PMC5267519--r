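#' Pipeline configuration
#'
#' Collects every tunable threshold of the RIS workflow in one place, with
#' defaults equal to the values used throughout the package:
#'
#' * `cv_threshold` — replicate coefficient of variation above which a
#'   concentration point is excluded from curve fitting (fraction, default
#'   0.40: points are accepted only when the replicate CV is below 40%);
#' * `r2_min` — minimum coefficient of determination for an induction curve
#'   fit to be accepted (default 0.85);
#' * `min_max_response` — minimum observed maximum fold induction for a
#'   series to be eligible for Emax/EC50 estimation (default 1.4);
#' * `positive_threshold` — fold-induction level that, reached on both
#'   endpoints with a concentration-dependent pattern, classifies a compound
#'   as a positive inducer (default 2.0);
#' * `auc_cutoff_pct` — predicted percent AUC change defining the RIS cutoff
#'   for a clinically relevant inducer (default 20);
#' * `plateau_emax_ratio`, `plateau_top_fraction` — plateau criterion for the
#'   Hill-4 fit: a plateau exists when fitted Emax is at most
#'   `plateau_emax_ratio` times the observed maximum fold increase and the
#'   fitted response at the top tested concentration reaches at least
#'   `plateau_top_fraction` of fitted Emax (defaults 1.2 and 0.9); otherwise
#'   the observed maximum fold increase is taken as Emax;
#' * `nonmidazolam_exclude` — compounds dropped from the nonmidazolam
#'   accuracy stratum (default `"Clotrimazole"`, which lacks an
#'   activity-based RIS);
#' * `seed` — integer seed used for any stochastic step.
#'
#' @param cv_threshold Replicate CV acceptance threshold (fraction in (0, 1)).
#' @param r2_min Minimum accepted R-squared for curve fits.
#' @param min_max_response Fold-induction floor for fit eligibility.
#' @param positive_threshold Fold-induction threshold for positive induction.
#' @param auc_cutoff_pct Percent AUC change at which the RIS cutoff is taken.
#' @param plateau_emax_ratio Plateau test: max fitted-Emax / observed-max ratio.
#' @param plateau_top_fraction Plateau test: minimum fitted response at the top
#'   concentration as a fraction of fitted Emax.
#' @param nonmidazolam_exclude Character vector of compounds excluded from the
#'   nonmidazolam accuracy stratum.
#' @param seed Optional integer seed.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$cv_threshold
#' @export
pipeline_config <- function(cv_threshold = 0.40,
                            r2_min = 0.85,
                            min_max_response = 1.4,
                            positive_threshold = 2.0,
                            auc_cutoff_pct = 20,
                            plateau_emax_ratio = 1.2,
                            plateau_top_fraction = 0.9,
                            nonmidazolam_exclude = "Clotrimazole",
                            seed = NULL) {
  cfg <- list(
    cv_threshold = cv_threshold,
    r2_min = r2_min,
    min_max_response = min_max_response,
    positive_threshold = positive_threshold,
    auc_cutoff_pct = auc_cutoff_pct,
    plateau_emax_ratio = plateau_emax_ratio,
    plateau_top_fraction = plateau_top_fraction,
    nonmidazolam_exclude = nonmidazolam_exclude,
    seed = seed
  )
  for (fld in c("cv_threshold", "r2_min", "min_max_response",
                "positive_threshold", "auc_cutoff_pct",
                "plateau_emax_ratio", "plateau_top_fraction")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("pipeline_config: '", fld, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$cv_threshold >= 1) {
    stop("pipeline_config: 'cv_threshold' must be below 1", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("RIS pipeline configuration\n")
  for (nm in setdiff(names(x), "seed")) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %-22s %s\n", "seed",
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}
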