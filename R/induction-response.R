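#' Fold induction from enzyme-activity replicates
#'
#' Normalizes treated-well enzyme activity to the solvent-vehicle control:
#' the ratio of the treated replicate mean to the vehicle replicate mean.
#'
#' @param treated Numeric vector of treated-well raw values.
#' @param vehicle Numeric vector of vehicle-control raw values.
#' @return Fold induction (dimensionless ratio).
#' @examples
#' fold_induction_activity(c(9, 10, 11), c(4, 5, 6))  # 2
#' @export
fold_induction_activity <- function(treated, vehicle) {
  if (length(vehicle) == 0 || !all(is.finite(vehicle)) ||
      mean(vehicle) <= 0) {
    stop("fold_induction_activity: vehicle mean must be positive",
         call. = FALSE)
  }
  mean(treated) / mean(vehicle)
}

#' Fold induction from qPCR delta-delta-Ct
#'
#' Relative mRNA quantification: fold change versus vehicle control is
#' `2^(-ddct)`.
#'
#' @param ddct Delta-delta-Ct value(s).
#' @return Fold induction, vectorized over `ddct`.
#' @examples
#' fold_induction_mrna(-3)  # 8
#' @export
fold_induction_mrna <- function(ddct) {
  if (any(!is.finite(ddct))) {
    stop("fold_induction_mrna: 'ddct' must be finite", call. = FALSE)
  }
  2^(-ddct)
}

# sample CV (n-1 denominator) of raw replicate values
replicate_cv <- function(values) {
  m <- mean(values)
  if (m == 0) return(Inf)
  sd(values) / m
}

#' Build fold-increase points from a replicate series
#'
#' Collapses raw replicate wells for one compound/lot/endpoint into one
#' fold-increase point per concentration: fold induction is the treated
#' replicate mean over the vehicle replicate mean, fold increase is fold
#' induction minus 1, and the replicate CV (sample SD over mean of the raw
#' replicate values) is carried for QC. Points listed in `exclusions`
#' (toxicity or insolubility, known from the experiment) are pre-flagged.
#'
#' @param points A data frame with columns `concentration_um`, `value`, and
#'   optionally `replicate`; one row per well.
#' @param vehicle Numeric vector of vehicle-control raw values.
#' @param exclusions Optional data frame with columns `concentration_um` and
#'   `reason` (`"toxicity"` or `"insolubility"`).
#' @return A tibble with one row per concentration: `concentration_um`,
#'   `fold_induction`, `fold_increase`, `replicate_cv`, `n_replicates`,
#'   `accepted` (all `NA` until [apply_replicate_qc()] runs),
#'   `exclusion_reason`.
#' @export
fold_increase_points <- function(points, vehicle, exclusions = NULL) {
  points <- tibble::as_tibble(points)
  if (any(points$concentration_um <= 0)) {
    stop("fold_increase_points: concentrations must be strictly positive",
         call. = FALSE)
  }
  out <- points |>
    dplyr::group_by(.data$concentration_um) |>
    dplyr::summarise(
      fold_induction = fold_induction_activity(.data$value, vehicle),
      replicate_cv = replicate_cv(.data$value),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$concentration_um)
  if (any(out$n_replicates < 2)) {
    stop("fold_increase_points: every concentration needs >= 2 replicates",
         call. = FALSE)
  }
  out$fold_increase <- out$fold_induction - 1
  out$accepted <- NA
  out$exclusion_reason <- "none"
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    idx <- match(out$concentration_um, exclusions$concentration_um)
    hit <- !is.na(idx)
    out$exclusion_reason[hit] <- exclusions$reason[idx[hit]]
  }
  dplyr::select(out, "concentration_um", "fold_induction", "fold_increase",
                "replicate_cv", "n_replicates", "accepted",
                "exclusion_reason")
}

#' Replicate-variability QC filter
#'
#' Accepts a concentration point for curve fitting only when its replicates
#' (two or more) show a coefficient of variation below `cv_threshold`;
#' points at or above the threshold are rejected with reason `"cv"`. Points
#' already flagged for toxicity or insolubility keep that reason and stay
#' rejected regardless of their CV.
#'
#' @param points A tibble from [fold_increase_points()].
#' @param cv_threshold CV acceptance threshold (fraction, default 0.40).
#' @return The same tibble with `accepted` and `exclusion_reason` filled in.
#' @examples
#' pts <- fold_increase_points(
#'   data.frame(concentration_um = rep(c(1, 10), each = 3),
#'              value = c(10, 10, 10, 1, 2, 3)),
#'   vehicle = c(5, 5, 5))
#' apply_replicate_qc(pts)
#' @export
apply_replicate_qc <- function(points, cv_threshold = 0.40) {
  flagged <- points$exclusion_reason != "none"
  fails_cv <- points$replicate_cv >= cv_threshold
  points$exclusion_reason[!flagged & fails_cv] <- "cv"
  points$accepted <- !flagged & !fails_cv
  points
}

# concentration dependence: positive rank correlation between concentration
# and fold increase, >= 3 accepted points, maximum above the lowest tested
# concentration
is_concentration_dependent <- function(points) {
  pts <- points[points$accepted %in% TRUE, ]
  if (nrow(pts) < 3) return(FALSE)
  rho <- suppressWarnings(
    cor(pts$concentration_um, pts$fold_increase, method = "spearman"))
  if (!is.finite(rho) || rho <= 0) return(FALSE)
  pts$concentration_um[which.max(pts$fold_increase)] >
    min(pts$concentration_um)
}

#' Classify the induction response of a compound
#'
#' Applies the positivity and fit-eligibility rules per endpoint and
#' combines them. An endpoint is *positive* when its maximum fold induction
#' exceeds `positive_threshold` (default twofold) with a
#' concentration-dependent pattern; it is *fit-eligible* (suitable for
#' Emax/EC50 estimation) when concentration-dependent with maximum fold
#' induction above `min_max_response` (default 1.4-fold). The combined
#' verdict is `"positive"` when both endpoints are positive, `"negative"`
#' when both are negative, and `"indeterminate"` otherwise (e.g. an
#' mRNA-only response, as seen when potent enzyme inhibition masks the
#' activity signal).
#'
#' For classification, negative fold increases are floored at zero;
#' the raw values are untouched for fitting.
#'
#' @param endpoint_points Named list of QC-applied point tibbles, one per
#'   endpoint (names e.g. `c("activity", "mRNA")`).
#' @param positive_threshold Fold induction defining a positive response.
#' @param min_max_response Fold induction floor for fit eligibility.
#' @return A list with `per_endpoint` (tibble: `endpoint`, `verdict`,
#'   `fit_eligible`, `max_fold_induction`) and `combined` (one of
#'   `"positive"`, `"negative"`, `"indeterminate"`).
#' @export
classify_induction <- function(endpoint_points,
                               positive_threshold = 2.0,
                               min_max_response = 1.4) {
  stopifnot(is.list(endpoint_points), length(endpoint_points) >= 1)
  rows <- lapply(names(endpoint_points), function(ep) {
    pts <- endpoint_points[[ep]]
    acc <- pts[pts$accepted %in% TRUE, ]
    max_fi <- if (nrow(acc) == 0) NA_real_ else {
      max(pmax(acc$fold_induction, 0))
    }
    dep <- is_concentration_dependent(pts)
    verdict <- if (is.na(max_fi)) {
      "negative"
    } else if (dep && max_fi > positive_threshold) {
      "positive"
    } else {
      "negative"
    }
    tibble::tibble(
      endpoint = ep,
      verdict = verdict,
      fit_eligible = !is.na(max_fi) && dep && max_fi > min_max_response,
      max_fold_induction = max_fi
    )
  })
  per_endpoint <- dplyr::bind_rows(rows)
  combined <- if (all(per_endpoint$verdict == "positive")) {
    "positive"
  } else if (all(per_endpoint$verdict == "negative")) {
    "negative"
  } else {
    "indeterminate"
  }
  list(per_endpoint = per_endpoint, combined = combined)
}
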