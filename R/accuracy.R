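#' Root mean square error of AUC-change predictions
#'
#' `sqrt(mean((p_i - o_i)^2))` computed on the fractional AUC-change scale
#' (percent / 100), so that e.g. a single 20-percentage-point miss gives
#' 0.20.
#'
#' @param predicted,observed Percent AUC changes, equal length, n >= 1.
#' @return RMSE (fraction).
#' @examples
#' auc_rmse(30, 10)  # 0.2
#' @export
auc_rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("auc_rmse: input lengths differ", call. = FALSE)
  }
  if (length(predicted) == 0) {
    stop("auc_rmse: empty input", call. = FALSE)
  }
  sqrt(mean(((predicted - observed) / 100)^2))
}

#' Geometric mean fold error
#'
#' `10^(mean(|log10(p_i / o_i)|))`: a bias-insensitive fold-accuracy
#' measure, 1 for perfect prediction. Pairs where either value is
#' non-positive have no defined fold error; they are excluded and reported.
#'
#' @param predicted,observed Percent AUC changes, equal length.
#' @param return_exclusions If `TRUE`, return a list with `gmfe`,
#'   `n_used`, and `excluded` (tibble of dropped pairs with reasons);
#'   otherwise just the GMFE.
#' @return GMFE (dimensionless, >= 1), or the list described above.
#' @examples
#' gmfe(c(20, 50), c(10, 50))  # sqrt(2) x ... = 10^(mean(|log10|)) = 1.414
#' @export
gmfe <- function(predicted, observed, return_exclusions = FALSE) {
  if (length(predicted) != length(observed)) {
    stop("gmfe: input lengths differ", call. = FALSE)
  }
  ok <- predicted > 0 & observed > 0 & is.finite(predicted) &
    is.finite(observed)
  bad_pred <- predicted[!ok]
  excluded <- tibble::tibble(
    index = which(!ok),
    predicted = bad_pred,
    observed = observed[!ok],
    reason = ifelse(!is.finite(bad_pred) | bad_pred <= 0,
                    "nonpositive_predicted", "nonpositive_observed")
  )
  if (sum(ok) == 0) {
    stop("gmfe: no pairs with positive predicted and observed values (",
         nrow(excluded), " excluded)", call. = FALSE)
  }
  g <- 10^(mean(abs(log10(predicted[ok] / observed[ok]))))
  if (return_exclusions) {
    list(gmfe = g, n_used = sum(ok), excluded = excluded)
  } else {
    g
  }
}

#' Accuracy report stratified by victim-substrate class
#'
#' RMSE and GMFE for each lot x endpoint, over all evaluable compounds and
#' within the midazolam and nonmidazolam strata. The midazolam stratum is
#' the set of compounds whose observed AUC change comes from a
#' midazolam-probe clinical study (the calibration compounds); the
#' nonmidazolam stratum holds the remaining inducers, minus any compounds in
#' `exclude` (by default clotrimazole, which lacks an activity-based RIS).
#' GMFE exclusions (non-positive predicted or observed values) are recorded
#' per stratum.
#'
#' @param predictions A data frame with columns `compound`, `lot`,
#'   `endpoint`, `predicted_auc_pct`.
#' @param compounds A data frame with columns `compound`,
#'   `observed_auc_pct`, `substrate_class` (`"midazolam"` /
#'   `"nonmidazolam"`).
#' @param exclude Compounds dropped from the nonmidazolam stratum.
#' @return A list with `report` (tibble: `lot`, `endpoint`, `subset`,
#'   `rmse`, `gmfe`, `n_compounds`) and `gmfe_exclusions` (tibble of
#'   dropped pairs).
#' @export
stratified_report <- function(predictions, compounds,
                              exclude = "Clotrimazole") {
  predictions <- tibble::as_tibble(predictions)
  compounds <- tibble::as_tibble(compounds)
  dat <- dplyr::inner_join(
    predictions,
    dplyr::select(compounds, "compound", "observed_auc_pct",
                  "substrate_class"),
    by = "compound"
  )
  combos <- dplyr::distinct(dat, .data$lot, .data$endpoint)
  rows <- list()
  exclusions <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- dat[dat$lot == combos$lot[i] & dat$endpoint == combos$endpoint[i], ]
    strata <- list(
      all = sub,
      midazolam = sub[sub$substrate_class == "midazolam", ],
      nonmidazolam = sub[sub$substrate_class == "nonmidazolam" &
                           !(sub$compound %in% exclude), ]
    )
    for (nm in names(strata)) {
      s <- strata[[nm]]
      if (nrow(s) == 0) next
      g <- tryCatch(
        gmfe(s$predicted_auc_pct, s$observed_auc_pct,
             return_exclusions = TRUE),
        error = function(e) list(gmfe = NA_real_, n_used = 0L,
                                 excluded = tibble::tibble())
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lot = combos$lot[i], endpoint = combos$endpoint[i], subset = nm,
        rmse = auc_rmse(s$predicted_auc_pct, s$observed_auc_pct),
        gmfe = g$gmfe, n_compounds = nrow(s)
      )
      if (nrow(g$excluded) > 0) {
        ex <- g$excluded
        ex$compound <- s$compound[ex$index]
        ex$lot <- combos$lot[i]
        ex$endpoint <- combos$endpoint[i]
        ex$subset <- nm
        exclusions[[length(exclusions) + 1L]] <-
          dplyr::select(ex, "lot", "endpoint", "subset", "compound",
                        "predicted", "observed", "reason")
      }
    }
  }
  list(report = dplyr::bind_rows(rows),
       gmfe_exclusions = if (length(exclusions)) dplyr::bind_rows(exclusions)
                         else tibble::tibble())
}
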