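#' Run the full RIS prediction pipeline
#'
#' Composes the analysis stages end to end: replicate wells to QC-filtered
#' fold-increase points, induction classification, Hill-4 curve fitting,
#' RIS computation, per-lot Hill-3 calibration against observed midazolam
#' AUC changes, AUC-change prediction for every compound, RIS cutoffs at the
#' configured threshold, and the stratified accuracy report. The run is
#' deterministic given inputs, config, and seed.
#'
#' @param wells Well-level data: a tibble with columns `compound`, `lot`,
#'   `endpoint`, `concentration_um`, `replicate`, `value`, `is_vehicle`
#'   (and optionally `is_toxic_truth`), or a path to such a CSV, or a
#'   `synthetic_panel`.
#' @param compounds Compound metadata: a tibble (or CSV path) with columns
#'   `compound`, `cmax_ub_um`, `observed_auc_pct`, `substrate_class`,
#'   `in_calibration_set`.
#' @param config A [pipeline_config()].
#' @param exclusions Optional data frame of known exclusions (`compound`,
#'   `lot`, `endpoint`, `concentration_um`, `reason`).
#' @param use_toxicity_flags When `TRUE` (default), wells flagged
#'   `is_toxic_truth` are turned into toxicity exclusions.
#'
#' @return A list with `fit_table`, `classifications`, `ris_values`,
#'   `ris_summary`, `calibrations` (list of [calibration_model()]s keyed
#'   `lot/endpoint`), `predictions`, `cutoffs`, `accuracy`, and `manifest`.
#' @export
run_pipeline <- function(wells, compounds, config = pipeline_config(),
                         exclusions = NULL, use_toxicity_flags = TRUE) {
  if (inherits(wells, "synthetic_panel")) wells <- wells$wells
  if (is.character(wells)) wells <- read_panel_csv(wells)
  wells <- tibble::as_tibble(wells)
  if (nrow(wells) == 0) {
    stop("run_pipeline: empty panel", call. = FALSE)
  }
  if (is.character(compounds)) {
    compounds <- readr::read_csv(compounds, show_col_types = FALSE)
  }
  compounds <- tibble::as_tibble(compounds)
  if (!is.null(config$seed)) set.seed(config$seed)

  if (use_toxicity_flags && "is_toxic_truth" %in% names(wells)) {
    tox <- wells |>
      dplyr::filter(.data$is_toxic_truth) |>
      dplyr::distinct(.data$compound, .data$lot, .data$endpoint,
                      .data$concentration_um) |>
      dplyr::mutate(reason = "toxicity")
    exclusions <- dplyr::bind_rows(exclusions, tox)
  }

  combos <- wells |>
    dplyr::filter(!.data$is_vehicle) |>
    dplyr::distinct(.data$compound, .data$lot, .data$endpoint)
  fits <- list()
  class_rows <- list()
  qc_points <- list()
  for (i in seq_len(nrow(combos))) {
    cmp <- combos$compound[i]; lot <- combos$lot[i]; ep <- combos$endpoint[i]
    sub <- wells[wells$compound == cmp & wells$lot == lot &
                   wells$endpoint == ep, ]
    vehicle <- sub$value[sub$is_vehicle]
    treated <- sub[!sub$is_vehicle, ]
    excl <- NULL
    if (!is.null(exclusions) && nrow(exclusions) > 0) {
      excl <- exclusions[exclusions$compound == cmp &
                           exclusions$lot == lot &
                           exclusions$endpoint == ep,
                         c("concentration_um", "reason")]
    }
    pts <- fold_increase_points(treated, vehicle, exclusions = excl)
    pts <- apply_replicate_qc(pts, cv_threshold = config$cv_threshold)
    qc_points[[paste(cmp, lot, ep, sep = "/")]] <- pts
  }

  for (i in seq_len(nrow(combos))) {
    cmp <- combos$compound[i]; lot <- combos$lot[i]; ep <- combos$endpoint[i]
    pts <- qc_points[[paste(cmp, lot, ep, sep = "/")]]
    cls <- classify_induction(
      setNames(list(pts), ep),
      positive_threshold = config$positive_threshold,
      min_max_response = config$min_max_response
    )$per_endpoint
    cls$compound <- cmp
    cls$lot <- lot
    class_rows[[length(class_rows) + 1L]] <- cls
    entry <- list(compound = cmp, lot = lot, endpoint = ep,
                  max_fold_induction = cls$max_fold_induction[1])
    if (cls$fit_eligible[1]) {
      fit <- tryCatch(
        fit_hill4(pts, r2_min = config$r2_min,
                  plateau_emax_ratio = config$plateau_emax_ratio,
                  plateau_top_fraction = config$plateau_top_fraction),
        error = function(e) NULL)
      if (is.null(fit)) {
        entry$status <- "NA"
      } else {
        entry$fit <- fit
      }
    } else if (is.na(cls$max_fold_induction[1]) ||
               cls$max_fold_induction[1] <= config$min_max_response) {
      entry$status <- "NI"
    } else {
      entry$status <- "NA"
    }
    fits[[length(fits) + 1L]] <- entry
  }
  fit_table <- collect_fit_table(fits)
  classifications <- dplyr::bind_rows(class_rows)

  ris_values <- fit_table |>
    dplyr::left_join(
      dplyr::select(compounds, "compound", "cmax_ub_um"),
      by = "compound"
    ) |>
    dplyr::mutate(
      ris = ifelse(.data$status == "fit" & !is.na(.data$cmax_ub_um),
                   .data$e_max * .data$cmax_ub_um /
                     (.data$ec50_um + .data$cmax_ub_um),
                   NA_real_)
    ) |>
    dplyr::select("compound", "lot", "endpoint", "ris")

  ris_summary <- tryCatch(summarize_ris(ris_values), error = function(e) NULL)

  cal_set <- compounds$compound[compounds$in_calibration_set]
  cal_combos <- ris_values |>
    dplyr::filter(.data$compound %in% cal_set, !is.na(.data$ris)) |>
    dplyr::distinct(.data$lot, .data$endpoint)
  calibrations <- list()
  for (i in seq_len(nrow(cal_combos))) {
    lot <- cal_combos$lot[i]; ep <- cal_combos$endpoint[i]
    pts <- ris_values |>
      dplyr::filter(.data$lot == !!lot, .data$endpoint == !!ep,
                    .data$compound %in% cal_set, !is.na(.data$ris)) |>
      dplyr::inner_join(
        dplyr::select(compounds, "compound", "observed_auc_pct"),
        by = "compound")
    if (nrow(pts) < 4) {
      stop("run_pipeline: fewer than 4 calibration compounds with an ",
           "accepted RIS for lot ", lot, ", endpoint ", ep, call. = FALSE)
    }
    calibrations[[paste(lot, ep, sep = "/")]] <-
      fit_calibration(pts$ris, pts$observed_auc_pct, lot = lot,
                      endpoint = ep)
  }
  if (length(calibrations) == 0) {
    stop("run_pipeline: no calibration model could be fitted; check that ",
         "calibration compounds carry 'cmax_ub_um' and accepted fits",
         call. = FALSE)
  }

  predictions <- ris_values |>
    dplyr::rowwise() |>
    dplyr::mutate(
      predicted_auc_pct = {
        key <- paste(.data$lot, .data$endpoint, sep = "/")
        if (key %in% names(calibrations)) {
          predict_auc_change(calibrations[[key]], .data$ris)
        } else {
          NA_real_
        }
      }
    ) |>
    dplyr::ungroup()

  cutoffs <- tibble::tibble(
    lot = vapply(calibrations, function(m) m$lot, character(1)),
    endpoint = vapply(calibrations, function(m) m$endpoint, character(1)),
    cutoff = unname(vapply(calibrations, ris_cutoff, numeric(1),
                           auc_threshold = config$auc_cutoff_pct))
  )

  accuracy <- NULL
  if (all(c("observed_auc_pct", "substrate_class") %in% names(compounds))) {
    accuracy <- stratified_report(
      dplyr::filter(predictions, !is.na(.data$predicted_auc_pct)),
      compounds, exclude = config$nonmidazolam_exclude)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("riscal")),
    config = unclass(config),
    n_wells = nrow(wells),
    n_compounds = length(unique(combos$compound)),
    lots = sort(unique(combos$lot)),
    endpoints = sort(unique(combos$endpoint)),
    input_hash = rlang::hash(list(wells, compounds))
  )

  list(fit_table = fit_table,
       classifications = classifications,
       ris_values = ris_values,
       ris_summary = ris_summary,
       calibrations = calibrations,
       predictions = predictions,
       cutoffs = cutoffs,
       accuracy = accuracy,
       manifest = manifest)
}

#' Reproduce the headline reference results from packaged tables
#'
#' Runs the desk-scale reproduction: cross-lot RIS summaries from the
#' packaged RIS table, per-lot Hill-3 calibration fits on the six
#' calibration compounds (mRNA endpoint), the lot-level and mean RIS
#' cutoffs at 20% AUC change, and the stratified accuracy metrics computed
#' from the packaged predicted/observed AUC table.
#'
#' @return A list with `ris_summary`, `calibrations`, `cutoffs`
#'   (per-lot tibble plus `mean`, `cv_pct`), and `accuracy`.
#' @export
reproduce_reference <- function() {
  ris <- load_fixtures("table3_ris")
  auc <- load_fixtures("table5_auc")
  meta <- load_fixtures("compounds")
  cal_set <- meta$compound[meta$in_calibration_set]

  models <- lapply(c("2B", "3A", "3B"), function(lot) {
    pts <- ris |>
      dplyr::filter(.data$endpoint == "mRNA", .data$lot == !!lot,
                    .data$compound %in% cal_set) |>
      dplyr::inner_join(
        dplyr::select(meta, "compound", "observed_auc_pct"),
        by = "compound")
    fit_calibration(pts$ris, pts$observed_auc_pct, lot = lot,
                    endpoint = "mRNA")
  })
  names(models) <- c("2B", "3A", "3B")
  cut <- ris_cutoff_summary(models, auc_threshold = 20)

  acc <- stratified_report(
    dplyr::select(auc, "compound", "lot", "endpoint", "predicted_auc_pct"),
    dplyr::select(meta, "compound", "observed_auc_pct", "substrate_class")
  )

  list(ris_summary = summarize_ris(ris),
       calibrations = models,
       cutoffs = cut,
       accuracy = acc)
}
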