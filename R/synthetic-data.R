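#' Specify a synthetic induction panel
#'
#' Describes a multi-lot hepatocyte induction experiment: a set of compounds,
#' each with a true Hill concentration-response (Emax as fold increase, EC50
#' in uM, slope, Emin fixed at 0), a log-spaced concentration grid, replicate
#' wells, and a multiplicative log-normal replicate noise level. The spec is
#' the ground truth that [generate_panel()] realizes and that downstream
#' recovery tests compare against.
#'
#' @param compounds A data frame with one row per compound and columns
#'   `compound`, `e_max` (true maximum fold increase), `ec50_um` (uM),
#'   `slope` (Hill coefficient), `conc_low_um`, `conc_high_um` (tested
#'   concentration range, uM), and optionally `cmax_ub_um` (unbound plasma
#'   Cmax, uM, used for RIS truth). See [default_panel_compounds()] for a
#'   realistic 13-compound panel.
#' @param n_lots Number of cell lots (default 3).
#' @param n_concentrations Concentrations per compound, log-spaced over
#'   `[conc_low_um, conc_high_um]` (default 8).
#' @param n_replicates Replicate wells per concentration (default 3; at
#'   least 2).
#' @param endpoints Endpoints to simulate, subset of
#'   `c("activity", "mRNA")`.
#' @param noise_cv Fractional replicate coefficient of variation of the
#'   multiplicative log-normal well noise (default 0.1; 0 gives noise-free
#'   wells).
#' @param toxicity_threshold Optional concentration (uM) above which the
#'   response collapses towards zero, mimicking overt cytotoxicity at the top
#'   of the tested range. `NA` (default) disables the toxic regime.
#' @param vehicle_mean Mean raw signal of vehicle-control wells (arbitrary
#'   units, default 100).
#' @param seed Integer seed making generation reproducible.
#'
#' @return An object of class `panel_spec`.
#' @seealso [generate_panel()], [generate_calibration_truth()]
#' @export
panel_spec <- function(compounds,
                       n_lots = 3,
                       n_concentrations = 8,
                       n_replicates = 3,
                       endpoints = c("activity", "mRNA"),
                       noise_cv = 0.1,
                       toxicity_threshold = NA_real_,
                       vehicle_mean = 100,
                       seed = 1L) {
  compounds <- tibble::as_tibble(compounds)
  required <- c("compound", "e_max", "ec50_um", "slope",
                "conc_low_um", "conc_high_um")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols) > 0) {
    stop("panel_spec: 'compounds' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("cmax_ub_um" %in% names(compounds))) {
    compounds$cmax_ub_um <- NA_real_
  }
  check_pos <- function(field, x, strict = TRUE) {
    bad <- !is.finite(x) | (if (strict) x <= 0 else x < 0)
    if (any(bad)) {
      stop("panel_spec: field '", field, "' must be ",
           if (strict) "positive" else "non-negative",
           " (offending compound: ",
           compounds$compound[which(bad)[1]], ")", call. = FALSE)
    }
  }
  check_pos("ec50_um", compounds$ec50_um)
  check_pos("e_max", compounds$e_max, strict = FALSE)
  check_pos("slope", compounds$slope)
  check_pos("conc_low_um", compounds$conc_low_um)
  check_pos("conc_high_um", compounds$conc_high_um)
  if (any(compounds$conc_high_um <= compounds$conc_low_um)) {
    stop("panel_spec: field 'conc_high_um' must exceed 'conc_low_um'",
         call. = FALSE)
  }
  scalars <- list(n_lots = n_lots, n_concentrations = n_concentrations,
                  n_replicates = n_replicates, vehicle_mean = vehicle_mean)
  for (fld in names(scalars)) {
    v <- scalars[[fld]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("panel_spec: field '", fld, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (n_replicates < 2) {
    stop("panel_spec: field 'n_replicates' must be at least 2", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || is.na(noise_cv) ||
      noise_cv < 0) {
    stop("panel_spec: field 'noise_cv' must be a single non-negative number",
         call. = FALSE)
  }
  endpoints <- match.arg(endpoints, c("activity", "mRNA"),
                         several.ok = TRUE)
  structure(
    list(compounds = compounds,
         n_lots = as.integer(n_lots),
         n_concentrations = as.integer(n_concentrations),
         n_replicates = as.integer(n_replicates),
         endpoints = endpoints,
         noise_cv = noise_cv,
         toxicity_threshold = as.numeric(toxicity_threshold),
         vehicle_mean = vehicle_mean,
         seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Realistic default compound panel
#'
#' A 13-compound panel whose true Hill parameters mirror the packaged
#' reference fit table (`load_fixtures("table2_fits")`, lot 2B): Emax (fold
#' increase) and EC50 (uM) from the fitted induction curves, the tested
#' concentration range per compound, and an unbound plasma Cmax back-derived
#' from each compound's reference RIS (so the panel's RIS truth matches the
#' reference RIS values). Slopes default to 1, a typical Hill coefficient for
#' PXR-mediated induction.
#'
#' @return A tibble suitable as the `compounds` argument of [panel_spec()].
#' @export
default_panel_compounds <- function() {
  fits <- load_fixtures("table2_fits")
  ris <- load_fixtures("table3_ris")
  fits <- dplyr::filter(fits, .data$lot == "2B", .data$status == "fit")
  ris <- dplyr::filter(ris, .data$lot == "2B", .data$endpoint == "mRNA",
                       !is.na(.data$ris))
  out <- dplyr::inner_join(
    dplyr::select(fits, "compound", "conc_low_um", "conc_high_um",
                  e_max = "e_max", ec50_um = "ec50_um"),
    dplyr::select(ris, "compound", "ris"),
    by = "compound"
  )
  out$slope <- 1
  # invert RIS = Emax*C/(EC50 + C) for the Cmax,ub that reproduces it
  out$cmax_ub_um <- out$ec50_um * out$ris / (out$e_max - out$ris)
  dplyr::select(out, "compound", "e_max", "ec50_um", "slope",
                "conc_low_um", "conc_high_um", "cmax_ub_um")
}

# log-normal noise factors with unit mean and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Generate a synthetic induction panel
#'
#' Realizes a [panel_spec()] as tidy well-level data. Each treated well is
#' `vehicle_mean * (1 + hill4(conc; truth)) * noise`, where `noise` is
#' multiplicative log-normal with unit mean and coefficient of variation
#' `noise_cv`; vehicle-control wells are `vehicle_mean * noise` under the
#' same noise model, so fold induction computed against the vehicle mean is
#' centred on the true Hill curve plus one. Wells above
#' `toxicity_threshold` are drawn from a collapsed-response regime (signal
#' near zero) and flagged `is_toxic_truth` so exclusion behaviour can be
#' tested. Generation is reproducible: the same spec and seed give
#' bit-identical panels.
#'
#' @param spec A [panel_spec()].
#' @param cal Optional [calibration_model()]; when supplied, per-compound
#'   true observed AUC changes are attached via
#'   [generate_calibration_truth()].
#'
#' @return An object of class `synthetic_panel`: a list with `wells` (tibble
#'   with columns `compound`, `lot`, `endpoint`, `concentration_um`,
#'   `replicate`, `value`, `is_vehicle`, `is_toxic_truth`), `spec` (the
#'   truth), and `observed_auc_change` (tibble, or `NULL` when `cal` is
#'   absent).
#' @examples
#' cmp <- tibble::tibble(compound = "rifampicin", e_max = 22, ec50_um = 0.36,
#'                       slope = 1, conc_low_um = 0.01, conc_high_um = 50)
#' panel <- generate_panel(panel_spec(cmp, n_lots = 1, noise_cv = 0, seed = 7))
#' head(panel$wells)
#' @export
generate_panel <- function(spec, cal = NULL) {
  if (!inherits(spec, "panel_spec")) {
    stop("generate_panel: 'spec' must be a panel_spec object", call. = FALSE)
  }
  set.seed(spec$seed)
  lots <- paste0("lot", seq_len(spec$n_lots))
  grid <- tidyr::expand_grid(
    compound = spec$compounds$compound,
    lot = lots,
    endpoint = spec$endpoints
  )
  truth <- spec$compounds
  well_tabs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cmp <- truth[truth$compound == grid$compound[i], ]
    concs <- 10^seq(log10(cmp$conc_low_um), log10(cmp$conc_high_um),
                    length.out = spec$n_concentrations)
    toxic <- !is.na(spec$toxicity_threshold) &
      concs > spec$toxicity_threshold
    fi_true <- hill4(concs, e_min = 0, e_max = cmp$e_max,
                     ec50 = cmp$ec50_um, slope = cmp$slope)
    # collapsed regime: signal drops to ~5% of vehicle, as after overt toxicity
    signal <- ifelse(toxic, 0.05, 1 + fi_true)
    n_treat <- spec$n_concentrations * spec$n_replicates
    treated <- tibble::tibble(
      compound = cmp$compound,
      lot = grid$lot[i],
      endpoint = grid$endpoint[i],
      concentration_um = rep(concs, each = spec$n_replicates),
      replicate = rep(seq_len(spec$n_replicates), spec$n_concentrations),
      value = spec$vehicle_mean * rep(signal, each = spec$n_replicates) *
        lognormal_noise(n_treat, spec$noise_cv),
      is_vehicle = FALSE,
      is_toxic_truth = rep(toxic, each = spec$n_replicates)
    )
    vehicle <- tibble::tibble(
      compound = cmp$compound,
      lot = grid$lot[i],
      endpoint = grid$endpoint[i],
      concentration_um = 0,
      replicate = seq_len(spec$n_replicates),
      value = spec$vehicle_mean *
        lognormal_noise(spec$n_replicates, spec$noise_cv),
      is_vehicle = TRUE,
      is_toxic_truth = FALSE
    )
    well_tabs[[i]] <- dplyr::bind_rows(vehicle, treated)
  }
  panel <- list(
    wells = dplyr::bind_rows(well_tabs),
    spec = spec,
    observed_auc_change = NULL
  )
  if (!is.null(cal)) {
    panel$observed_auc_change <- generate_calibration_truth(spec, cal)
  }
  structure(panel, class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic induction panel: %d compounds x %d lots x %s, %d wells\n",
    nrow(x$spec$compounds), x$spec$n_lots,
    paste(x$spec$endpoints, collapse = "/"), nrow(x$wells)))
  invisible(x)
}

#' True observed AUC changes for a synthetic panel
#'
#' Closes the loop between the generator and the calibration stage: for each
#' compound with an unbound Cmax, the true RIS is computed from the spec's
#' Hill truth and passed through a reference calibration model, giving the
#' "observed" percent AUC change that a panel generated from `spec` should
#' recover. Optional Gaussian noise perturbs the result.
#'
#' @param spec A [panel_spec()] whose compounds carry `cmax_ub_um`.
#' @param cal A [calibration_model()].
#' @param noise_sd Standard deviation (percentage points) of additive noise
#'   on the AUC change (default 0, exact).
#'
#' @return A tibble with columns `compound`, `ris_true`,
#'   `observed_auc_change`.
#' @export
generate_calibration_truth <- function(spec, cal, noise_sd = 0) {
  stopifnot(inherits(spec, "panel_spec"))
  cmp <- spec$compounds
  ris_true <- cmp$e_max * cmp$cmax_ub_um / (cmp$ec50_um + cmp$cmax_ub_um)
  auc <- predict_auc_change(cal, ris_true)
  if (noise_sd > 0) auc <- auc + rnorm(length(auc), 0, noise_sd)
  tibble::tibble(compound = cmp$compound, ris_true = ris_true,
                 observed_auc_change = auc)
}

#' Write / read a synthetic panel as tidy CSV with a YAML truth sidecar
#'
#' `write_panel()` writes the well table to `path` and the generating truth
#' (compound parameters and panel design) to `paste0(path, ".truth.yaml")`,
#' so a panel on disk is self-describing. `read_panel_csv()` reads any tidy
#' well table with the same columns back into a tibble.
#'
#' @param panel A `synthetic_panel`.
#' @param path CSV file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel_csv()`
#'   returns a tibble of wells.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "synthetic_panel"))
  readr::write_csv(panel$wells, path)
  truth <- list(
    compounds = lapply(seq_len(nrow(panel$spec$compounds)), function(i) {
      as.list(panel$spec$compounds[i, ])
    }),
    n_lots = panel$spec$n_lots,
    n_concentrations = panel$spec$n_concentrations,
    n_replicates = panel$spec$n_replicates,
    endpoints = panel$spec$endpoints,
    noise_cv = panel$spec$noise_cv,
    toxicity_threshold = panel$spec$toxicity_threshold,
    vehicle_mean = panel$spec$vehicle_mean,
    seed = panel$spec$seed
  )
  yaml::write_yaml(truth, paste0(path, ".truth.yaml"))
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_panel_csv: file not found: ", path, call. = FALSE)
  }
  wells <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("compound", "lot", "endpoint", "concentration_um",
                "replicate", "value", "is_vehicle")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop("read_panel_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(wells) == 0) {
    stop("read_panel_csv: panel file is empty: ", path, call. = FALSE)
  }
  if (!("is_toxic_truth" %in% names(wells))) wells$is_toxic_truth <- FALSE
  wells
}
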