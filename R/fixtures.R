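# expected schema (and row count) per packaged fixture
.fixture_schema <- list(
  table2_fits = list(
    file = "table2_fits.csv",
    cols = c("compound", "conc_low_um", "conc_high_um", "lot", "status",
             "r_squared", "e_max", "ec50_um", "max_fold_induction"),
    rows = 54L
  ),
  table3_ris = list(
    file = "table3_ris.csv",
    cols = c("compound", "endpoint", "lot", "ris"),
    rows = 78L
  ),
  table5_auc = list(
    file = "table5_auc.csv",
    cols = c("compound", "observed_auc_pct", "endpoint", "lot",
             "predicted_auc_pct"),
    rows = 78L
  ),
  compounds = list(
    file = "compounds.csv",
    cols = c("compound", "cmax_ub_um", "observed_auc_pct",
             "substrate_class", "in_calibration_set", "category"),
    rows = 13L
  )
)

#' Packaged reference tables
#'
#' Loads one of the reference tables shipped with the package, validated
#' against its expected schema and row count:
#'
#' * `"table2_fits"` — Hill-4 induction fit parameters (R-squared, Emax as
#'   fold increase, EC50 in uM) per compound and lot, mRNA endpoint, for the
#'   18-compound panel, with `NI` (no induction) and `NA` (no
#'   concentration-dependent curve; observed maximum fold induction
#'   reported) sentinels mapped to a `status` column;
#' * `"table3_ris"` — RIS per compound, lot, and endpoint (mRNA and enzyme
#'   activity) for the 13 fit-eligible compounds;
#' * `"table5_auc"` — observed percent midazolam AUC change and predicted
#'   percent AUC change per compound, lot, and endpoint;
#' * `"compounds"` — compound metadata: unbound plasma Cmax where published,
#'   observed AUC change, victim-substrate class, calibration-set
#'   membership, clinical inducer category.
#'
#' @param name Fixture name, one of the above.
#' @return A tibble.
#' @examples
#' load_fixtures("table3_ris")
#' @export
load_fixtures <- function(name) {
  if (!name %in% names(.fixture_schema)) {
    stop("load_fixtures: unknown fixture '", name, "'; available: ",
         paste(names(.fixture_schema), collapse = ", "), call. = FALSE)
  }
  schema <- .fixture_schema[[name]]
  path <- system.file("extdata", schema$file, package = "riscal")
  if (path == "") {
    stop("load_fixtures: packaged file missing: ", schema$file,
         call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(tab), schema$cols) || nrow(tab) != schema$rows) {
    stop("load_fixtures: fixture '", name, "' failed its integrity check",
         call. = FALSE)
  }
  tab
}
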