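# Readers and writers for the pipeline's CSV schemas (RFC 4180, UTF-8,
# header row). Real-data ingestion uses the same schemas as the generator's
# output; the ground-truth sidecar is absent in real-data mode.

feature_cols <- function() {
  readr::cols(
    feature_id = readr::col_character(),
    neutral_mass = readr::col_double(),
    rt = readr::col_double(),
    mode = readr::col_character(),
    batch = readr::col_integer(),
    sample_id = readr::col_character(),
    replicate = readr::col_integer(),
    abundance = readr::col_double()
  )
}

#' Read a long-format feature table
#' @param path CSV path.
#' @return Tibble in the schema written by [write_pipeline_inputs()].
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, col_types = feature_cols())
}

#' Read a sample table
#' @param path CSV path.
#' @return Tibble (`sample_id`, `participant_id`, `matrix`, `batch`).
#' @export
read_samples_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    participant_id = readr::col_character(),
    matrix = readr::col_character(),
    batch = readr::col_integer()
  ))
}

#' Read a cohort table
#' @param path CSV path.
#' @return Cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    city = readr::col_character(),
    .default = readr::col_guess()
  ))
}

#' Read a chemical database (one row per isomer)
#' @param path CSV path.
#' @return Chemical database tibble.
#' @export
read_chemdb_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    formula = readr::col_character(),
    monoisotopic_mass = readr::col_double(),
    isomer = readr::col_character(),
    pubmed_count = readr::col_double(),
    pubchem_count = readr::col_double(),
    production_volume = readr::col_double(),
    categories = readr::col_character()
  ))
}

#' Read a wristband concentration table
#' @param path CSV path.
#' @return Wristband tibble.
#' @export
read_wristband_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    chemical = readr::col_character(),
    formula = readr::col_character(),
    in_serum_db = readr::col_logical(),
    categories = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Write all generated pipeline inputs to a directory
#'
#' Writes `features.csv`, `samples.csv`, `cohort.csv`, `chemdb.csv`,
#' `wristband.csv`, and the ground-truth sidecar `truth.json`.
#'
#' @param generated List with `features`, `samples`, `feature_truth`.
#' @param cohort,db,wristband,truth The remaining inputs.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_inputs <- function(generated, cohort, db, wristband, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(generated$features, file.path(dir, "features.csv"))
  readr::write_csv(generated$samples, file.path(dir, "samples.csv"))
  readr::write_csv(cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(db, file.path(dir, "chemdb.csv"))
  readr::write_csv(wristband, file.path(dir, "wristband.csv"))
  truth_out <- list(
    chemicals = truth$chemicals,
    differential = truth$differential,
    batch_shift = as.list(truth$batch_shift),
    pesticide_coupling = truth$pesticide_coupling,
    feature_truth = generated$feature_truth
  )
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
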