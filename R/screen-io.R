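# Readers/writers and validation for the pipeline's tabular interchange
# formats. All files are plain CSV: comma-separated, UTF-8, header row
# mandatory, '.' decimal separator. Concentrations are micromolar and the
# drug-free control is concentration 0 exactly.

cell_key_cols <- c("drug_id", "concentration_um", "marker", "cell_id")

#' Write a per-cell feature table to CSV
#'
#' @param cells Per-cell feature tibble as produced by [generate_screen()]
#'   or read by [read_cell_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_features <- function(cells, path) {
  missing <- setdiff(cell_key_cols, names(cells))
  if (length(missing) > 0) {
    abort(paste0("Missing key columns: ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(cells, path)
  invisible(path)
}

#' Read and validate a per-cell feature table
#'
#' Reads a CSV with key columns `drug_id`, `concentration_um`, `marker`,
#' `cell_id` followed by one numeric column per cytological feature.
#' Validation is total: on any failure nothing is returned. Checks are:
#' all feature values numeric (malformed cells reported with line numbers);
#' every (drug, marker) group contains a concentration-0 control; the number
#' of feature columns is one of `allowed_feature_counts` (default 16 or 25,
#' the two-channel and three-channel staining-set schemas).
#'
#' @param path CSV file path.
#' @param allowed_feature_counts Permitted numbers of feature columns;
#'   `NULL` to accept any positive count.
#' @return Validated per-cell feature tibble.
#' @export
read_cell_features <- function(path, allowed_feature_counts = c(16L, 25L)) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  header <- names(readr::read_csv(path,
    n_max = 0, show_col_types = FALSE,
    progress = FALSE
  ))
  missing <- setdiff(cell_key_cols, header)
  if (length(missing) > 0) {
    abort(paste0(
      "Not a cell feature table; missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  feat_cols <- setdiff(header, cell_key_cols)
  if (length(feat_cols) == 0) {
    abort("No feature columns found.")
  }
  if (!is.null(allowed_feature_counts) &&
    !(length(feat_cols) %in% allowed_feature_counts)) {
    abort(paste0(
      "Schema error: ", length(feat_cols), " feature columns; expected one of ",
      paste(allowed_feature_counts, collapse = ", "),
      ". Pass allowed_feature_counts = NULL to accept."
    ))
  }
  spec <- readr::cols(
    drug_id = readr::col_character(),
    concentration_um = readr::col_double(),
    marker = readr::col_character(),
    cell_id = readr::col_character(),
    .default = readr::col_double()
  )
  tbl <- readr::read_csv(path,
    col_types = spec, show_col_types = FALSE,
    progress = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Parse error: non-numeric feature values at line(s) ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  if (any(tbl$concentration_um < 0)) {
    abort("Negative concentrations found.")
  }
  no_ctrl <- tbl |>
    summarise(has_ctrl = any(.data$concentration_um == 0), .by = c("drug_id", "marker")) |>
    filter(!.data$has_ctrl)
  if (nrow(no_ctrl) > 0) {
    abort(paste0(
      "Missing concentration-0 control for drug(s): ",
      paste(unique(no_ctrl$drug_id), collapse = ", ")
    ))
  }
  tbl
}

#' Read and validate an in vivo histology table
#'
#' Reads literature-derived records of pathologist-graded fibrosis scores:
#' the untreated (`sc_raw`) and drug-treated (`st_raw`) histological score
#' per study, on the study's original scale with maximum `scale_max`.
#'
#' @param path CSV path with columns `drug_id`, `model`, `study_id`,
#'   `sc_raw`, `st_raw`, `scale_max`.
#' @return Tibble of validated records (possibly empty).
#' @export
read_invivo_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  tbl <- readr::read_csv(path,
    col_types = readr::cols(
      drug_id = readr::col_character(),
      model = readr::col_character(),
      study_id = readr::col_character(),
      sc_raw = readr::col_double(),
      st_raw = readr::col_double(),
      scale_max = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0("Parse error at line(s) ", paste(unique(probs$row), collapse = ", ")))
  }
  bad <- tbl |>
    filter(.data$sc_raw < 0 | .data$st_raw < 0 |
      .data$sc_raw > .data$scale_max | .data$st_raw > .data$scale_max |
      .data$scale_max <= 0)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Scores out of [0, scale_max] bounds for drug(s): ",
      paste(unique(bad$drug_id), collapse = ", ")
    ))
  }
  tbl
}

#' Read and validate a marker-direction table
#'
#' @param path CSV path with columns `marker`, `direction`.
#' @return Tibble with exactly one `+1`/`-1` entry per marker.
#' @export
read_marker_directions <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  tbl <- readr::read_csv(path,
    col_types = readr::cols(
      marker = readr::col_character(),
      direction = readr::col_integer()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  if (anyDuplicated(tbl$marker)) {
    abort("Duplicate marker entries in direction table.")
  }
  if (!all(tbl$direction %in% c(-1L, 1L))) {
    abort("Directions must be +1 or -1.")
  }
  tbl
}

#' Packaged in vivo histology table
#'
#' The literature-curated table of pathologist-graded fibrosis scores for
#' rat DMN-treatment, CCl4-treatment and CCl4-preventive models (18 study
#' records across 12 drugs), already on a 0-4 scale.
#'
#' @return Tibble of in vivo records; see [read_invivo_table()].
#' @export
load_invivo_histology <- function() {
  read_invivo_table(system.file("extdata", "invivo_histology.csv",
    package = "fibroscore", mustWork = TRUE
  ))
}

#' Published in vitro efficacy predictor values
#'
#' The published per-drug E_predict values for the 49-drug screen, consumed
#' as a fixture for grouping and in vitro-in vivo regression (the optimized
#' weight vector behind them is not published, so they are inputs here, not
#' recomputed quantities).
#'
#' @return Tibble with columns `drug_id`, `e_predict`.
#' @export
load_published_epredict <- function() {
  tbl <- readr::read_csv(
    system.file("extdata", "epredict_published.csv",
      package = "fibroscore", mustWork = TRUE
    ),
    col_types = readr::cols(
      drug_id = readr::col_character(),
      e_predict = readr::col_double()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  tbl
}
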