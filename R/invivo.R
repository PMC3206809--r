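# In vivo efficacy index from pathologist-graded histological scores.
# E_in vivo = (Sc - St) x Sc on scores rescaled to 0-4: the score reduction
# weighted by baseline severity, since severe fibrosis demands higher
# efficacy to move the score at all.

#' Rescale a histological score to the 0-4 range
#'
#' Linear map `raw * 4 / scale_max` from a study's original ordinal scale
#' (Metavir, Knodell, Ludwig, ...) onto the common 0-4 range.
#'
#' @param raw Score(s) on the original scale, in `[0, scale_max]`.
#' @param scale_max Maximum of the original scale (> 0).
#' @return Score(s) in `[0, 4]`.
#' @export
rescale_score <- function(raw, scale_max) {
  stopifnot_scalar_num(scale_max, "scale_max", positive = TRUE)
  if (any(raw < 0 | raw > scale_max)) {
    abort("`raw` must lie within [0, scale_max].")
  }
  raw * 4 / scale_max
}

#' In vivo efficacy index
#'
#' `E_in vivo = (Sc - St) x Sc` for control score `Sc` and treated score
#' `St`, both on the 0-4 scale. Negative values (the drug worsened fibrosis)
#' are retained, unlike the in vitro predictor which clips at 0.
#'
#' @param sc,st Control and treated histological scores in `[0, 4]`
#'   (vectorized).
#' @return Numeric efficacy index; can be negative.
#' @export
efficacy_index <- function(sc, st) {
  if (any(sc < 0 | sc > 4) || any(st < 0 | st > 4)) {
    abort("`sc` and `st` must lie in [0, 4].")
  }
  (sc - st) * sc
}

#' Build the per-drug, per-model in vivo efficacy index
#'
#' Rescales every record to 0-4, computes `E_in vivo` per study and keeps,
#' for each (drug, model), the study with the highest index. The maximum is
#' taken within a model, never across models: severity induced by different
#' hepatotoxins differs, so the indices are only comparable within the same
#' fibrosis model.
#'
#' @param records In vivo records tibble ([read_invivo_table()] /
#'   [generate_invivo()]).
#' @return Tibble with columns `drug_id`, `model`, `e_invivo`, `sc_scaled`,
#'   `st_scaled`, `study_id` — one row per (drug, model). Empty input gives
#'   an empty index.
#' @export
build_invivo_index <- function(records) {
  cols <- c("drug_id", "model", "study_id", "sc_raw", "st_raw", "scale_max")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    return(tibble(
      drug_id = character(), model = character(), e_invivo = numeric(),
      sc_scaled = numeric(), st_scaled = numeric(), study_id = character()
    ))
  }
  records |>
    mutate(
      sc_scaled = .data$sc_raw * 4 / .data$scale_max,
      st_scaled = .data$st_raw * 4 / .data$scale_max,
      e_invivo = efficacy_index(.data$sc_scaled, .data$st_scaled)
    ) |>
    slice_max(.data$e_invivo,
      n = 1, with_ties = FALSE,
      by = c("drug_id", "model")
    ) |>
    select("drug_id", "model", "e_invivo", "sc_scaled", "st_scaled", "study_id") |>
    arrange(.data$model, .data$e_invivo)
}
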