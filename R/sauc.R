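# SAUC: per drug x marker summary of the KR-versus-concentration profiles.
# Each feature's KR series is integrated over a normalized concentration
# axis; the per-feature areas are summed within the marker and multiplied
# by the marker's anti-fibrotic direction so a positive SAUC always means
# an anti-fibrotic response.

#' Area under a KR-versus-concentration series
#'
#' Trapezoidal integral of KR over a concentration axis normalized to
#' `[0, 1]`, so a series constant at 1 over the whole axis scores exactly 1.
#' If the series has no concentration-0 point, the control anchor `(0, 0)`
#' is prepended (KR of the control against itself is 0 by definition).
#'
#' Axis modes:
#' * `"index"` (default): dilution-step index, equally spaced. Drugs are
#'   screened with different maximum concentrations (anchored at their
#'   IC50s), so an index axis makes the integral comparable across drugs.
#' * `"log2"`: log2 of concentration, i.e. dilution steps of an exact
#'   2-fold series; control anchored one step below the lowest dose.
#' * `"raw_um"`: raw micromolar axis.
#'
#' @param concentration Strictly increasing concentrations (µM).
#' @param kr KR values, same length.
#' @param axis_mode One of `"index"`, `"log2"`, `"raw_um"`.
#' @return The normalized area, a single number.
#' @export
feature_auc <- function(concentration, kr,
                        axis_mode = c("index", "log2", "raw_um")) {
  axis_mode <- match.arg(axis_mode)
  if (length(concentration) != length(kr)) {
    abort("`concentration` and `kr` must have the same length.")
  }
  if (any(diff(concentration) <= 0)) {
    abort("Concentrations must be strictly increasing.")
  }
  if (length(concentration) < 2) {
    abort("Need at least 2 points to integrate.")
  }
  if (concentration[1] > 0) {
    concentration <- c(0, concentration)
    kr <- c(0, kr)
  }
  x <- switch(axis_mode,
    index = seq_along(concentration) - 1,
    log2 = {
      pos <- concentration[concentration > 0]
      steps <- log2(concentration / min(pos))
      # control sits one dilution step below the lowest dose
      ifelse(concentration == 0, min(steps[is.finite(steps)]) - 1, steps)
    },
    raw_um = concentration
  )
  x <- (x - min(x)) / (max(x) - min(x))
  pracma::trapz(x, kr)
}

#' Compute the SAUC matrix of a screen
#'
#' `SAUC(drug, marker) = scale x direction(marker) x sum over features of
#' feature_auc(feature's KR series)`. The direction correction makes SAUC
#' increase when the drug acts anti-fibrotically on that marker, whichever
#' way the raw staining moves.
#'
#' @param profile KR profile from [compute_kr_profile()].
#' @param directions Marker-direction table (default [marker_directions()]).
#' @param axis_mode Concentration axis for the integral; see [feature_auc()].
#' @param scale Cosmetic multiplier (default 1000) placing SAUC — and hence
#'   the downstream efficacy predictor — on the order of magnitude of
#'   published values.
#' @return Tidy tibble with columns `drug_id`, `marker`, `sauc`, carrying
#'   `axis_mode` and `scale` as attributes.
#' @export
compute_sauc <- function(profile, directions = marker_directions(),
                         axis_mode = c("index", "log2", "raw_um"),
                         scale = 1000) {
  axis_mode <- match.arg(axis_mode)
  dir_map <- setNames(directions$direction, directions$marker)
  missing <- setdiff(unique(profile$marker), names(dir_map))
  if (length(missing) > 0) {
    abort(paste0(
      "No direction entry for marker(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  out <- profile |>
    arrange(.data$drug_id, .data$marker, .data$feature, .data$concentration_um) |>
    summarise(
      auc = feature_auc(.data$concentration_um, .data$kr, axis_mode = axis_mode),
      .by = c("drug_id", "marker", "feature")
    ) |>
    summarise(
      sauc = scale * dir_map[[.data$marker[1]]] * sum(.data$auc),
      .by = c("drug_id", "marker")
    )
  attr(out, "axis_mode") <- axis_mode
  attr(out, "scale") <- scale
  out
}

#' Widen a tidy SAUC table into a drugs x markers matrix
#'
#' @param sauc Tidy SAUC tibble from [compute_sauc()] (columns `drug_id`,
#'   `marker`, `sauc`).
#' @param markers Column order; defaults to order of appearance.
#' @return Numeric matrix, rows named by drug, columns by marker.
#' @export
sauc_matrix <- function(sauc, markers = NULL) {
  if (is.matrix(sauc)) {
    return(sauc)
  }
  if (is.null(markers)) markers <- unique(sauc$marker)
  wide <- sauc |>
    pivot_wider(
      id_cols = "drug_id", names_from = "marker",
      values_from = "sauc"
    )
  m <- as.matrix(wide[, markers, drop = FALSE])
  rownames(m) <- wide$drug_id
  if (anyNA(m)) abort("SAUC table must cover every (drug, marker) pair.")
  m
}
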