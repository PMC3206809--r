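#' The ten fibrosis markers of the screening panel
#'
#' Marker identifiers for the ten stained readouts tracked on activated
#' hepatic stellate cells: proliferation (BrdU), contractility (F-actin),
#' apoptosis (mitochondrial membrane potential, caspase 3), extracellular
#' matrix (collagen III, MMP-2, TIMP-1), oxidative stress (DHE) and cytokine
#' signalling (Smad3, pCREB). `mito_potential` stands for the mitochondrial
#' membrane potential readout.
#'
#' @return Character vector of length 10.
#' @export
fibrosis_markers <- function() {
  c(
    "BrdU", "F-actin", "mito_potential", "caspase3", "collagen_III",
    "MMP-2", "TIMP-1", "DHE", "Smad3", "pCREB"
  )
}

#' Marker anti-fibrotic directions
#'
#' Each marker carries a sign such that an anti-fibrotic response moves the
#' marker's intensity features in the `direction x positive` sense: e.g.
#' caspase 3 rises under pro-apoptotic (anti-fibrotic) treatment (+1) while
#' proliferation (BrdU), contractility (F-actin) and collagen III fall (-1).
#' Directions are configurable data, not code: supply your own table with
#' one `{+1, -1}` entry per marker to override the packaged defaults.
#'
#' @param path Optional path to a CSV with columns `marker`, `direction`.
#'   Defaults to the packaged direction table.
#' @return A tibble with columns `marker` (character) and `direction`
#'   (integer, +1 or -1), one row per marker.
#' @export
marker_directions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_directions.csv",
      package = "fibroscore", mustWork = TRUE
    )
  }
  read_marker_directions(path)
}
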