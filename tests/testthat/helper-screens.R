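# Small synthetic screens shared across test files, built once per run.
# Sizes are deliberately modest: enough cells for stable KR values, small
# enough that the whole suite stays fast.

.screens <- new.env(parent = emptyenv())

# 5 drugs x 3 markers x 4 features x 6 concentrations x 150 cells
tiny_screen <- function() {
  if (is.null(.screens$tiny)) {
    des <- screen_design(
      n_concentrations = 6,
      markers = c("BrdU", "caspase3", "collagen_III"),
      features_per_marker = 4, cells_per_condition = 150, seed = 11
    )
    panel <- synthetic_drug_panel(
      n_drugs = 5,
      markers = des$markers, seed = 12
    )
    cells <- generate_screen(panel, des)
    .screens$tiny <- list(
      design = des, panel = panel, cells = cells,
      profile = compute_kr_profile(cells)
    )
  }
  .screens$tiny
}

# full 10-marker panel, 6 drugs, small cell counts; used for SAUC and
# profiling checks that need the complete marker set
panel_screen <- function() {
  if (is.null(.screens$panel)) {
    des <- screen_design(
      n_concentrations = 6, features_per_marker = 4,
      cells_per_condition = 150, seed = 21
    )
    panel <- synthetic_drug_panel(n_drugs = 6, seed = 22)
    cells <- generate_screen(panel, des)
    prof <- compute_kr_profile(cells)
    .screens$panel <- list(
      design = des, panel = panel, cells = cells,
      profile = prof, sauc = compute_sauc(prof)
    )
  }
  .screens$panel
}

# fixture-derived regression data: published E_predict joined to the
# recomputed in vivo index for one fibrosis model
ivivc_fixture <- function(model) {
  idx <- build_invivo_index(load_invivo_histology())
  idx <- idx[idx$model == model, ]
  ep <- load_published_epredict()
  merge <- dplyr::inner_join(idx, ep, by = "drug_id")
  dplyr::select(merge, "drug_id", "e_predict", "e_invivo")
}
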