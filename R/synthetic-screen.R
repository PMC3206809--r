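# Synthetic high-content screen generator.
#
# Emulates the structure of a plate-based hepatic stellate cell screen:
# drugs x (2-fold dilution series + drug-free control) x markers x per-cell
# cytological features, with known ground-truth efficacies so the whole
# scoring pipeline can be exercised and its rank recovery measured.

# fixed distributional constants of the simulator (documented in the
# methods vignette; not exposed as arguments on purpose)
.sim <- list(
  uni_mean = 100, uni_sd = 20, # unimodal feature baseline
  effect_size = 1.5, # max mean shift at full efficacy, in sd units
  bi_neg = 50, bi_pos = 100, bi_sd = 5, # bimodal modes (10 sd apart)
  bi_p0 = 0.5, bi_gain = 0.45, # baseline + max shift of responder fraction
  nonspecific_gain = 1.2 # collagen III increase of non-specific drugs, sd units
)

#' Design of a synthetic high-content screen
#'
#' Fixes the experimental grid: a 2-fold serial dilution from the highest
#' concentration plus a drug-free control (concentration 0), the marker
#' panel, the number of cytological features per marker and the number of
#' cells imaged per condition.
#'
#' @param n_concentrations Total number of concentrations including the
#'   drug-free control (default 11: control + 10 dilution steps).
#' @param markers Character vector of marker identifiers (default the
#'   ten-marker fibrosis panel from [fibrosis_markers()]).
#' @param features_per_marker Number of per-cell features per marker
#'   (default 16, as for two-channel staining sets).
#' @param cells_per_condition Number of cells per drug/marker/concentration
#'   (default 1000).
#' @param max_concentration_um Highest concentration of the dilution series
#'   in micromolar (default 40).
#' @param bimodal_markers Markers whose intensity features are drawn from a
#'   two-component (positive/negative cell) mixture rather than a single
#'   Gaussian; default `"BrdU"`, mimicking labelled/unlabelled nuclei.
#' @param seed Integer seed; the same design and drug panel always produce
#'   an identical table.
#' @return A `screen_design` list with the validated grid, including the
#'   strictly increasing `concentrations` vector (control first, at 0).
#' @export
screen_design <- function(n_concentrations = 11,
                          markers = fibrosis_markers(),
                          features_per_marker = 16,
                          cells_per_condition = 1000,
                          max_concentration_um = 40,
                          bimodal_markers = "BrdU",
                          seed = 1L) {
  stopifnot_scalar_num(n_concentrations, "n_concentrations", positive = TRUE)
  stopifnot_scalar_num(features_per_marker, "features_per_marker", positive = TRUE)
  stopifnot_scalar_num(cells_per_condition, "cells_per_condition", positive = TRUE)
  stopifnot_scalar_num(max_concentration_um, "max_concentration_um", positive = TRUE)
  if (n_concentrations < 2) {
    abort("`n_concentrations` must be at least 2 (control + one dose).")
  }
  if (length(markers) < 1 || anyDuplicated(markers)) {
    abort("`markers` must be a non-empty set of unique labels.")
  }
  bimodal_markers <- intersect(bimodal_markers, markers)
  conc <- c(0, max_concentration_um / 2^((n_concentrations - 2):0))
  if (any(diff(conc) <= 0)) {
    abort("Concentration grid must be strictly increasing.")
  }
  structure(
    list(
      concentrations = conc,
      markers = as.character(markers),
      features_per_marker = as.integer(features_per_marker),
      cells_per_condition = as.integer(cells_per_condition),
      bimodal_markers = as.character(bimodal_markers),
      seed = as.integer(seed)
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat(
    "<screen_design> ", length(x$concentrations), " concentrations (0-",
    max(x$concentrations), " uM), ", length(x$markers), " markers, ",
    x$features_per_marker, " features/marker, ",
    x$cells_per_condition, " cells/condition\n",
    sep = ""
  )
  invisible(x)
}

# feature name schema shared by the generator and the profiling helpers:
# two intensity features first, then generic morphology slots
feature_names <- function(n) {
  base <- c("avg_intensity", "total_intensity")
  if (n <= 2) {
    return(base[seq_len(n)])
  }
  c(base, sprintf("feature_%02d", 3:n))
}

#' Panel of synthetic drugs with known ground-truth efficacy
#'
#' Each drug carries a `true_efficacy` in `[0, 1]`, a per-marker
#' susceptibility in `[0, 1]` (how strongly that marker's features respond),
#' Hill dose-response parameters and an optional non-specific-collagen flag
#' (the drug increases collagen III staining with concentration regardless
#' of efficacy, as cytotoxic compounds do).
#'
#' @param n_drugs Number of drugs.
#' @param true_efficacy Numeric in `[0, 1]`, recycled; default an even grade
#'   from 0 to 1 across the panel.
#' @param markers Marker panel (must match the screen design).
#' @param ec50_um EC50 of the Hill response in micromolar, recycled
#'   (default 5, so a 40 uM series reaches ~96% of saturation).
#' @param hill_n Hill coefficient, recycled (default 1.5).
#' @param nonspecific_collagen Logical, recycled (default `FALSE`).
#' @param susceptibility Optional list of named per-marker vectors in
#'   `[0, 1]`, one per drug; by default drawn uniformly from `[0.5, 1]`.
#' @param seed Integer seed for the susceptibility draw.
#' @return Tibble with columns `drug_id`, `true_efficacy`, `ec50_um`,
#'   `hill_n`, `nonspecific_collagen` and the list-column `susceptibility`.
#' @export
synthetic_drug_panel <- function(n_drugs = 12,
                                 true_efficacy = seq(0, 1, length.out = n_drugs),
                                 markers = fibrosis_markers(),
                                 ec50_um = 5,
                                 hill_n = 1.5,
                                 nonspecific_collagen = FALSE,
                                 susceptibility = NULL,
                                 seed = 1L) {
  stopifnot_scalar_num(n_drugs, "n_drugs", positive = TRUE)
  eff <- rep_len(true_efficacy, n_drugs)
  if (any(eff < 0 | eff > 1)) abort("`true_efficacy` must lie in [0, 1].")
  ec50 <- rep_len(ec50_um, n_drugs)
  hn <- rep_len(hill_n, n_drugs)
  if (any(ec50 <= 0) || any(hn <= 0)) {
    abort("`ec50_um` and `hill_n` must be positive.")
  }
  ns <- rep_len(as.logical(nonspecific_collagen), n_drugs)
  if (is.null(susceptibility)) {
    susceptibility <- withr::with_seed(seed, {
      lapply(seq_len(n_drugs), function(i) {
        setNames(runif(length(markers), 0.5, 1), markers)
      })
    })
  } else {
    susceptibility <- lapply(susceptibility, function(s) {
      if (is.null(names(s))) names(s) <- markers
      if (!setequal(names(s), markers)) {
        abort("Each susceptibility vector must be named by the marker panel.")
      }
      if (any(s < 0 | s > 1)) abort("Susceptibilities must lie in [0, 1].")
      s[markers]
    })
    if (length(susceptibility) != n_drugs) {
      abort("`susceptibility` must supply one vector per drug.")
    }
  }
  tibble(
    drug_id = sprintf("drug_%02d", seq_len(n_drugs)),
    true_efficacy = eff,
    ec50_um = ec50,
    hill_n = hn,
    nonspecific_collagen = ns,
    susceptibility = susceptibility
  )
}

#' Hill dose-response fraction
#'
#' `h(c) = c^n / (c^n + ec50^n)`: the saturating fraction of the maximal
#' effect reached at concentration `c`. `h(0) = 0` exactly.
#'
#' @param conc Concentration(s), same units as `ec50`.
#' @param ec50 Half-maximal concentration (> 0).
#' @param n Hill coefficient (> 0).
#' @return Numeric in `[0, 1)`.
#' @export
hill_response <- function(conc, ec50, n = 1) {
  stopifnot_scalar_num(ec50, "ec50", positive = TRUE)
  stopifnot_scalar_num(n, "n", positive = TRUE)
  conc^n / (conc^n + ec50^n)
}

#' Generate a synthetic per-cell feature table
#'
#' Draws one row per simulated cell. Unimodal features come from a Gaussian
#' whose mean shifts by
#' `true_efficacy x susceptibility x direction x h(c)` (in units of the
#' feature's standard deviation, scaled by a fixed effect size); bimodal
#' features come from a two-component mixture whose responder fraction
#' shifts by the same factor. A drug with `true_efficacy = 0` is drawn from
#' the control distribution at every concentration. Drugs flagged
#' `nonspecific_collagen` get a concentration-dependent *increase* in their
#' collagen III intensity features regardless of efficacy.
#'
#' @param drugs Drug panel from [synthetic_drug_panel()].
#' @param design Screen design from [screen_design()].
#' @param directions Marker-direction table (default [marker_directions()]);
#'   simulated shifts follow it so anti-fibrotic drugs yield positive SAUC
#'   by construction.
#' @return Tibble with columns `drug_id`, `concentration_um`, `marker`,
#'   `cell_id` and one numeric column per feature
#'   (`avg_intensity`, `total_intensity`, `feature_03`, ...).
#' @export
generate_screen <- function(drugs, design = screen_design(),
                            directions = marker_directions()) {
  if (!inherits(design, "screen_design")) {
    abort("`design` must be created by screen_design().")
  }
  if (!is.data.frame(drugs) || nrow(drugs) == 0) {
    abort("`drugs` must be a non-empty drug panel.")
  }
  if (any(diff(design$concentrations) <= 0)) {
    abort("Concentration grid must be strictly increasing.")
  }
  dir_map <- setNames(directions$direction, directions$marker)
  if (!all(design$markers %in% names(dir_map))) {
    abort("Every marker in the design needs a direction entry.")
  }

  cells <- design$cells_per_condition
  feats <- feature_names(design$features_per_marker)
  conds <- expand_grid(
    drug_id = drugs$drug_id,
    marker = design$markers,
    concentration_um = design$concentrations
  )
  i <- match(conds$drug_id, drugs$drug_id)
  eff <- drugs$true_efficacy[i]
  susc <- map_dbl(seq_len(nrow(conds)), function(k) {
    drugs$susceptibility[[i[k]]][[conds$marker[k]]]
  })
  h <- hill_mv(conds$concentration_um, drugs$ec50_um[i], drugs$hill_n[i])
  delta <- eff * susc * dir_map[conds$marker] * h
  # non-specific drugs: collagen III intensity rises with dose, overriding
  # whatever the drug's true effect on that marker would have been
  ns_rows <- drugs$nonspecific_collagen[i] & conds$marker == "collagen_III"
  delta_collagen <- ifelse(ns_rows, .sim$nonspecific_gain / .sim$effect_size * h, delta)

  n_rows <- nrow(conds) * cells
  per_row <- function(x) rep(x, each = cells)
  bimodal_cond <- conds$marker %in% design$bimodal_markers
  out <- tibble(
    drug_id = per_row(conds$drug_id),
    concentration_um = per_row(conds$concentration_um),
    marker = per_row(conds$marker),
    cell_id = as.character(rep(seq_len(cells), times = nrow(conds)))
  )
  withr::with_seed(design$seed, {
    for (f in seq_along(feats)) {
      intensity <- f <= 2L
      d_cond <- if (intensity) delta_collagen else delta
      bim <- bimodal_cond & intensity
      d_row <- per_row(ifelse(bim, 0, d_cond))
      vals <- rnorm(
        n_rows,
        mean = .sim$uni_mean + .sim$effect_size * .sim$uni_sd * d_row,
        sd = .sim$uni_sd
      )
      if (any(bim)) {
        sel <- per_row(bim)
        p <- pmin(pmax(.sim$bi_p0 + .sim$bi_gain * per_row(d_cond)[sel], 0.02), 0.98)
        comp <- rbinom(sum(sel), 1L, p)
        vals[sel] <- rnorm(
          sum(sel),
          mean = ifelse(comp == 1L, .sim$bi_pos, .sim$bi_neg),
          sd = .sim$bi_sd
        )
      }
      out[[feats[f]]] <- vals
    }
  })
  out
}

# vectorized Hill over per-condition ec50/hill_n
hill_mv <- function(conc, ec50, n) {
  ifelse(conc == 0, 0, conc^n / (conc^n + ec50^n))
}

#' Generate matched synthetic in vivo histology records
#'
#' The synthetic counterpart of a literature table of pathologist-graded
#' fibrosis scores: for each drug a control score `Sc` is drawn from
#' `sc_range` and the treated score is
#' `St = clip(Sc - g(true_efficacy) * Sc + eps, 0, Sc)` with
#' `eps ~ Normal(0, noise_sd)`. With `noise_sd = 0` and zero efficacy,
#' `St = Sc` exactly. The link `g` is the identity by default: the simplest
#' monotone map from in vitro ground truth to in vivo score reduction.
#'
#' @param drugs Drug panel from [synthetic_drug_panel()].
#' @param model Fibrosis model label (default `"CCl4_treatment"`).
#' @param sc_range Interval within `[0, 4]` for the untreated score.
#' @param noise_sd Non-negative standard deviation of the score noise.
#' @param seed Integer seed.
#' @param g Monotone increasing link from efficacy to fractional score
#'   reduction; default `identity`.
#' @return Tibble of records with columns `drug_id`, `model`, `study_id`,
#'   `sc_raw`, `st_raw`, `scale_max` (= 4).
#' @export
generate_invivo <- function(drugs, model = "CCl4_treatment",
                            sc_range = c(2.5, 4), noise_sd = 0.3,
                            seed = 1L, g = identity) {
  if (length(sc_range) != 2 || sc_range[1] > sc_range[2] ||
    sc_range[1] < 0 || sc_range[2] > 4) {
    abort("`sc_range` must be an interval within [0, 4].")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  n <- nrow(drugs)
  withr::with_seed(seed, {
    sc <- runif(n, sc_range[1], sc_range[2])
    eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n)
    st <- pmin(pmax(sc - g(drugs$true_efficacy) * sc + eps, 0), sc)
  })
  tibble(
    drug_id = drugs$drug_id,
    model = model,
    study_id = paste0("synthetic_", model),
    sc_raw = sc,
    st_raw = st,
    scale_max = 4
  )
}
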