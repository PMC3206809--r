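# KR statistics: per-feature, per-concentration effect scores in [-1, 1]
# relative to the drug-free control. Unimodal features get a signed
# two-sample Kolmogorov-Smirnov score; bimodal features (positive/negative
# cell populations) get a difference of positive fractions. Only the KS
# statistic D is used, never its p-value: the KR value is an effect size.

#' Classify a feature distribution as unimodal or bimodal
#'
#' Fits 1- and 2-component Gaussian mixtures (equal- and varying-variance)
#' to the control sample and picks the component count by BIC; a sample is
#' declared bimodal only if the 2-component model wins *and* its fitted
#' density actually has two modes. A mixture whose components sit closer
#' than the bimodality limit (about 2 sd for equal weights) therefore
#' classifies as unimodal, which is the property the downstream ratio score
#' needs: a usable threshold must separate two real modes.
#'
#' @param values Numeric sample of control-cell feature values (>= 50).
#' @param min_n Minimum sample size (default 50).
#' @return `"unimodal"` or `"bimodal"`.
#' @export
classify_modality <- function(values, min_n = 50) {
  fit <- modality_fit(values, min_n = min_n)
  fit$modality
}

# Full modality fit: label plus, for bimodal samples, the two mode
# locations and the midpoint threshold between them.
# Deterministic for a given sample: mclust is initialised from an
# evenly-spaced subset of the sorted values, no RNG involved.
modality_fit <- function(values, min_n = 50) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < min_n) {
    abort(paste0("Need at least ", min_n, " values to classify modality; got ", n, "."))
  }
  if (sd(values) == 0) {
    return(list(modality = "unimodal", threshold = NA_real_, modes = NA_real_))
  }
  init <- NULL
  if (n > 2000) {
    init <- list(subset = order(values)[round(seq(1, n, length.out = 2000))])
  }
  fit <- tryCatch(
    suppressWarnings(Mclust(values,
      G = 1:2, modelNames = c("E", "V"),
      initialization = init, verbose = FALSE
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate sample; fall back to a histogram-valley (Otsu) split
    thr <- otsu_threshold(values)
    return(list(modality = "unimodal", threshold = thr, modes = NA_real_))
  }
  if (fit$G == 1) {
    return(list(modality = "unimodal", threshold = NA_real_, modes = NA_real_))
  }
  modes <- mixture_modes(fit)
  if (length(modes) < 2) {
    return(list(modality = "unimodal", threshold = NA_real_, modes = modes))
  }
  list(
    modality = "bimodal",
    threshold = mean(range(modes)),
    modes = modes
  )
}

# locate modes of a fitted 1-D Gaussian mixture on a fine grid
mixture_modes <- function(fit) {
  p <- fit$parameters
  sds <- sqrt(if (p$variance$modelName == "E") {
    rep(p$variance$sigmasq, fit$G)
  } else {
    p$variance$sigmasq
  })
  lo <- min(p$mean - 4 * sds)
  hi <- max(p$mean + 4 * sds)
  grid <- seq(lo, hi, length.out = 1024)
  dens <- rowSums(vapply(seq_len(fit$G), function(k) {
    p$pro[k] * stats::dnorm(grid, p$mean[k], sds[k])
  }, numeric(length(grid))))
  i <- 2:(length(grid) - 1)
  peaks <- i[dens[i] > dens[i - 1] & dens[i] >= dens[i + 1]]
  grid[peaks]
}

# Otsu's histogram threshold (between-class variance maximiser); fallback
# splitter when a mixture fit is unavailable
otsu_threshold <- function(values, n_bins = 256) {
  h <- graphics::hist(values, breaks = n_bins, plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Signed two-sample Kolmogorov-Smirnov score
#'
#' Magnitude is the two-sample KS statistic
#' `D = max |ECDF_treated - ECDF_control|` (exact under ties); the sign is
#' the sign of `median(treated) - median(control)`. When the medians are
#' exactly equal the sign is taken from the mean difference; if that is also
#' zero the score is 0. Identical samples score exactly 0.
#'
#' @param treated,control Non-empty numeric samples.
#' @return A value in `[-1, 1]`.
#' @export
signed_ks_score <- function(treated, control) {
  treated <- treated[is.finite(treated)]
  control <- control[is.finite(control)]
  if (length(treated) == 0 || length(control) == 0) {
    abort("Both samples must be non-empty.")
  }
  v <- sort(unique(c(treated, control)))
  d <- max(abs(
    findInterval(v, sort(treated)) / length(treated) -
      findInterval(v, sort(control)) / length(control)
  ))
  if (d == 0) {
    return(0)
  }
  s <- sign(median(treated) - median(control))
  if (s == 0) s <- sign(mean(treated) - mean(control))
  if (s == 0) {
    return(0)
  }
  s * d
}

#' Positive-fraction ratio score for bimodal features
#'
#' For features with distinct positive/negative cell populations (e.g. BrdU
#' incorporation) the effect score is the difference of positive fractions,
#' `p_treated - p_control`, where a cell is positive when its value exceeds
#' `threshold`. Bounded in `[-1, 1]`.
#'
#' @param treated,control Non-empty numeric samples.
#' @param threshold Cut separating the two control modes (e.g. the midpoint
#'   of the fitted mode locations). A threshold outside the observed range
#'   raises a warning but the score is still defined.
#' @return A value in `[-1, 1]`.
#' @export
bimodal_ratio_score <- function(treated, control, threshold) {
  if (length(treated) == 0 || length(control) == 0) {
    abort("Both samples must be non-empty.")
  }
  stopifnot_scalar_num(threshold, "threshold")
  rng <- range(c(treated, control))
  if (threshold < rng[1] || threshold > rng[2]) {
    warn("`threshold` lies outside the observed value range.")
  }
  mean(treated > threshold) - mean(control > threshold)
}

#' Compute the KR profile of a screen
#'
#' Converts a per-cell feature table into one KR value per
#' (drug, marker, feature, non-control concentration). The modality of each
#' (marker, feature) is decided once, on the control cells of all drugs
#' pooled, and is constant across concentrations; bimodal features use the
#' pooled-control mixture threshold for the ratio score, unimodal features
#' the signed KS score against the drug's own control.
#'
#' @param cells Per-cell feature tibble ([generate_screen()] /
#'   [read_cell_features()]).
#' @param min_control_n Minimum pooled control cells required per feature
#'   for the modality decision (default 50).
#' @return Tibble with columns `drug_id`, `marker`, `feature`,
#'   `concentration_um`, `kr`, `modality`.
#' @export
compute_kr_profile <- function(cells, min_control_n = 50) {
  feats <- setdiff(names(cells), cell_key_cols)
  if (length(feats) == 0) abort("No feature columns in `cells`.")
  has_ctrl <- cells |>
    summarise(ok = any(.data$concentration_um == 0), .by = c("drug_id", "marker"))
  if (!all(has_ctrl$ok)) {
    abort("Every (drug, marker) group needs a concentration-0 control.")
  }
  long <- cells |>
    pivot_longer(all_of(feats), names_to = "feature", values_to = "value")

  ctrl <- long |> filter(.data$concentration_um == 0)
  mods <- ctrl |>
    summarise(fit = list(modality_fit(.data$value, min_n = min_control_n)),
      .by = c("marker", "feature")
    ) |>
    mutate(
      modality = map_chr(.data$fit, "modality"),
      threshold = map_dbl(.data$fit, "threshold")
    ) |>
    select(-"fit")

  ctrl_by_drug <- ctrl |>
    summarise(control = list(.data$value), .by = c("drug_id", "marker", "feature"))

  long |>
    filter(.data$concentration_um > 0) |>
    summarise(treated = list(.data$value),
      .by = c("drug_id", "marker", "feature", "concentration_um")
    ) |>
    left_join(ctrl_by_drug, by = c("drug_id", "marker", "feature")) |>
    left_join(mods, by = c("marker", "feature")) |>
    mutate(kr = pmap(
      list(.data$treated, .data$control, .data$modality, .data$threshold),
      function(t, c, m, thr) {
        if (m == "bimodal") {
          bimodal_ratio_score(t, c, thr)
        } else {
          signed_ks_score(t, c)
        }
      }
    )) |>
    mutate(kr = unlist(.data$kr)) |>
    select("drug_id", "marker", "feature", "concentration_um", "kr", "modality") |>
    arrange(.data$drug_id, .data$marker, .data$feature, .data$concentration_um)
}
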