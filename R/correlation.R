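# In vitro-in vivo correlation, prediction, saturation/robustness and drug
# profiling. The regression step is plain OLS of E_in vivo on E_predict,
# with one named (or automatically detected) outlier excluded — small
# literature-derived training sets routinely contain one study whose dosing
# or duration is not comparable to the rest.

#' Fit the in vitro-in vivo linear relationship
#'
#' Ordinary least squares of `e_invivo` on `e_predict` after optionally
#' removing one outlier drug. `exclude` may be a drug name, `"none"`, or
#' `"auto"`: automatic mode refits without the point with the largest
#' absolute studentized residual and keeps the exclusion only if it
#' improves R-squared by more than 0.1.
#'
#' @param data Tibble with columns `drug_id`, `e_predict`, `e_invivo`
#'   (at least 4 rows before exclusion).
#' @param exclude Drug name, `"auto"`, or `"none"` (default `"none"`).
#' @return A `fibro_ivivc` object with elements `fit` (the `lm`), `slope`,
#'   `intercept`, `r_squared`, `excluded_drug`, `n_points`, `data`.
#' @export
fit_ivivc <- function(data, exclude = "none") {
  req <- c("drug_id", "e_predict", "e_invivo")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns drug_id, e_predict, e_invivo.")
  }
  if (nrow(data) < 4) abort("Need at least 4 drugs before exclusion.")
  fit_on <- function(d) lm(e_invivo ~ e_predict, data = d)
  excluded <- NA_character_
  if (identical(exclude, "auto")) {
    full <- fit_on(data)
    r <- abs(rstudent(full))
    # a non-finite studentized residual means the remaining points fit
    # perfectly without this one: it is maximally outlying
    r[!is.finite(r)] <- Inf
    cand <- data$drug_id[which.max(r)]
    reduced <- fit_on(data[data$drug_id != cand, , drop = FALSE])
    if (summary(reduced)$r.squared - summary(full)$r.squared > 0.1) {
      excluded <- cand
    }
  } else if (!identical(exclude, "none") && !is.null(exclude)) {
    if (!exclude %in% data$drug_id) {
      abort(paste0("Drug '", exclude, "' not present in `data`."))
    }
    excluded <- exclude
  }
  included <- if (is.na(excluded)) data else data[data$drug_id != excluded, , drop = FALSE]
  if (nrow(included) < 3) abort("Need at least 3 points after exclusion.")
  fit <- fit_on(included)
  structure(
    list(
      fit = fit,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      excluded_drug = excluded,
      n_points = nrow(included),
      data = as_tibble(data)
    ),
    class = "fibro_ivivc"
  )
}

#' @export
print.fibro_ivivc <- function(x, ...) {
  cat("<fibro_ivivc> E_in vivo = ",
    format(x$intercept, digits = 4), " + ",
    format(x$slope, digits = 4), " x E_predict\n",
    sep = ""
  )
  cat(
    " R-squared:", format(x$r_squared, digits = 4), "on", x$n_points, "drugs",
    if (!is.na(x$excluded_drug)) paste0("(excluded: ", x$excluded_drug, ")") else "",
    "\n"
  )
  invisible(x)
}

#' Predict E_in vivo from an E_predict value
#'
#' @param fit A `fibro_ivivc` fit.
#' @param e_predict Non-negative predictor value(s).
#' @return Predicted `E_in vivo` value(s): `intercept + slope x e_predict`.
#' @export
predict_einvivo <- function(fit, e_predict) {
  if (!inherits(fit, "fibro_ivivc")) abort("`fit` must be a fibro_ivivc object.")
  fit$intercept + fit$slope * e_predict
}

#' @export
predict.fibro_ivivc <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(predict(object$fit))
  }
  if (is.data.frame(newdata)) {
    return(predict(object$fit, newdata = newdata))
  }
  predict_einvivo(object, newdata)
}

#' Predict the treated histological score
#'
#' Inverts the in vivo efficacy definition `(Sc - St) x Sc = E` for the
#' treated score: `St = Sc - E / Sc`, clipped to `[0, Sc]`.
#'
#' @param e_invivo_pred Predicted in vivo efficacy.
#' @param sc Untreated control score in `(0, 4]`.
#' @return Predicted treated score in `[0, sc]`.
#' @export
predict_treated_score <- function(e_invivo_pred, sc) {
  if (any(sc <= 0)) abort("`sc` must be positive.")
  if (any(sc > 4)) abort("`sc` must lie in (0, 4].")
  pmin(pmax(sc - e_invivo_pred / sc, 0), sc)
}

#' Group drugs by predictor value into n / p / vp strata
#'
#' The negative (n) group holds exactly the drugs with `e_predict = 0`; the
#' very-positive (vp) group holds the `vp_size` largest positive values
#' (boundary ties broken alphabetically by drug); the positive (p) group is
#' the remainder.
#'
#' @param epredict Tibble with columns `drug_id`, `e_predict`.
#' @param vp_size Size of the vp group (default 7; must be smaller than the
#'   number of drugs with positive `e_predict`).
#' @return Input tibble with an added `group` factor (`n` < `p` < `vp`).
#' @export
assign_groups <- function(epredict, vp_size = 7) {
  if (!all(c("drug_id", "e_predict") %in% names(epredict))) {
    abort("`epredict` needs columns drug_id, e_predict.")
  }
  pos <- epredict |> filter(.data$e_predict > 0)
  if (vp_size >= nrow(pos)) {
    abort(paste0(
      "`vp_size` (", vp_size, ") must be smaller than the number of drugs ",
      "with positive e_predict (", nrow(pos), ")."
    ))
  }
  vp_ids <- pos |>
    arrange(desc(.data$e_predict), .data$drug_id) |>
    slice_head(n = vp_size) |>
    pull("drug_id")
  epredict |>
    mutate(group = factor(
      case_when(
        .data$e_predict == 0 ~ "n",
        .data$drug_id %in% vp_ids ~ "vp",
        .default = "p"
      ),
      levels = c("n", "p", "vp"), ordered = TRUE
    ))
}

#' Principal component analysis of the SAUC matrix
#'
#' PCA of the column-centered (by default unscaled) drugs x markers SAUC
#' matrix, used to find the marker combinations that carry the most
#' variation among effective drugs.
#'
#' @param sauc Tidy SAUC tibble or drugs x markers matrix (>= 2 drugs).
#' @param scale. Scale columns to unit variance before PCA (default
#'   `FALSE`).
#' @return A `fibro_pca` object wrapping [stats::prcomp()] with
#'   `variance_ratio` (descending, sums to 1), `scores` and `loadings`.
#' @export
pca_on_sauc <- function(sauc, scale. = FALSE) {
  S <- sauc_matrix(sauc)
  if (nrow(S) < 2) abort("Need at least 2 drugs for PCA.")
  if (all(apply(S, 2, sd) == 0)) {
    abort("Degenerate SAUC matrix: no variance in any marker column.")
  }
  p <- prcomp(S, center = TRUE, scale. = scale.)
  vr <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      prcomp = p,
      variance_ratio = vr,
      scores = p$x,
      loadings = p$rotation
    ),
    class = "fibro_pca"
  )
}

#' @export
print.fibro_pca <- function(x, ...) {
  k <- min(4, length(x$variance_ratio))
  cat(
    "<fibro_pca> top", k, "components explain",
    format(100 * sum(x$variance_ratio[1:k]), digits = 3), "% of variance\n"
  )
  invisible(x)
}

#' Marker saturation curve: best attainable rho vs panel size
#'
#' For random marker subsets of each requested size, enumerates the weight
#' lattice restricted to the subset and records the best outlier-tolerant
#' Spearman rho attainable against the training index; the mean over
#' subsets traces how quickly predictive power saturates with panel size.
#'
#' @inheritParams optimize_weights
#' @param subset_size Integer vector of panel sizes to probe
#'   (each in `1..n_markers`).
#' @param n_subsets Random subsets drawn per size (default 20; sizes where
#'   fewer distinct subsets exist use all of them).
#' @param seed Integer seed.
#' @return Tibble with columns `subset_size`, `mean_rho`, `sd_rho`.
#' @export
marker_saturation <- function(sauc, training, model = NULL,
                              subset_size, n_subsets = 20, seed = 1L,
                              max_outliers = 1, clip = TRUE) {
  S <- sauc_matrix(sauc)
  if (!is.null(model)) {
    training <- training |> filter(.data$model == !!model)
  }
  common <- intersect(rownames(S), training$drug_id)
  if (length(common) < 4) {
    abort("Need at least 4 training drugs present in both SAUC and in vivo index.")
  }
  S <- S[common, , drop = FALSE]
  y <- training$e_invivo[match(common, training$drug_id)]
  m <- ncol(S)
  if (any(subset_size < 1 | subset_size > m)) {
    abort(paste0("`subset_size` must lie in 1..", m, "."))
  }
  best_for_subset <- function(cols) {
    W <- enumerate_weight_vectors(length(cols))
    E <- S[, cols, drop = FALSE] %*% t(W)
    if (clip) E <- pmax(E, 0)
    max(best_rho_by_column(E, y, max_outliers = max_outliers), na.rm = TRUE)
  }
  withr::with_seed(seed, {
    purrr::map(subset_size, function(s) {
      n_avail <- choose(m, s)
      k <- min(n_subsets, n_avail)
      subsets <- if (n_avail <= n_subsets) {
        utils::combn(m, s, simplify = FALSE)
      } else {
        lapply(seq_len(k), function(i) sort(sample.int(m, s)))
      }
      rhos <- map_dbl(subsets, best_for_subset)
      tibble(
        subset_size = s, mean_rho = mean(rhos),
        sd_rho = if (length(rhos) > 1) sd(rhos) else NA_real_
      )
    }) |> list_rbind()
  })
}

#' Per-group summaries of marker intensity responses
#'
#' For each drug and marker, the mean KR of the chosen intensity feature
#' across concentrations; then, per efficacy group and marker, the boxplot
#' statistics of those per-drug means (median, quartiles, 1.5 x IQR
#' whiskers, and drugs falling outside the whiskers).
#'
#' @param profile KR profile from [compute_kr_profile()].
#' @param groups Group assignment from [assign_groups()] (columns
#'   `drug_id`, `group`).
#' @param feature Intensity feature to summarise (default
#'   `"avg_intensity"`).
#' @return Tibble with one row per (group, marker): `n`, `median`, `q1`,
#'   `q3`, `lower`, `upper`, `n_outliers`, `outliers` (list of drug ids).
#'   Groups with no drugs are absent.
#' @export
group_intensity_summary <- function(profile, groups, feature = "avg_intensity") {
  sel <- profile |> filter(.data$feature == !!feature)
  if (nrow(sel) == 0) {
    abort(paste0("Feature '", feature, "' not found in profile."))
  }
  per_drug <- sel |>
    summarise(mean_kr = mean(.data$kr), .by = c("drug_id", "marker")) |>
    inner_join(groups |> select("drug_id", "group"), by = "drug_id")
  per_drug |>
    summarise(
      n = dplyr::n(),
      median = median(.data$mean_kr),
      q1 = quantile(.data$mean_kr, 0.25, names = FALSE),
      q3 = quantile(.data$mean_kr, 0.75, names = FALSE),
      .by = c("group", "marker")
    ) |>
    mutate(
      lower = .data$q1 - 1.5 * (.data$q3 - .data$q1),
      upper = .data$q3 + 1.5 * (.data$q3 - .data$q1)
    ) |>
    left_join(per_drug, by = c("group", "marker")) |>
    summarise(
      n = .data$n[1], median = .data$median[1], q1 = .data$q1[1],
      q3 = .data$q3[1], lower = .data$lower[1], upper = .data$upper[1],
      outliers = list(.data$drug_id[.data$mean_kr < .data$lower |
        .data$mean_kr > .data$upper]),
      .by = c("group", "marker")
    ) |>
    mutate(n_outliers = lengths(.data$outliers)) |>
    arrange(.data$group, .data$marker)
}
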