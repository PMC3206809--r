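# E_predict: the in vitro efficacy predictor. Per-marker integer weights in
# {0, 1, 2} are optimised by exhaustive enumeration of all 3^m weight
# vectors against a training in vivo index, scoring each candidate with an
# outlier-tolerant Spearman rank criterion; the optimised weight per marker
# is the modal weight among all vectors achieving perfect concordance
# (rho = 1). E_predict itself is the weighted sum of SAUCs, clipped at 0,
# and zeroed for drugs flagged as non-specifically increasing collagen.

#' Enumerate all weight vectors over \{0, 1, 2\}
#'
#' @param n_markers Number of markers (>= 1).
#' @return Integer matrix with `3^n_markers` rows (one weight vector each,
#'   in lexicographic order: first all-0, last all-2) and `n_markers`
#'   columns.
#' @export
enumerate_weight_vectors <- function(n_markers) {
  stopifnot_scalar_num(n_markers, "n_markers", positive = TRUE)
  n_markers <- as.integer(n_markers)
  k <- 0:(3^n_markers - 1)
  vapply(seq_len(n_markers), function(j) {
    as.integer((k %/% 3^(n_markers - j)) %% 3)
  }, integer(length(k)))
}

#' Spearman rank correlation with one allowed outlier
#'
#' Computes Spearman's rho on the full paired sample and, when
#' `max_outliers = 1`, on every leave-one-out subset. If the full-sample rho
#' is already maximal it is returned with no outlier; otherwise the best
#' leave-one-out rho is returned together with the removed index (ties on
#' rho broken by the smallest index). Designed for small training sets
#' where a single aberrant study can mask an otherwise perfect ranking.
#'
#' @param x,y Equal-length numeric vectors (length >= 3; >= 4 when an
#'   outlier may be removed).
#' @param max_outliers 0 or 1.
#' @return List with elements `rho` and `outlier` (removed index, or `NA`).
#' @export
spearman_with_outlier <- function(x, y, max_outliers = 1) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have the same length.")
  if (!max_outliers %in% c(0, 1)) abort("`max_outliers` must be 0 or 1.")
  if (n < 3) abort("Need at least 3 paired observations.")
  if (max_outliers == 1 && n < 4) {
    abort("Need at least 4 paired observations to allow an outlier.")
  }
  rho_full <- suppressWarnings(cor(x, y, method = "spearman"))
  if (max_outliers == 0) {
    return(list(rho = rho_full, outlier = NA_integer_))
  }
  loo <- vapply(seq_len(n), function(i) {
    suppressWarnings(cor(x[-i], y[-i], method = "spearman"))
  }, numeric(1))
  best_loo <- if (all(is.na(loo))) NA_real_ else max(loo, na.rm = TRUE)
  if (is.na(best_loo) ||
    (!is.na(rho_full) && rho_full >= best_loo)) {
    return(list(rho = rho_full, outlier = NA_integer_))
  }
  i <- which(loo == best_loo)[1]
  list(rho = best_loo, outlier = as.integer(i))
}

# Vectorized perfect-concordance test: for an n x K matrix of candidate
# predictor values E and a training vector y, returns a logical K-vector
# that is TRUE where Spearman rho = 1 (strict rank concordance, no ties)
# on the full set or after removing a single drug. Equivalent to calling
# spearman_with_outlier() per column and testing rho == 1, but runs in a
# handful of matrix operations so the full 3^10 lattice stays cheap.
rho1_mask <- function(E, y, max_outliers = 1) {
  n <- length(y)
  ord <- order(y)
  ys <- y[ord]
  Es <- E[ord, , drop = FALSE]
  d <- Es[-1, , drop = FALSE] - Es[-n, , drop = FALSE]
  bad <- d <= 0
  nbad <- .colSums(bad, n - 1, ncol(E))
  y_ok_full <- all(diff(ys) > 0)
  ok <- if (y_ok_full) nbad == 0 else rep(FALSE, ncol(E))
  if (max_outliers >= 1 && n >= 4) {
    for (j in seq_len(n)) {
      if (any(diff(ys[-j]) <= 0)) next
      if (j == 1) {
        okj <- (nbad - bad[1, ]) == 0
      } else if (j == n) {
        okj <- (nbad - bad[n - 1, ]) == 0
      } else {
        okj <- (nbad - bad[j - 1, ] - bad[j, ]) == 0 & (Es[j + 1, ] - Es[j - 1, ] > 0)
      }
      ok <- ok | okj
    }
  }
  ok
}

# best attainable rho (with <= max_outliers removals) per column of E
best_rho_by_column <- function(E, y, max_outliers = 1) {
  n <- length(y)
  ranks <- apply(E, 2, rank)
  rho_of <- function(R, yy) {
    ry <- rank(yy)
    suppressWarnings(as.numeric(cor(R, ry)))
  }
  best <- rho_of(ranks, y)
  if (max_outliers >= 1 && n >= 4) {
    for (i in seq_len(n)) {
      ri <- apply(E[-i, , drop = FALSE], 2, rank)
      best <- pmax(best, rho_of(ri, y[-i]), na.rm = TRUE)
    }
  }
  best
}

#' Optimise per-marker weights against a training in vivo index
#'
#' Enumerates every weight vector in `{0,1,2}^m`, computes the candidate
#' predictor `max(0, sum_m w_m x SAUC_m)` per drug (negatives clipped before
#' the rank test; disable with `clip = FALSE`), and tests it for perfect
#' Spearman concordance (rho = 1, one outlier allowed) with the training
#' `E_in vivo` values. The optimised weight of each marker is the modal
#' weight among all rho = 1 vectors (ties broken toward the smaller
#' weight); the per-marker weight histograms and the count of rho = 1
#' vectors are retained for inspection.
#'
#' @param sauc Tidy SAUC tibble or drugs x markers matrix.
#' @param training In vivo index from [build_invivo_index()].
#' @param model Fibrosis model label selecting the training rows.
#' @param max_outliers 0 or 1 (default 1).
#' @param clip Clip negative candidate values to 0 before the rank test
#'   (default `TRUE`).
#' @return A `fibro_weights` object: list with `weights` (named integer
#'   vector), `rho_achieving_count`, `weight_frequency` (3 x m count
#'   matrix), `n_vectors`, `training_drugs`, `model`.
#' @export
optimize_weights <- function(sauc, training, model = NULL,
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
  W <- enumerate_weight_vectors(m)
  E <- S %*% t(W)
  if (clip) E <- pmax(E, 0)
  mask <- rho1_mask(E, y, max_outliers = max_outliers)
  count <- sum(mask)
  if (count == 0) {
    best <- max(best_rho_by_column(E, y, max_outliers = max_outliers), na.rm = TRUE)
    abort(paste0(
      "No weight vector achieves rho = 1; best rho attained: ",
      format(best, digits = 4)
    ))
  }
  Wg <- W[mask, , drop = FALSE]
  freq <- vapply(seq_len(m), function(j) {
    tabulate(Wg[, j] + 1L, nbins = 3L)
  }, integer(3))
  dimnames(freq) <- list(weight = 0:2, marker = colnames(S))
  weights <- apply(freq, 2, function(cnt) which.max(cnt) - 1L)
  structure(
    list(
      weights = setNames(as.integer(weights), colnames(S)),
      rho_achieving_count = count,
      weight_frequency = freq,
      n_vectors = nrow(W),
      training_drugs = common,
      model = if (is.null(model)) NA_character_ else model
    ),
    class = "fibro_weights"
  )
}

#' @export
print.fibro_weights <- function(x, ...) {
  cat("<fibro_weights> optimised over", x$n_vectors, "weight vectors\n")
  cat(
    " rho = 1 achieved by", x$rho_achieving_count, "vectors (",
    format(100 * x$rho_achieving_count / x$n_vectors, digits = 3), "% )\n"
  )
  cat(" weights:\n")
  print(x$weights)
  invisible(x)
}

#' Compute the in vitro efficacy predictor E_predict
#'
#' `E_predict = max(0, sum_m w_m x SAUC_m)` per drug; drugs flagged as
#' non-specific collagen increasers are assigned 0 outright.
#'
#' @param sauc Tidy SAUC tibble or drugs x markers matrix.
#' @param weights A `fibro_weights` object or named integer vector of
#'   per-marker weights in `{0, 1, 2}`.
#' @param nonspecific Optional tibble (`drug_id`, `nonspecific`) from
#'   [flag_nonspecific()], or a logical vector named by drug.
#' @return Tibble with columns `drug_id`, `e_predict`, `nonspecific`.
#' @export
compute_epredict <- function(sauc, weights, nonspecific = NULL) {
  S <- sauc_matrix(sauc)
  if (inherits(weights, "fibro_weights")) weights <- weights$weights
  if (is.null(names(weights))) {
    if (length(weights) != ncol(S)) {
      abort("Unnamed `weights` must match the number of markers.")
    }
    names(weights) <- colnames(S)
  }
  if (!all(colnames(S) %in% names(weights))) {
    abort("`weights` must cover every marker in the SAUC table.")
  }
  e <- pmax(as.numeric(S %*% weights[colnames(S)]), 0)
  flags <- rep(FALSE, nrow(S))
  if (!is.null(nonspecific)) {
    if (is.data.frame(nonspecific)) {
      flags <- nonspecific$nonspecific[match(rownames(S), nonspecific$drug_id)]
      flags[is.na(flags)] <- FALSE
    } else {
      flags <- as.logical(nonspecific[rownames(S)])
      flags[is.na(flags)] <- FALSE
    }
  }
  e[flags] <- 0
  tibble(drug_id = rownames(S), e_predict = e, nonspecific = flags)
}

#' Flag drugs that non-specifically increase collagen III
#'
#' Some compounds (e.g. cytotoxic cell-cycle blockers) raise collagen III
#' staining with dose without any anti-fibrotic action; their predictor
#' values are not interpretable and are zeroed. A drug is flagged when the
#' KR series of its collagen III total-intensity feature exceeds
#' `kr_threshold` at the top `top_k` concentrations *and* is non-decreasing
#' (within `monotone_tol`) over the upper half of the concentration range.
#' Thresholds are configurable; the defaults trip on a monotone
#' concentration-dependent increase while null drugs (|KR| < 0.05) never
#' flag.
#'
#' @param profile KR profile from [compute_kr_profile()].
#' @param marker Collagen marker name (default `"collagen_III"`).
#' @param feature Intensity feature examined (default `"total_intensity"`).
#' @param kr_threshold KR level that must be exceeded at the top
#'   concentrations (default 0.2).
#' @param top_k Number of top concentrations tested (default 2).
#' @param monotone_tol Allowed decrease between successive KR values in the
#'   upper half (default 0.05).
#' @return Tibble with columns `drug_id`, `nonspecific`.
#' @export
flag_nonspecific <- function(profile, marker = "collagen_III",
                             feature = "total_intensity",
                             kr_threshold = 0.2, top_k = 2,
                             monotone_tol = 0.05) {
  series <- profile |>
    filter(.data$marker == !!marker, .data$feature == !!feature)
  if (nrow(series) == 0) {
    abort(paste0("Marker '", marker, "' / feature '", feature, "' absent from profile."))
  }
  series |>
    arrange(.data$concentration_um) |>
    summarise(
      nonspecific = {
        kr <- .data$kr
        upper <- kr[seq.int(ceiling(length(kr) / 2), length(kr))]
        all(tail(kr, top_k) > kr_threshold) &&
          all(diff(upper) > -monotone_tol)
      },
      .by = "drug_id"
    )
}

#' Robustness of the weight lattice: how often is rho = 1 reached?
#'
#' Fraction of all `3^m` weight vectors achieving perfect concordance with
#' the real training ranks, and the same fraction averaged over `n_random`
#' random permutations of the in vivo ranks (the noise floor). A real
#' in vitro-in vivo signal shows up as the first fraction clearly exceeding
#' the second, meaning the predictor does not depend delicately on one
#' particular weight assignment.
#'
#' @inheritParams optimize_weights
#' @param n_random Number of rank permutations for the random control
#'   (0 for none).
#' @param seed Integer seed for the permutations.
#' @return List with `fraction_rho1` and `random_fraction_rho1` (`NA` when
#'   `n_random = 0`).
#' @export
weight_robustness <- function(sauc, training, model = NULL,
                              n_random = 20, seed = 1L,
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
  W <- enumerate_weight_vectors(ncol(S))
  E <- S %*% t(W)
  if (clip) E <- pmax(E, 0)
  frac <- mean(rho1_mask(E, y, max_outliers = max_outliers))
  rand <- NA_real_
  if (n_random > 0) {
    rand <- withr::with_seed(seed, {
      mean(vapply(seq_len(n_random), function(i) {
        mean(rho1_mask(E, sample(y), max_outliers = max_outliers))
      }, numeric(1)))
    })
  }
  list(fraction_rho1 = frac, random_fraction_rho1 = rand)
}
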