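# broom-style accessors for the fitted objects

#' Tidy an in vitro-in vivo fit
#'
#' @param x A `fibro_ivivc` object.
#' @param ... Unused.
#' @return One row per regression term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.fibro_ivivc <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' Glance at an in vitro-in vivo fit
#'
#' @param x A `fibro_ivivc` object.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `slope`, `intercept`, `n_points`,
#'   `excluded_drug`.
#' @export
glance.fibro_ivivc <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    n_points = x$n_points,
    excluded_drug = x$excluded_drug
  )
}

#' Tidy an optimised weight vector
#'
#' @param x A `fibro_weights` object.
#' @param ... Unused.
#' @return One row per marker: the optimised `weight` and the counts
#'   `n_weight_0/1/2` of each weight among all rho = 1 vectors (the
#'   pie-chart data behind the mode choice).
#' @export
tidy.fibro_weights <- function(x, ...) {
  tibble(
    marker = names(x$weights),
    weight = unname(x$weights),
    n_weight_0 = unname(x$weight_frequency["0", ]),
    n_weight_1 = unname(x$weight_frequency["1", ]),
    n_weight_2 = unname(x$weight_frequency["2", ])
  )
}

#' Glance at an optimised weight vector
#'
#' @param x A `fibro_weights` object.
#' @param ... Unused.
#' @return One-row tibble: `n_vectors`, `rho_achieving_count`,
#'   `fraction_rho1`, `n_training_drugs`, `model`.
#' @export
glance.fibro_weights <- function(x, ...) {
  tibble(
    n_vectors = x$n_vectors,
    rho_achieving_count = x$rho_achieving_count,
    fraction_rho1 = x$rho_achieving_count / x$n_vectors,
    n_training_drugs = length(x$training_drugs),
    model = x$model
  )
}

#' Tidy a SAUC principal component analysis
#'
#' @param x A `fibro_pca` object.
#' @param ... Unused.
#' @return One row per component: `component`, `variance_ratio`,
#'   `cumulative_variance`.
#' @export
tidy.fibro_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$variance_ratio),
    variance_ratio = x$variance_ratio,
    cumulative_variance = cumsum(x$variance_ratio)
  )
}
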