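test_that("the regression without exclusion is textbook OLS", {
  withr::with_seed(71, {
    d <- tibble::tibble(
      drug_id = sprintf("d%d", 1:8),
      e_predict = runif(8, 0, 40000),
      e_invivo = runif(8, 0, 8)
    )
  })
  f <- fit_ivivc(d)
  # closed-form normal equations
  b <- cov(d$e_predict, d$e_invivo) / var(d$e_predict)
  a <- mean(d$e_invivo) - b * mean(d$e_predict)
  expect_equal(f$slope, b)
  expect_equal(f$intercept, a)
  expect_equal(f$r_squared, cor(d$e_predict, d$e_invivo)^2)
  expect_true(is.na(f$excluded_drug))
})

test_that("perfectly collinear points give an exact fit", {
  d <- tibble::tibble(
    drug_id = sprintf("d%d", 1:5),
    e_predict = c(0, 10, 20, 30, 40),
    e_invivo = 1 + 0.2 * c(0, 10, 20, 30, 40)
  )
  f <- fit_ivivc(d)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 0.2)
  expect_equal(f$intercept, 1)
})

test_that("named and automatic outlier exclusion behave as specified", {
  d <- tibble::tibble(
    drug_id = sprintf("d%d", 1:6),
    e_predict = c(0, 10, 20, 30, 40, 5),
    e_invivo = c(1, 3, 5, 7, 9, 20) # d6 breaks an otherwise perfect line
  )
  named <- fit_ivivc(d, exclude = "d6")
  expect_equal(named$excluded_drug, "d6")
  expect_equal(named$r_squared, 1)
  expect_equal(named$n_points, 5)
  auto <- fit_ivivc(d, exclude = "auto")
  expect_equal(auto$excluded_drug, "d6")
  expect_equal(auto$r_squared, 1)
  # auto keeps all points when no removal earns its keep
  clean <- fit_ivivc(d[1:5, ], exclude = "auto")
  expect_true(is.na(clean$excluded_drug))
  expect_error(fit_ivivc(d, exclude = "nope"), "not present")
  expect_error(fit_ivivc(d[1:3, ]), "at least 4")
})

test_that("fixture regressions reach the reported explanatory power", {
  ct <- fit_ivivc(ivivc_fixture("CCl4_treatment"), exclude = "taurine")
  expect_gte(ct$r_squared, 0.9)
  dmn <- fit_ivivc(ivivc_fixture("DMN_treatment"), exclude = "colchicine")
  expect_gte(dmn$r_squared, 0.9)
  cp <- fit_ivivc(ivivc_fixture("CCl4_preventive"), exclude = "PCN")
  expect_lt(cp$r_squared, min(ct$r_squared, dmn$r_squared))
  expect_gte(cp$r_squared, 0.50)
  expect_lte(cp$r_squared, 0.56)
})

test_that("predictions follow the fitted line and invert the index", {
  ct <- fit_ivivc(ivivc_fixture("CCl4_treatment"), exclude = "taurine")
  expect_equal(predict_einvivo(ct, 0), ct$intercept)
  expect_lt(abs(predict_einvivo(ct, 39437) - 5.8), 0.15)
  expect_equal(predict(ct, 1000), ct$intercept + 1000 * ct$slope)
  # treated-score prediction
  expect_equal(round_half_out(predict_treated_score(5.8, 3.0), 1), 1.1)
  expect_equal(predict_treated_score(0, 2.5), 2.5)
  expect_equal(predict_treated_score(9, 3), 0) # e = sc^2, maximal effect
  expect_error(predict_treated_score(1, 0), "positive")
  # inversion: efficacy_index(sc, St(e, sc)) = e on interior solutions
  for (e in c(0.5, 2, 4)) {
    st <- predict_treated_score(e, 3)
    expect_equal(efficacy_index(3, st), e)
  }
})

test_that("drug grouping partitions by predictor value", {
  ep <- load_published_epredict()
  g <- assign_groups(ep, vp_size = 7)
  expect_equal(sum(g$group == "n"), 16)
  expect_setequal(
    g$drug_id[g$group == "vp"],
    c(
      "sulfasalazine", "pioglitazone", "glycyrrhizin", "staurosporine",
      "berberine chloride", "rosmarinic acid", "bortezomib"
    )
  )
  expect_equal(sum(g$group == "p"), 49 - 16 - 7)
  # n group is exactly the zero-predictor drugs
  expect_setequal(g$drug_id[g$group == "n"], ep$drug_id[ep$e_predict == 0])
  zeros <- tibble::tibble(drug_id = c("a", "b"), e_predict = c(0, 0))
  expect_error(assign_groups(zeros, vp_size = 1), "positive")
})

test_that("PCA of the SAUC matrix is a proper variance decomposition", {
  s <- panel_screen()
  p <- pca_on_sauc(s$sauc)
  expect_equal(sum(p$variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_ratio) <= 1e-12))
  # rank-1 matrix: first component explains everything
  r1 <- outer(c(1, 2, 3, 4), c(1, 0.5, 0.25, 0.1, 0.05))
  dimnames(r1) <- list(sprintf("d%d", 1:4), sprintf("m%d", 1:5))
  expect_equal(pca_on_sauc(r1)$variance_ratio[1], 1)
  # apoptosis-dominant panel: PC1 loads mainly on the mito marker
  withr::with_seed(73, {
    S <- matrix(rnorm(8 * 10, sd = 5), 8, 10,
      dimnames = list(sprintf("d%d", 1:8), fibrosis_markers())
    )
    S[, "mito_potential"] <- S[, "mito_potential"] + c(0, 40, 80, 120, 160, 200, 240, 280)
  })
  p2 <- pca_on_sauc(S)
  expect_equal(
    which.max(abs(p2$loadings[, 1])),
    which(fibrosis_markers() == "mito_potential"),
    ignore_attr = TRUE
  )
  flat <- matrix(5, 3, 4, dimnames = list(letters[1:3], letters[4:7]))
  expect_error(pca_on_sauc(flat), "Degenerate")
})

test_that("the marker saturation curve saturates at the full panel", {
  s <- panel_screen()
  idx <- build_invivo_index(generate_invivo(s$panel, noise_sd = 0, seed = 24))
  full <- marker_saturation(s$sauc, idx,
    subset_size = 10, n_subsets = 1, seed = 1
  )
  # with all markers allowed, the best rho equals the full-panel optimum
  S <- sauc_matrix(s$sauc)
  W <- enumerate_weight_vectors(10)
  E <- pmax(S %*% t(W), 0)
  y <- idx$e_invivo[match(rownames(S), idx$drug_id)]
  best <- max(fibroscore:::best_rho_by_column(E, y), na.rm = TRUE)
  expect_equal(full$mean_rho, best)
  # mean rho does not decrease with panel size
  curve <- marker_saturation(s$sauc, idx,
    subset_size = c(1, 4, 10), n_subsets = 8, seed = 2
  )
  expect_true(all(diff(curve$mean_rho) > -0.05))
  expect_error(
    marker_saturation(s$sauc, idx, subset_size = 0),
    "subset_size"
  )
})

test_that("group intensity summaries expose outliers and tight groups", {
  mk <- function(ids, krs) {
    tidyr::expand_grid(drug_id = ids, concentration_um = c(1, 2)) |>
      dplyr::mutate(
        marker = "caspase3", feature = "avg_intensity",
        kr = rep(krs, each = 2), modality = "unimodal"
      )
  }
  ids <- sprintf("d%02d", 1:11)
  krs <- c(0, 0, 0, 0, 0.1, 0.12, 0.14, 5, 0.5, 0.51, 0.52)
  prof <- mk(ids, krs)
  groups <- tibble::tibble(
    drug_id = ids,
    group = factor(c(rep("n", 4), rep("p", 4), rep("vp", 3)),
      levels = c("n", "p", "vp"), ordered = TRUE
    )
  )
  per_group <- group_intensity_summary(prof, groups)
  pooled <- group_intensity_summary(
    prof,
    dplyr::mutate(groups, group = factor("all"))
  )
  vp <- per_group[per_group$group == "vp", ]
  expect_equal(vp$n_outliers, 0)
  expect_gte(pooled$n_outliers, 1)
  expect_true("d08" %in% pooled$outliers[[1]])
  # a single-drug group reports that drug's value as its median
  solo <- group_intensity_summary(
    mk("only", 0.3),
    tibble::tibble(drug_id = "only", group = factor("vp"))
  )
  expect_equal(solo$median, 0.3)
  expect_equal(solo$n_outliers, 0)
  # all-zero KR gives all-zero summaries
  zero <- group_intensity_summary(mk(ids[1:3], c(0, 0, 0)), groups[1:3, ])
  expect_true(all(zero$median == 0 & zero$q1 == 0 & zero$q3 == 0))
})
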