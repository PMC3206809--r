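test_that("weight enumeration is exhaustive, unique and lexicographic", {
  expect_equal(nrow(enumerate_weight_vectors(1)), 3)
  W2 <- enumerate_weight_vectors(2)
  expect_equal(nrow(W2), 9)
  expect_equal(W2[1, ], c(0L, 0L))
  expect_equal(W2[9, ], c(2L, 2L))
  expect_equal(anyDuplicated(W2), 0)
  expect_equal(nrow(enumerate_weight_vectors(10)), 59049)
})

test_that("outlier-tolerant Spearman matches its examples", {
  r <- spearman_with_outlier(1:6, 1:6)
  expect_equal(r$rho, 1)
  expect_true(is.na(r$outlier))
  r <- spearman_with_outlier(1:5, c(1, 2, 3, 4, 0))
  expect_equal(r$rho, 1)
  expect_equal(r$outlier, 5L)
  r <- spearman_with_outlier(1:5, 5:1)
  expect_equal(r$rho, -1) # no single removal fixes a full reversal
  expect_error(spearman_with_outlier(1:2, 1:2), "at least")
  expect_error(spearman_with_outlier(1:3, 1:3, max_outliers = 1), "at least 4")
})

test_that("allowing an outlier never lowers the correlation", {
  withr::with_seed(55, {
    for (i in 1:1000) {
      x <- sample(6)
      y <- sample(6)
      plain <- cor(x, y, method = "spearman")
      expect_gte(spearman_with_outlier(x, y, 1)$rho, plain)
    }
  })
})

test_that("outlier-tolerant Spearman agrees with the naive oracle", {
  withr::with_seed(56, {
    for (i in 1:200) {
      x <- rnorm(sample(4:8, 1))
      y <- rnorm(length(x))
      expect_equal(
        spearman_with_outlier(x, y)$rho,
        oracle_spearman_outlier(x, y)$rho
      )
    }
  })
})

test_that("the fast rho = 1 mask equals per-column Spearman evaluation", {
  withr::with_seed(57, {
    for (rep in 1:20) {
      n <- sample(4:7, 1)
      K <- 40
      E <- matrix(rnorm(n * K), n, K)
      E[, 1:10] <- pmax(E[, 1:10], 0) # inject ties at zero
      y <- rnorm(n)
      mask <- fibroscore:::rho1_mask(E, y)
      ref <- vapply(seq_len(K), function(k) {
        r <- oracle_spearman_outlier(E[, k], y)$rho
        !is.na(r) && r > 1 - 1e-9
      }, logical(1))
      expect_identical(mask, ref)
    }
  })
})

test_that("optimization matches a naive brute-force reimplementation", {
  withr::with_seed(58, {
    for (rep in 1:10) {
      n_drugs <- sample(4:6, 1)
      m <- sample(2:3, 1)
      S <- matrix(runif(n_drugs * m, 10, 100), n_drugs, m,
        dimnames = list(sprintf("d%d", 1:n_drugs), sprintf("m%d", 1:m))
      )
      # guarantee at least one achieving vector: order y like one candidate
      w0 <- sample(0:2, m, replace = TRUE)
      if (all(w0 == 0)) w0[1] <- 1
      y <- as.numeric(S %*% w0)
      training <- tibble::tibble(
        drug_id = rownames(S), model = "CCl4_treatment", e_invivo = y
      )
      got <- optimize_weights(S, training, model = "CCl4_treatment")
      ref <- oracle_optimize(S, y)
      expect_equal(unname(got$weights), ref$weights)
      expect_equal(got$rho_achieving_count, ref$count)
      expect_equal(unname(got$weight_frequency), unname(ref$freq))
    }
  })
})

test_that("a rank-informative marker receives a positive weight", {
  # marker 1 rank-identical to the training index, marker 2 anti-correlated
  S <- cbind(
    m1 = c(10, 20, 30, 40, 50),
    m2 = c(5, 4, 3, 2, 1) * 10
  )
  rownames(S) <- sprintf("d%d", 1:5)
  training <- tibble::tibble(
    drug_id = rownames(S), model = "x", e_invivo = 1:5
  )
  w <- optimize_weights(S, training, model = "x")
  expect_gt(w$weights[["m1"]], 0)
  # histogram mass sums to the achieving count for every marker
  expect_true(all(colSums(w$weight_frequency) == w$rho_achieving_count))
})

test_that("optimization fails loudly when no vector reaches rho = 1", {
  S <- cbind(m1 = c(1, 2, 3, 4), m2 = c(2, 1, 4, 3))
  rownames(S) <- sprintf("d%d", 1:4)
  training <- tibble::tibble(
    drug_id = rownames(S), model = "x",
    e_invivo = c(4, 3, 1, 2) # no weighting can rank this, even loo
  )
  expect_error(
    optimize_weights(S, training, model = "x", max_outliers = 0),
    "best rho"
  )
})

test_that("E_predict is the clipped weighted SAUC combination", {
  S <- rbind(
    d1 = c(100, 50, 999, rep(0, 7)),
    d2 = c(-300, 100, 0, rep(0, 7))
  )
  colnames(S) <- fibrosis_markers()
  w <- setNames(c(2L, 1L, 0L, rep(0L, 7)), colnames(S))
  ep <- compute_epredict(S, w)
  expect_equal(ep$e_predict[ep$drug_id == "d1"], 250)
  expect_equal(ep$e_predict[ep$drug_id == "d2"], 0) # -500 clipped
  expect_equal(compute_epredict(S, setNames(rep(0L, 10), colnames(S)))$e_predict, c(0, 0))
  # positively homogeneous of degree 1 before clipping
  expect_equal(compute_epredict(S * 3, w)$e_predict, 3 * ep$e_predict)
  # non-specific flag forces zero
  ns <- tibble::tibble(drug_id = "d1", nonspecific = TRUE)
  expect_equal(compute_epredict(S, w, nonspecific = ns)$e_predict[1], 0)
})

test_that("non-specific collagen increases are flagged, nulls are not", {
  mk_profile <- function(kr) {
    tibble::tibble(
      drug_id = "d", marker = "collagen_III", feature = "total_intensity",
      concentration_um = 1:6, kr = kr, modality = "unimodal"
    )
  }
  rising <- mk_profile(c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) # aphidicolin-like
  expect_true(flag_nonspecific(rising)$nonspecific)
  falling <- mk_profile(-c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5))
  expect_false(flag_nonspecific(falling)$nonspecific)
  null <- mk_profile(c(0.03, -0.02, 0.04, -0.01, 0.02, 0.04))
  expect_false(flag_nonspecific(null)$nonspecific)
  expect_error(flag_nonspecific(rising, marker = "caspase3"), "absent")
})

test_that("weight robustness is maximal for a perfectly aligned panel", {
  # every marker rank-identical to the training index: every non-zero
  # weight vector achieves rho = 1
  S <- matrix(rep(c(1, 2, 3, 4, 5) * 10, 10), ncol = 10,
    dimnames = list(sprintf("d%d", 1:5), fibrosis_markers())
  )
  training <- tibble::tibble(
    drug_id = rownames(S), model = "x", e_invivo = 1:5
  )
  rb <- weight_robustness(S, training, model = "x", n_random = 0)
  expect_equal(rb$fraction_rho1, (3^10 - 1) / 3^10)
  expect_true(is.na(rb$random_fraction_rho1))
})
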