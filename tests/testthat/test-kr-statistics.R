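test_that("modality classification separates clear cases", {
  withr::with_seed(101, {
    gauss <- rnorm(1000)
    far <- c(rnorm(500, 0, 1), rnorm(500, 6, 1)) # modes 6 sd apart
    near <- c(rnorm(500, 0, 1), rnorm(500, 1, 1)) # components 1 sd apart
  })
  expect_identical(classify_modality(gauss), "unimodal")
  expect_identical(classify_modality(far), "bimodal")
  expect_identical(classify_modality(near), "unimodal")
  expect_error(classify_modality(rnorm(10)), "at least 50")
})

test_that("signed KS score matches its construction on extreme samples", {
  expect_equal(signed_ks_score(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signed_ks_score(rep(1, 4), rep(0, 4)), 1)
  expect_equal(signed_ks_score(rep(0, 4), rep(1, 4)), -1)
  expect_error(signed_ks_score(numeric(), 1:3), "non-empty")
})

test_that("signed KS score is antisymmetric and bounded", {
  withr::with_seed(42, {
    for (i in 1:25) {
      a <- sample(0:5, sample(3:12, 1), replace = TRUE)
      b <- sample(0:5, sample(3:12, 1), replace = TRUE)
      s_ab <- signed_ks_score(a, b)
      expect_lte(abs(s_ab), 1)
      expect_equal(signed_ks_score(a, a), 0)
      if (median(a) != median(b)) {
        expect_equal(signed_ks_score(b, a), -s_ab)
      }
    }
  })
})

test_that("signed KS agrees with a brute-force ECDF oracle on small samples", {
  # exhaustive over all samples of size <= 3 on {0,1,2}
  vals <- list()
  for (n in 1:3) {
    grids <- rep(list(0:2), n)
    vals <- c(vals, asplit(as.matrix(expand.grid(grids)), 1))
  }
  for (a in vals) {
    for (b in vals) {
      expect_equal(signed_ks_score(a, b), oracle_signed_ks(a, b))
    }
  }
  # random larger samples up to size 8 on the same alphabet
  withr::with_seed(7, {
    for (i in 1:500) {
      a <- sample(0:2, sample(1:8, 1), replace = TRUE)
      b <- sample(0:2, sample(1:8, 1), replace = TRUE)
      expect_equal(signed_ks_score(a, b), oracle_signed_ks(a, b))
    }
  })
})

test_that("KS magnitude agrees with stats::ks.test on tie-free samples", {
  withr::with_seed(9, {
    for (i in 1:20) {
      a <- rnorm(40)
      b <- rnorm(35, mean = runif(1, -1, 1))
      expect_equal(
        abs(signed_ks_score(a, b)),
        unname(suppressWarnings(stats::ks.test(a, b)$statistic))
      )
    }
  })
})

test_that("bimodal ratio score is the difference of positive fractions", {
  ctrl <- c(rep(0, 8), rep(10, 2)) # 20% positive above 5
  trt <- c(rep(0, 2), rep(10, 8)) # 80% positive
  expect_equal(bimodal_ratio_score(trt, ctrl, 5), 0.6)
  expect_equal(bimodal_ratio_score(ctrl, ctrl, 5), 0)
  expect_equal(bimodal_ratio_score(rep(0, 5), rep(10, 5), 5), -1)
  expect_warning(bimodal_ratio_score(trt, ctrl, 99), "outside")
})

test_that("the KR profile has one entry per condition and stays in [-1, 1]", {
  des <- screen_design(
    n_concentrations = 11, markers = "caspase3",
    features_per_marker = 16, cells_per_condition = 150, seed = 31
  )
  panel <- synthetic_drug_panel(n_drugs = 1, markers = "caspase3", seed = 31)
  prof <- compute_kr_profile(generate_screen(panel, des))
  expect_equal(nrow(prof), 1 * 10 * 1 * 16)
  expect_true(all(abs(prof$kr) <= 1))
  expect_equal(
    unique(prof[, c("marker", "feature", "modality")])$modality |> unique(),
    "unimodal"
  )
})

test_that("KR responds monotonically to a Hill-shaped true effect", {
  des <- screen_design(
    n_concentrations = 6, markers = "caspase3",
    features_per_marker = 4, cells_per_condition = 800, seed = 32
  )
  panel <- synthetic_drug_panel(
    n_drugs = 1, true_efficacy = 1, markers = "caspase3",
    susceptibility = list(c(caspase3 = 1)), seed = 32
  )
  prof <- compute_kr_profile(generate_screen(panel, des))
  for (d in split(prof, prof$feature)) {
    d <- d[order(d$concentration_um), ]
    expect_true(all(diff(abs(d$kr)) > -0.1))
  }
})

test_that("bimodal features are detected and scored through the profile", {
  s <- tiny_screen()
  brdu <- s$profile[s$profile$marker == "BrdU", ]
  expect_setequal(
    unique(brdu$feature[brdu$modality == "bimodal"]),
    c("avg_intensity", "total_intensity")
  )
  # strongest drug suppresses the positive (proliferating) fraction
  top_drug <- s$panel$drug_id[which.max(s$panel$true_efficacy)]
  top <- brdu[brdu$drug_id == top_drug & brdu$modality == "bimodal", ]
  expect_lt(min(top$kr[top$concentration_um == max(top$concentration_um)]), -0.2)
})
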