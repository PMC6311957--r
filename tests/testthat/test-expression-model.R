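test_that("quartile labelling takes equal top/bottom 25% with ties by id", {
  expr <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:8))
  lab <- quartile_labels(expr)
  expect_equal(lab$n_high, 2L)
  expect_equal(lab$n_low, 2L)
  expect_setequal(names(lab$labels)[lab$labels == "high"], c("g1", "g2"))
  expect_setequal(names(lab$labels)[lab$labels == "low"], c("g7", "g8"))
  expect_equal(lab$fpkm_high_min, 7)
  expect_equal(lab$fpkm_low_max, 2)
  expect_error(quartile_labels(setNames(rep(1, 8), paste0("g", 1:8))),
               "degenerate")
  expect_error(quartile_labels(c(a = 1, b = 2)), "at least 4")
})

test_that("labels equal a rank-based oracle on random expression", {
  set.seed(61)
  expr <- setNames(round(rexp(100, 0.2), 4), sprintf("g%03d", 1:100))
  lab <- quartile_labels(expr)
  rk <- rank(-expr, ties.method = "first")  # ids are already sorted
  expect_setequal(names(lab$labels)[lab$labels == "high"],
                  names(expr)[rk <= 25])
  expect_setequal(names(lab$labels)[lab$labels == "low"],
                  names(expr)[rk > 75])
})

test_that("evaluation metrics implement Sn, Sp and balanced accuracy", {
  m <- evaluate_metrics(100, 100, 0, 0)
  expect_equal(c(m$sn, m$sp, m$acc), c(1, 1, 1))
  m <- evaluate_metrics(0, 100, 0, 100)
  expect_equal(c(m$sn, m$sp, m$acc), c(0, 1, 0.5))
  m <- evaluate_metrics(80, 60, 40, 20)
  expect_equal(c(m$sn, m$sp, m$acc), c(0.8, 0.6, 0.7))
  expect_error(evaluate_metrics(0, 5, 5, 0), "no positive")
  expect_error(evaluate_metrics(5, 0, 0, 5), "no negative")
})

test_that("fold assignment is stratified, deterministic, and seed-sensitive", {
  lab <- structure(list(labels = factor(rep(c("high", "low"), each = 50),
                                        levels = c("high", "low"))),
                   class = "ExpressionLabels")
  f1 <- cochip:::.make_folds(lab$labels, 5, seed = 9)
  f2 <- cochip:::.make_folds(lab$labels, 5, seed = 9)
  f3 <- cochip:::.make_folds(lab$labels, 5, seed = 10)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  for (k in 1:5) {
    expect_equal(sum(f1 == k & lab$labels == "high"), 10L)
    expect_equal(sum(f1 == k & lab$labels == "low"), 10L)
  }
})

test_that("feature scaling uses training-fold statistics only", {
  set.seed(62)
  tr <- matrix(rnorm(40, mean = 5), 20, 2)
  te <- matrix(rnorm(10, mean = 5), 5, 2)
  sc1 <- cochip:::.scale_train_test(tr, te)
  te2 <- te
  te2[1, ] <- te2[1, ] + 100  # perturbing test data must not move the scaler
  sc2 <- cochip:::.scale_train_test(tr, te2)
  expect_identical(sc1$train, sc2$train)
  expect_equal(sc2$test[-1, ], sc1$test[-1, ])
  expect_equal(colMeans(sc1$train), c(0, 0), tolerance = 1e-12)
})

test_that("SVM scan separates a deterministic driver and validates input", {
  cfg <- simulation_config(n_genes = 200, n_factors = 2,
                           peaks_per_factor = 800, tss_enrichment = 0.9,
                           driver_factors = "TF01", seed = 63)
  sim <- simulate_genome(cfg)
  genes <- filter_nonoverlapping_genes(sim$genes)
  a <- tfas_matrix(sim$tracks$GM12878, genes)
  expr <- simulate_expression(genes, a, "TF01", noise_sd = 0, seed = 63)
  lab <- quartile_labels(expr)
  res <- svm_scan(a, lab, feature_sets = list(TF01 = "TF01"), seed = 1)
  expect_gte(res$acc, 0.99)
  expect_error(svm_scan(a, lab, feature_sets = list(bad = "NOPE")),
               "unknown factor")
  expect_error(svm_scan(a, lab, feature_sets = list(empty = character())),
               "empty feature set")
  # the all-factor model cannot do worse than chance on the same folds
  res_all <- svm_scan(a, lab, feature_sets = list(all = c("TF01", "TF02")),
                      seed = 1)
  expect_gte(res_all$acc, 0.5)
})

test_that("a pure-noise feature barely moves the noise-free benchmark", {
  cfg <- simulation_config(n_genes = 200, n_factors = 3,
                           peaks_per_factor = 800, tss_enrichment = 0.9,
                           driver_factors = "TF01", seed = 64)
  sim <- simulate_genome(cfg)
  genes <- filter_nonoverlapping_genes(sim$genes)
  a <- tfas_matrix(sim$tracks$GM12878, genes)
  expr <- simulate_expression(genes, a, "TF01", noise_sd = 0, seed = 64)
  lab <- quartile_labels(expr)
  res <- svm_scan(a, lab,
                  feature_sets = list(drv = "TF01",
                                      with_noise = c("TF01", "TF03")),
                  seed = 2)
  expect_lt(abs(res$acc[1] - res$acc[2]), 0.03)
})

test_that("prediction difference index and dynamics correlation behave", {
  expect_equal(prediction_difference(0.7, 0.7), 0)
  expect_equal(prediction_difference(0.9, 0.6), 0.2)
  expect_equal(prediction_difference(0.6, 0.9),
               -prediction_difference(0.9, 0.6))
  expect_error(prediction_difference(0, 0), "zero")
  d <- c(-0.5, 0, 0.2, 0.6)
  expect_equal(correlate_dynamics(d, d), 1.0)
  set.seed(65)
  expect_lt(abs(correlate_dynamics(rnorm(1000), rnorm(1000))), 0.1)
})
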