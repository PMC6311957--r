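test_that("config validation rejects inconsistent plantings", {
  expect_error(simulation_config(planted_pairs = list(
    list(factor_a = "TF01", factor_b = "TF02", co_rate = 1.5))),
    "co_rate")
  expect_error(simulation_config(planted_enrichment = c(TF01 = -2)),
               "f_true")
  expect_error(simulation_config(
    planted_pairs = list(list(factor_a = "TF01", factor_b = "TF02",
                              co_rate = 0.5)),
    planted_enrichment = c(TF01 = 2)),
    "both pair-planted and enrichment-planted")
  expect_error(simulation_config(driver_factors = "NOPE"), "unknown driver")
  # grid peaks must fit the chromosome
  expect_error(simulation_config(
    n_genes = 2, gene_spacing = 41000, peaks_per_factor = 100000,
    planted_pairs = list(list(factor_a = "TF01", factor_b = "TF02",
                              co_rate = 1))),
    "infeasible")
})

test_that("generation is deterministic given config and seed", {
  cfg <- simulation_config(n_genes = 30, n_factors = 2,
                           peaks_per_factor = 200, seed = 71)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  s3 <- simulate_genome(simulation_config(n_genes = 30, n_factors = 2,
                                          peaks_per_factor = 200,
                                          seed = 72))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("genes are spaced so the overlap filter keeps all by default", {
  cfg <- simulation_config(n_genes = 40, seed = 73)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(filter_nonoverlapping_genes(sim$genes)), 40L)
})

test_that("co_rate extremes give exact overlap ratios", {
  mk <- function(co) simulate_genome(simulation_config(
    n_genes = 20, n_factors = 2, peaks_per_factor = 300,
    planted_pairs = list(list(factor_a = "TF01", factor_b = "TF02",
                              co_rate = co)),
    seed = 74))
  s1 <- mk(1)
  expect_equal(overlap_ratio(s1$tracks$GM12878$TF01,
                             s1$tracks$GM12878$TF02)$r_o, 1.0)
  s0 <- mk(0)
  expect_equal(overlap_ratio(s0$tracks$GM12878$TF01,
                             s0$tracks$GM12878$TF02)$r_o, 0.0)
})

test_that("roundtrip through files reproduces the in-memory tracks", {
  cfg <- simulation_config(n_genes = 20, n_factors = 2, hm_factors = "TF02",
                           peaks_per_factor = 100, seed = 75)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  np <- read_narrowpeak(file.path(d, "GM12878", "TF01.narrowPeak"),
                        cell_line = "GM12878")
  expect_equal(np$peaks$start, sim$tracks$GM12878$TF01$peaks$start)
  expect_equal(np$peaks$signal, sim$tracks$GM12878$TF01$peaks$signal)
  bp <- read_broadpeak(file.path(d, "GM12878", "TF02.broadPeak"))
  expect_equal(bp$peaks$end, sim$tracks$GM12878$TF02$peaks$end)
  genes <- read_gene_annotation(file.path(d, "genes.tsv"))
  expect_equal(as.data.frame(genes), as.data.frame(sim$genes))
})

test_that("noise-free expression is a monotone function of driver TFAS", {
  cfg <- simulation_config(n_genes = 100, n_factors = 2,
                           peaks_per_factor = 400, tss_enrichment = 0.9,
                           driver_factors = "TF01", seed = 76)
  sim <- simulate_genome(cfg)
  genes <- filter_nonoverlapping_genes(sim$genes)
  a <- tfas_matrix(sim$tracks$GM12878, genes)
  expr <- simulate_expression(genes, a, "TF01", noise_sd = 0, seed = 76)
  expect_equal(order(expr), order(a[, "TF01"]))
  expect_true(all(expr > 0))
  expect_error(simulate_expression(genes, a, "NOPE"), "unknown driver")
})

test_that("non-driver factors predict at chance under the null", {
  accs <- sapply(81:88, function(seed) {
    cfg <- simulation_config(n_genes = 400, n_factors = 2,
                             peaks_per_factor = 800, tss_enrichment = 0.9,
                             driver_factors = "TF01", seed = seed)
    sim <- simulate_genome(cfg)
    genes <- filter_nonoverlapping_genes(sim$genes)
    a <- tfas_matrix(sim$tracks$GM12878, genes)
    expr <- simulate_expression(genes, a, "TF01", noise_sd = 0, seed = seed)
    svm_scan(a, quartile_labels(expr),
             feature_sets = list(null = "TF02"), seed = seed)$acc
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})
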