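peak <- function(start, end, chrom = "chr1") {
  list(chrom = chrom, start = start, end = end)
}

test_that("midpoint overlap predicate is strict and chromosome-aware", {
  expect_true(peaks_overlap(peak(75, 125), peak(95, 145)))   # 20 < 50
  expect_true(peaks_overlap(peak(75, 125), peak(75, 125)))   # identity
  expect_false(peaks_overlap(peak(-25, 25), peak(75, 125)))  # 100 !< 50
  # touching half-widths: |50 - 0| = (50+50)/2, strictly not an overlap
  expect_false(peaks_overlap(peak(-25, 25), peak(25, 75)))
  expect_false(peaks_overlap(peak(0, 100), peak(0, 100, chrom = "chr2")))
})

test_that("overlap ratio handles self, disjoint, and worked examples", {
  a <- make_track(c(0L, 200L), c(100L, 300L), name = "A")
  b <- make_track(c(50L, 400L), c(150L, 500L), name = "B")
  expect_equal(overlap_ratio(a, a)$r_o, 1.0)
  far <- make_track(c(10000L, 20000L), c(10100L, 20100L), name = "F")
  expect_equal(overlap_ratio(a, far)$r_o, 0.0)
  # A1 overlaps B1 only: n = (1 + 1)/2 = 1, r_o = 2/(2+2)
  ro <- overlap_ratio(a, b)
  expect_equal(ro$n_overlap, 1)
  expect_equal(ro$r_o, 0.5)
  expect_equal(overlap_ratio(b, a)$r_o, ro$r_o)  # symmetric
  expect_error(overlap_ratio(make_track(integer(), integer()),
                             make_track(integer(), integer())), "empty")
})

test_that("engine matches the brute-force oracle on random track pairs", {
  set.seed(41)
  for (rep in 1:25) {
    a <- random_track(sample(5:40, 1), chrom_length = 2e4,
                      chroms = c("chr1", "chr2"), name = "A")
    b <- random_track(sample(5:40, 1), chrom_length = 2e4,
                      chroms = c("chr1", "chr2"), name = "B")
    expect_equal(overlap_ratio(a, b)$r_o, oracle_overlap_ratio(a, b))
  }
})

test_that("covering a previously unmatched A peak raises R_o's numerator", {
  # A peaks on a sparse grid; B covers the first two only
  a <- make_track(seq(0L, 9000L, 1000L), seq(100L, 9100L, 1000L), name = "A")
  b <- make_track(c(0L, 1000L), c(100L, 1100L), name = "B")
  hit <- overlap_ratio(a, b)$n_overlap
  b2 <- factor_track(rbind(b$peaks[, 1:3],
                           data.frame(chrom = "chr1", start = 5000L,
                                      end = 5100L)), "B")
  expect_gt(overlap_ratio(a, b2)$n_overlap, hit)
})

test_that("region restriction filters by peak center", {
  a <- make_track(c(0L, 10000L), c(100L, 10100L), name = "A")
  b <- make_track(c(40L, 10040L), c(140L, 10140L), name = "B")
  whole <- data.frame(chrom = "chr1", start = 0L, end = 1e6L)
  expect_equal(overlap_ratio_in_regions(a, b, whole)$r_o,
               overlap_ratio(a, b)$r_o)
  left <- data.frame(chrom = "chr1", start = 0L, end = 5000L)
  ro <- overlap_ratio_in_regions(a, b, left)
  expect_equal(ro$n_a, 1L)
  expect_equal(ro$r_o, 1.0)
  nowhere <- data.frame(chrom = "chr9", start = 0L, end = 100L)
  expect_error(overlap_ratio_in_regions(a, b, nowhere),
               class = "cochip_empty_restriction")
})

test_that("relative variation index matches direct evaluation", {
  expect_equal(relative_variation(0.3, 0.3), 0)
  expect_equal(relative_variation(0, 0), 0)  # alpha guards the denominator
  expect_equal(relative_variation(0.366, 0.071), 0.6735,
               tolerance = 0.0001)
  expect_equal(relative_variation(0.2, 0.5),
               -relative_variation(0.5, 0.2))
  expect_true(abs(relative_variation(1, 0)) <= 1)
})

test_that("outlier flagging uses the population mean +/- 2 sd band", {
  same <- data.frame(i_rv = rep(0.2, 10))
  expect_false(any(outlier_pairs(same)$is_outlier))
  one <- data.frame(i_rv = c(rep(0.001, 30) + seq(0, 0.0029, 1e-4), 0.9))
  flagged <- outlier_pairs(one)
  expect_equal(which(flagged$is_outlier), 31L)
  # Gaussian i_rv: ~4.6% outside the 2 sd band
  set.seed(43)
  frac <- replicate(5, {
    mean(outlier_pairs(data.frame(i_rv = rnorm(1000)))$is_outlier)
  })
  expect_lt(abs(mean(frac) - 0.0455), 0.015)
})

test_that("average overlap ratio counts distinct factors per peak", {
  a <- make_track(c(0L, 1000L), c(100L, 1100L), name = "A")
  others_far <- list(make_track(5000L, 5100L, name = "B"),
                     make_track(7000L, 7100L, name = "C"))
  expect_equal(average_overlap_ratio(a, others_far)$r_av, 0)
  others_all <- list(make_track(c(10L, 1010L), c(110L, 1110L), name = "B"),
                     make_track(c(20L, 1020L), c(120L, 1120L), name = "C"))
  expect_equal(average_overlap_ratio(a, others_all)$r_av, 1)
  # one peak overlapped by exactly 2 of 54 other factors
  single <- make_track(0L, 100L, name = "S")
  panel <- c(list(make_track(10L, 110L, name = "o1"),
                  make_track(20L, 120L, name = "o2")),
             lapply(3:54, function(i) {
               make_track(90000L + i * 1000L, 90100L + i * 1000L,
                          name = paste0("o", i))
             }))
  expect_equal(average_overlap_ratio(single, panel)$r_av, 2 / 54)
})

test_that("triple mining equals exhaustive clique enumeration", {
  # all three pairs above threshold -> one triple
  pt <- data.frame(factor_a = c("A", "A", "B"), factor_b = c("B", "C", "C"),
                   r_o = c(0.7, 0.7, 0.7))
  got <- mine_combinations(pt)
  expect_equal(got$members, "A+B+C")
  expect_equal(got$min_r_o, 0.7)
  # chain A-B, B-C above threshold but A-C below -> no triple
  pt$r_o <- c(0.7, 0.1, 0.7)
  expect_equal(nrow(mine_combinations(pt)), 0L)
  # random 10-factor graph vs combn enumeration
  set.seed(44)
  fac <- LETTERS[1:10]
  cmb <- combn(fac, 2)
  pt <- data.frame(factor_a = cmb[1, ], factor_b = cmb[2, ],
                   r_o = round(runif(ncol(cmb)), 2))
  got <- mine_combinations(pt, k = 3, threshold = 0.5)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- setNames(pt$r_o, key(pt$factor_a, pt$factor_b))
  triples <- combn(fac, 3)
  want <- sort(unlist(lapply(seq_len(ncol(triples)), function(i) {
    t3 <- triples[, i]
    w <- lut[c(key(t3[1], t3[2]), key(t3[1], t3[3]), key(t3[2], t3[3]))]
    if (all(w > 0.5)) paste(t3, collapse = "+") else NULL
  })))
  expect_setequal(got$members, want)
})

test_that("pair table enumerates F(F-1)/2 pairs", {
  set.seed(45)
  tracks <- setNames(lapply(1:6, function(i) {
    random_track(5, name = paste0("F", i))
  }), paste0("F", 1:6))
  expect_equal(nrow(overlap_ratio_table(tracks)), 15L)
})
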