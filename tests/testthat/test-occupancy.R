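test_that("RPP equals brute-force tag-by-peak overlap counting", {
  gn <- genome_def(c(chr1 = 5000L))
  peaks <- toy_peaks("chr1", c(500, 2000, 4000), c(700, 2300, 4500))
  none <- tag_library(GenomicRanges::GRanges(), genome = gn)
  expect_equal(reads_per_peak(peaks, none, genome = gn), c(0L, 0L, 0L))

  inside <- make_tags("chr1", 550, "+", gn)
  expect_equal(reads_per_peak(peaks, inside, genome = gn), c(1L, 0L, 0L))

  set.seed(8)
  pos <- sample(0:4800, 10)
  str <- sample(c("+", "-"), 10, replace = TRUE)
  lib <- make_tags("chr1", pos, str, gn)
  got <- reads_per_peak(peaks, lib, ext = 133, genome = gn)
  ext <- t(vapply(1:10, function(i) bf_extend(pos[i], str[i], 133, 5000),
                  numeric(2)))
  want <- bf_rpp(GenomicRanges::start(peaks), GenomicRanges::end(peaks),
                 rep("chr1", 3), ext[, 1], ext[, 2], rep("chr1", 10))
  expect_equal(as.numeric(got), want)
})

test_that("R-squared matches the hand Pearson formula and its invariances", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  hand <- (sum((x - mean(x)) * (y - mean(y))) /
             sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(rsq(x, y), hand)
  expect_equal(rsq(x, x), 1.0)
  expect_equal(rsq(x, -x), 1.0)
  expect_equal(rsq(3 * x + 7, -2 * y + 1), rsq(x, y), tolerance = 1e-12)
  expect_error(rsq(x, rep(1, 4)), "constant")
  expect_error(rsq(x, y[1:3]), "equal length")
})

test_that("common/preferential classification partitions both peak lists", {
  a <- toy_peaks("chr1", c(100, 300, 500, 700, 900),
                 c(150, 350, 550, 750, 950))
  b <- toy_peaks("chr1", c(120, 320, 340, 2000), c(170, 330, 360, 2100))
  cls <- classify_common_preferential(a, b)
  # oracle: exhaustive pairing
  want_A <- vapply(seq_along(a), function(i)
    any(vapply(seq_along(b), function(j) intervals_overlap(a[i], b[j]),
               logical(1))), logical(1))
  want_B <- vapply(seq_along(b), function(j)
    any(vapply(seq_along(a), function(i) intervals_overlap(a[i], b[j]),
               logical(1))), logical(1))
  expect_equal(cls$is_common_A, want_A)
  expect_equal(cls$is_common_B, want_B)
  # partition: common + preferential = all, in each condition
  expect_equal(length(cls$common_A) + length(cls$preferential_A), length(a))
  expect_equal(length(cls$common_B) + length(cls$preferential_B), length(b))
  # peak 2 of A overlaps two B peaks but is counted once (site level)
  expect_equal(unname(cls$counts["common_A"]), 2L)

  same <- classify_common_preferential(a, a)
  expect_true(all(same$is_common_A))
  disjoint <- classify_common_preferential(a, toy_peaks("chr2", 100, 200))
  expect_false(any(disjoint$is_common_A))
})

test_that("KS statistic matches the ECDF-sup oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$statistic, 1 / 3)
  set.seed(13)
  for (i in 1:20) {
    x <- sample(0:30, sample(3:40, 1), replace = TRUE)
    y <- sample(0:30, sample(3:40, 1), replace = TRUE) + sample(0:3, 1)
    expect_equal(ks_two_sample(x, y)$statistic, bf_ks_D(x, y))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("median report separates strong common from weak preferential sites", {
  a <- toy_peaks("chr1", seq(1000, 40000, by = 1000),
                 seq(1000, 40000, by = 1000) + 200)
  # first 20 peaks of A overlap B (common), last 20 do not
  b <- toy_peaks("chr1", seq(1000, 20000, by = 1000),
                 seq(1000, 20000, by = 1000) + 200)
  cls <- classify_common_preferential(a, b)
  set.seed(4)
  rpp_a <- c(rpois(20, 30), rpois(20, 8)) # common sites 3-4x stronger
  rpp_b <- rpois(20, 30)
  rep <- median_rpp_report(cls, rpp_a, rpp_b)
  expect_gt(rep$median_common_A, rep$median_preferential_A)
  expect_lt(rep$ks_A$p.value, 0.01)
  expect_true(is.na(rep$median_preferential_B)) # all B peaks are common
  expect_equal(rep$median_common_B, median(rpp_b))
  expect_equal(rep$median_common_A, median(rpp_a[1:20]))
})

test_that("background regions reproduce the analytic overlap expectation", {
  gn <- genome_def(c(chr1 = 200000L))
  none <- tag_library(GenomicRanges::GRanges(), genome = gn)
  bg0 <- background_rpp(none, 50, 200, gn, seed = 1)
  expect_equal(as.numeric(bg0$rpp), rep(0, 50))

  rate <- 0.01
  lib <- with_seed_for_tests(6, {
    n <- rpois(1, rate * 200000)
    make_tags("chr1", sample(0:199866, n, replace = TRUE),
              sample(c("+", "-"), n, replace = TRUE), gn)
  })
  bg <- background_rpp(lib, 2000, 200, gn, seed = 2, ext = 133)
  # a fragment of length L overlaps a w-bp region when its start falls in
  # a (w + L - 1)-bp span: expected RPP = rate * (200 + 133 - 1)
  expected <- (lib$depth / 200000) * (200 + 133 - 1)
  se <- sd(bg$rpp) / sqrt(length(bg$rpp))
  expect_lt(abs(mean(bg$rpp) - expected), 3 * se + 1e-9)

  bg_again <- background_rpp(lib, 2000, 200, gn, seed = 2, ext = 133)
  expect_identical(bg$rpp, bg_again$rpp)
  expect_error(background_rpp(lib, 10, 300000, gn, 1), "exceeds")
})

test_that("occupancy-bin modification fractions follow the ranking", {
  peaks <- toy_peaks("chr1", seq(1000, 10000, by = 1000),
                     seq(1000, 10000, by = 1000) + 100)
  rpp <- c(5, 9, 1, 7, 3, 10, 2, 8, 4, 6)
  expect_equal(binned_modification_fraction(peaks, rpp, peaks, 5),
               rep(1, 5))
  expect_equal(binned_modification_fraction(peaks, rpp,
                                            GenomicRanges::GRanges(), 5),
               rep(0, 5))
  # mod peaks over exactly the two highest-RPP reference peaks -> only bin 5
  top2 <- peaks[rpp >= 9]
  expect_equal(binned_modification_fraction(peaks, rpp, top2, 5),
               c(0, 0, 0, 0, 1))
  # remainder goes to the lowest bins: 7 peaks in 3 bins -> sizes 3,2,2
  got <- binned_modification_fraction(peaks[1:7], rpp[1:7], peaks[1:7][rpp[1:7] <= 3], 3)
  expect_equal(got, c(1, 0, 0))
  expect_error(binned_modification_fraction(peaks[1:3], rpp[1:3], peaks, 5),
               "fewer peaks")
})
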