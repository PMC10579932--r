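test_that("region_level pools reads, not per-site fractions", {
  calls <- make_calls("chr1", c(10, 20), n_meth = c(3, 7), n_total = c(10, 10))
  iv <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  r <- region_level(calls, iv, context = "CG")
  expect_equal(r$n_meth, 10L)
  expect_equal(r$n_unmeth, 10L)
  expect_equal(r$level, 0.5)
  expect_equal(r$n_sites, 2L)
})

test_that("zero-coverage intervals are flagged undefined", {
  calls <- make_calls("chr1", 10, n_meth = 3, n_total = 10)
  iv <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L)
  r <- region_level(calls, iv)
  expect_true(is.na(r$level))
  expect_equal(r$n_sites, 0L)
})

test_that("pooled level is exactly additive over interval partitions", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    calls <- make_calls("chr1", sample.int(1000, n),
                        context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
                        n_meth = 0, n_total = sample(0:40, n, replace = TRUE))
    calls$n_meth <- as.integer(rbinom(n, calls$n_total, 0.4))
    calls$n_unmeth <- calls$n_total - calls$n_meth
    cuts <- sort(sample(1:999, sample(1:4, 1)))
    bounds <- unique(c(0L, cuts, 1000L))
    parts <- tibble::tibble(chrom = "chr1", start = bounds[-length(bounds)],
                            end = bounds[-1])
    whole <- region_level(calls, tibble::tibble(chrom = "chr1", start = 0L, end = 1000L))
    pieces <- region_level(calls, parts)
    expect_identical(sum(pieces$n_meth), whole$n_meth)
    expect_identical(sum(pieces$n_sites), whole$n_sites)
    repooled <- sum(pieces$n_meth) / (sum(pieces$n_meth) + sum(pieces$n_unmeth))
    expect_identical(repooled, whole$level)
  }
})

test_that("degree of difference satisfies its exact identities", {
  expect_equal(degree_of_difference(0.25, 0.5)$score, 2)
  expect_equal(degree_of_difference(0.5, 0.5)$score, 1)
  for (x in c(0.1, 0.3, 0.5, 0.9, 0.999)) {
    expect_equal(degree_of_difference(x, x)$score, 1)
  }
})

test_that("zero levels substitute 0.001 before the log", {
  r <- degree_of_difference(0, 0.5)
  expect_true(r$zero_substituted)
  expect_equal(r$score, log2(0.001) / log2(0.5))  # = 9.965784...
  expect_equal(r$score, 9.965784284662087, tolerance = 1e-12)
  r2 <- degree_of_difference(0.5, 0)
  expect_equal(r2$score, log2(0.5) / log2(0.001))
})

test_that("a unit denominator level is flagged infinite, not an error", {
  r <- degree_of_difference(0.25, 1)
  expect_true(r$infinite)
  expect_error(degree_of_difference(1.2, 0.5), "0, 1")
})

test_that("context proportions are shares of methylated sites", {
  calls <- make_calls("chr1", 1:100,
                      context = rep(c("CG", "CHG", "CHH"), c(90, 2, 8)),
                      n_meth = 2, n_total = 10)
  p <- context_proportions(calls)
  expect_equal(p$share_pct, c(90, 2, 8))
  # all-CG input
  cg <- make_calls("chr1", 1:10, context = "CG", n_meth = 1, n_total = 5)
  expect_equal(context_proportions(cg)$share_pct, c(100, 0, 0))
})

test_that("the methylated-site rule is honoured and pluggable", {
  calls <- make_calls("chr1", 1:4, context = "CG",
                      n_meth = c(1, 1, 0, 5), n_total = c(3, 10, 10, 10))
  # default: coverage >= 4 and n_meth >= 1 -> sites 2 and 4 count
  expect_equal(sum(context_proportions(calls)$n_sites), 2L)
  strict <- context_proportions(calls, site_rule = function(x) x$n_meth >= 5)
  expect_equal(sum(strict$n_sites), 1L)
  none <- context_proportions(calls[3, ])
  expect_true(all(is.na(none$share_pct)))
  expect_true(attr(none, "undefined"))
})

test_that("normalize_track returns fractions summing to one", {
  expect_equal(normalize_track(c(0.2, 0.2, 0.6)), c(0.2, 0.2, 0.6))
  expect_equal(normalize_track(c(2, 2)), c(0.5, 0.5))
  set.seed(9)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0, 5)
    expect_equal(sum(normalize_track(v)), 1, tolerance = 1e-12)
  }
  z <- normalize_track(c(0, 0, 0))
  expect_equal(z, c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(z, "all_zero"))
  expect_error(normalize_track(c(-1, 2)), "non-negative")
})

test_that("tile_methylation renders levels on the configured scale", {
  calls <- make_calls("chr1", c(5, 15), n_meth = c(5, 5), n_total = c(10, 10))
  tiles <- tile_methylation(calls, c(chr1 = 40L), tile_bp = 20)
  expect_equal(tiles$value[1], 0.5 * 20)
  expect_true(is.na(tiles$value[2]))
})
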