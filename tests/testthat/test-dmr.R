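# deterministic two-group scenario: per 100 bp window, `sites` cytosines at
# fixed coverage with n_meth = round(cov * level) in each group
scenario_calls <- function(levels, sites = 10, cov = 20, window_bp = 100,
                           chrom = "chr1") {
  pos <- unlist(lapply(seq_along(levels), function(w) {
    (w - 1) * window_bp + seq(5, window_bp - 5, length.out = sites)
  }))
  lvl <- rep(levels, each = sites)
  make_calls(chrom, round(pos), n_meth = round(cov * lvl), n_total = cov)
}

test_that("windows failing the site-count filter never pass", {
  g1 <- scenario_calls(0.1, sites = 4)
  g2 <- scenario_calls(0.6, sites = 10)
  w <- window_scan(g1, g2, c(chr1 = 100L), window_bp = 100)
  expect_false(w$eligible)
  expect_false(w$pass)
  expect_true(is.na(w$p))
})

test_that("a strong two-group contrast passes exactly when Fisher P allows", {
  g1 <- scenario_calls(0.10)
  g2 <- scenario_calls(0.60)
  w <- window_scan(g1, g2, c(chr1 = 100L), window_bp = 100)
  expect_equal(w$fold, 6)
  p_oracle <- oracle_fisher_p(w$n_meth_1, w$n_unmeth_1, w$n_meth_2, w$n_unmeth_2)
  expect_equal(w$p, p_oracle, tolerance = 1e-12)
  expect_equal(w$pass, p_oracle < 0.05)
  expect_true(w$pass)   # 20/200 vs 120/200 is overwhelming
  expect_equal(w$direction, "hyper")
})

test_that("the hypomethylation floor vetoes windows under the 'both' rule", {
  g1 <- scenario_calls(0.01)
  g2 <- scenario_calls(0.04)
  w <- window_scan(g1, g2, c(chr1 = 100L), window_bp = 100, floor = 0.05)
  expect_false(w$pass)
  w2 <- window_scan(g1, g2, c(chr1 = 100L), window_bp = 100, floor = 0.05,
                    hypo_rule = "either")
  expect_false(w2$pass)  # both below the floor fails either rule
  # one group above the floor: 'either' admits it, 'both' does not
  g3 <- scenario_calls(0.30)
  w3b <- window_scan(g1, g3, c(chr1 = 100L), window_bp = 100, floor = 0.05)
  w3e <- window_scan(g1, g3, c(chr1 = 100L), window_bp = 100, floor = 0.05,
                     hypo_rule = "either")
  expect_false(w3b$pass)
  expect_true(w3e$pass)
})

test_that("a single passing window becomes one identical DMR", {
  g1 <- scenario_calls(0.10)
  g2 <- scenario_calls(0.60)
  w <- window_scan(g1, g2, c(chr1 = 100L), window_bp = 100)
  d <- merge_interdependent(w, g1, g2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, w$start)
  expect_equal(d$end, w$end)
  expect_equal(d$merged_from, 1L)
  expect_equal(d$p, w$p)
})

test_that("interdependent neighbours merge and the merged span still passes", {
  g1 <- scenario_calls(c(0.10, 0.10))
  g2 <- scenario_calls(c(0.60, 0.55))
  w <- window_scan(g1, g2, c(chr1 = 200L), window_bp = 100)
  expect_true(all(w$pass))
  d <- merge_interdependent(w, g1, g2)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(0, 200))
  expect_equal(d$merged_from, 2L)
  # merged-span statistics recomputed from pooled calls, checked by oracle
  expect_equal(d$n_meth_1, sum(g1$n_meth))
  expect_equal(d$p, oracle_fisher_p(d$n_meth_1, d$n_unmeth_1,
                                    d$n_meth_2, d$n_unmeth_2),
               tolerance = 1e-12)
  expect_gte(d$fold, 2)
  expect_lt(d$p, 0.05)
})

test_that("opposite-direction neighbours are never merged", {
  g1 <- scenario_calls(c(0.10, 0.60))
  g2 <- scenario_calls(c(0.60, 0.10))
  w <- window_scan(g1, g2, c(chr1 = 200L), window_bp = 100)
  expect_true(all(w$pass))
  expect_equal(w$direction, c("hyper", "hypo"))
  d <- merge_interdependent(w, g1, g2)
  expect_equal(nrow(d), 2L)
  expect_true(all(d$merged_from == 1L))
})

test_that("windows separated by more than max_gap stay independent", {
  lv1 <- c(0.10, 0.10, 0.10, 0.10, 0.10)
  lv2 <- c(0.60, 0.10, 0.10, 0.10, 0.60)  # passing windows 1 and 5, gap 300
  g1 <- scenario_calls(lv1)
  g2 <- scenario_calls(lv2)
  w <- window_scan(g1, g2, c(chr1 = 500L), window_bp = 100)
  expect_equal(sum(w$pass), 2L)
  d <- merge_interdependent(w, g1, g2, max_gap = 100)
  expect_equal(nrow(d), 2L)
  d2 <- merge_interdependent(w, g1, g2, max_gap = 400)
  # wide gap allowed: merge only if the whole span still passes (it dilutes)
  expect_true(nrow(d2) %in% c(1L, 2L))
  if (nrow(d2) == 1L) expect_gte(d2$fold, 2)
})

test_that("merging is idempotent and the result is pairwise non-mergeable", {
  set.seed(77)
  lv1 <- runif(12, 0.05, 0.5)
  lv2 <- pmin(lv1 * sample(c(1, 3, 4), 12, replace = TRUE), 0.95)
  g1 <- scenario_calls(lv1)
  g2 <- scenario_calls(lv2)
  w <- window_scan(g1, g2, c(chr1 = 1200L), window_bp = 100)
  d1 <- merge_interdependent(w, g1, g2, max_gap = 100)
  d2 <- merge_interdependent(d1, g1, g2, max_gap = 100)
  expect_equal(d1, d2)
})

test_that("DMG assignment follows gene-body and promoter overlap rules", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    tx_start = 5001L, tx_end = 8000L, tss = 5001L, n_exons = 1L,
    exons = list(tibble::tibble(start = 5001L, end = 8000L)))
  dmr <- function(s, e) tibble::tibble(
    chrom = "chr1", start = as.integer(s), end = as.integer(e),
    context = "CG", direction = "hyper", level_1 = 0.1, level_2 = 0.6,
    p = 1e-5)
  # strictly inside the transcript
  inside <- assign_dmgs(dmr(6000, 6500), genes)
  expect_equal(inside$location, "gene_body")
  # spanning the TSS touches both the promoter and the gene body
  spanning <- assign_dmgs(dmr(4900, 5100), genes)
  expect_setequal(spanning$location, c("gene_body", "promoter"))
  # 3 kb upstream of the TSS is beyond the 2 kb promoter
  far <- assign_dmgs(dmr(1500, 2000), genes)
  expect_equal(nrow(far), 0L)
  # minus-strand promoter sits right of the gene
  genes_m <- dplyr::mutate(genes, strand = "-", tss = 8000L)
  right <- assign_dmgs(dmr(8500, 8700), genes_m)
  expect_equal(right$location, "promoter")
  expect_equal(count_dmgs(spanning)$n_genes, c(1L, 1L))
})

test_that("dmr_result accessors and BED export behave", {
  g1 <- scenario_calls(c(0.10, 0.10, 0.30))
  g2 <- scenario_calls(c(0.60, 0.55, 0.30))
  res <- call_dmrs(g1, g2, c(chr1 = 300L), window_bp = 100, max_gap = 100)
  expect_s3_class(res, "dmr_result")
  gl <- glance(res)
  expect_equal(gl$n_windows, 3L)
  expect_equal(gl$n_passing, 2L)
  expect_equal(gl$n_dmrs, nrow(tidy(res)))
  expect_equal(count_dmrs(res)$n, nrow(tidy(res)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(res, f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), nrow(tidy(res)))
  expect_match(bed$name[1], "^CG:(hyper|hypo)$")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
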