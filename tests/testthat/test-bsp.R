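amplicon <- "ATTCGATCCGTTACGATTTACTTACGGATCAGTCACGTT"  # 5 CpGs, extra non-CpG Cs

test_that("bisulfite conversion follows the planted pattern at rate 1", {
  cpg <- find_cpg_sites(amplicon)
  expect_equal(length(cpg), 5L)
  full <- bisulfite_convert(amplicon, rep(1, 5), conversion_rate = 1,
                            n_clones = 3, seed = 1)
  chars <- strsplit(full$clones$sequence[1], "")[[1]]
  expect_true(all(chars[cpg] == "C"))               # methylated CpGs kept
  noncpg_c <- setdiff(which(strsplit(amplicon, "")[[1]] == "C"), cpg)
  expect_true(all(chars[noncpg_c] == "T"))          # all other Cs converted
  none <- bisulfite_convert(amplicon, rep(0, 5), conversion_rate = 1,
                            n_clones = 2, seed = 1)
  expect_false(grepl("C", none$clones$sequence[1]))  # every C -> T
})

test_that("incomplete conversion retains the binomial share of non-CpG Cs", {
  set.seed(8)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                      prob = c(0.2, 0.45, 0.1, 0.25)), collapse = "")
  cpg <- find_cpg_sites(ref)
  noncpg <- setdiff(which(strsplit(ref, "")[[1]] == "C"), cpg)
  n_noncpg <- length(noncpg)
  expect_gt(n_noncpg, 600)
  sim <- bisulfite_convert(ref, rep(0, length(cpg)), conversion_rate = 0.99,
                           n_clones = 4, seed = 99)
  retained <- vapply(sim$clones$sequence, function(s) {
    sum(strsplit(s, "")[[1]][noncpg] == "C")
  }, numeric(1))
  expected <- 0.01 * n_noncpg
  tol <- 4 * sqrt(n_noncpg * 0.01 * 0.99)
  expect_true(all(abs(retained - expected) < tol))
})

test_that("calling a fully converted, unmethylated clone", {
  cpg <- find_cpg_sites(amplicon)
  clone <- chartr("C", "T", amplicon)
  r <- bsp_call_clone(amplicon, clone)
  expect_true(all(r$calls$call == "unmethylated"))
  expect_equal(r$conversion_rate, 1)
  expect_true(r$qc_pass)
  expect_equal(r$identity, 1)
})

test_that("an unconverted clone calls methylated everywhere but fails QC", {
  r <- bsp_call_clone(amplicon, amplicon)
  expect_true(all(r$calls$call == "methylated"))
  expect_equal(r$conversion_rate, 0)
  expect_false(r$qc_pass)
  expect_false(r$rejected)
})

test_that("unrelated sequences are rejected with a reason", {
  set.seed(12)
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(amplicon), TRUE), collapse = "")
  r <- bsp_call_clone(amplicon, junk, min_identity = 0.8)
  expect_true(r$rejected)
  expect_match(r$reason, "identity")
})

test_that("reverse-complement clones are auto-oriented", {
  clone <- chartr("C", "T", amplicon)       # converted, unmethylated
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(clone)))
  r <- bsp_call_clone(amplicon, rc)
  expect_equal(r$orientation, "reverse")
  expect_true(all(r$calls$call == "unmethylated"))
})

test_that("simulator-to-caller round trip is lossless at full conversion", {
  set.seed(21)
  for (i in 1:10) {
    ref <- random_dna(150, gc = 0.5)
    cpg <- find_cpg_sites(ref)
    if (length(cpg) == 0) next
    pattern <- sample(c(0, 1), length(cpg), replace = TRUE)
    sim <- bisulfite_convert(ref, pattern, conversion_rate = 1,
                             n_clones = 3, seed = i)
    res <- bsp_analyze(ref, sim$clones)
    got <- dplyr::arrange(res$calls, clone_id, cpg_pos)
    want <- dplyr::arrange(sim$truth, clone_id, cpg_pos)
    expect_equal(got$call == "methylated", want$methylated)
    expect_true(all(res$clones$qc_pass))
  }
})

test_that("matrix summary equals the planted pattern for clean clones", {
  ref <- "TTACGGATTCGCAATTACGGTT"
  pattern <- c(1, 0, 1)
  sim <- bisulfite_convert(ref, pattern, conversion_rate = 1,
                           n_clones = 10, seed = 4)
  mat <- bsp_matrix(bsp_analyze(ref, sim$clones))
  expect_equal(mat$summary$frac_methylated, pattern)
  expect_equal(length(mat$clone_ids), 10L)
  expect_equal(glance(mat)$n_cpgs, 3L)
  txt <- format(mat)
  expect_length(txt, 11L)      # 10 clones + summary line
  expect_s3_class(ggplot2::autoplot(mat), "ggplot")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bsp_matrix(mat, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 10L)
})

test_that("a matrix needs at least one QC-passing clone", {
  res <- bsp_analyze(amplicon, tibble::tibble(clone_id = "c1",
                                              sequence = amplicon))
  expect_error(bsp_matrix(res), "QC-passing")
})

test_that("lowering min_conversion never loses QC-passing clones", {
  set.seed(33)
  ref <- random_dna(200, gc = 0.5)
  cpg <- find_cpg_sites(ref)
  sim <- bisulfite_convert(ref, rep(0.5, length(cpg)), conversion_rate = 0.9,
                           n_clones = 20, seed = 5)
  passes <- vapply(c(0.99, 0.95, 0.9, 0.8, 0), function(th) {
    sum(bsp_analyze(ref, sim$clones, min_conversion = th)$clones$qc_pass)
  }, numeric(1))
  expect_true(all(diff(passes) >= 0))
})
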