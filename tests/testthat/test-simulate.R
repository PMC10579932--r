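small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_chroms = 1, chrom_len = 6e4, n_genes = 5,
             n_cpg_islands = 3, n_repeats = 3, n_dmrs = 3, ...)
}

test_that("the genome generator is byte-deterministic under a seed", {
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(simulate_genome(small_cfg())$genome, f1)
  Biostrings::writeXStringSet(simulate_genome(small_cfg())$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("observed GC content tracks the configured value", {
  cfg <- sim_config(seed = 4, n_chroms = 1, chrom_len = 1e5, n_genes = 0,
                    n_cpg_islands = 0, n_repeats = 0, n_dmrs = 0,
                    gc_content = 0.5)
  g <- simulate_genome(cfg)
  freq <- Biostrings::alphabetFrequency(g$genome)[1, c("C", "G")]
  expect_lt(abs(sum(freq) / 1e5 - 0.5), 0.03)
})

test_that("a zero-gene genome writes a GFF3 with no mRNA features", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_len = 2e4, n_genes = 0,
                    n_cpg_islands = 2, n_repeats = 2, n_dmrs = 0)
  sim <- simulate_genome(cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  expect_equal(nrow(read_gene_models(f)), 0L)
})

test_that("gene models survive a GFF3 round trip", {
  sim <- simulate_genome(small_cfg())
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  back <- read_gene_models(f)
  expect_equal(nrow(back), nrow(sim$genes))
  back <- back[match(sim$genes$gene_id, back$gene_id), ]
  expect_equal(back$tss, sim$genes$tss)
  expect_equal(back$strand, sim$genes$strand)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$exons[[i]]$start, sim$genes$exons[[i]]$start)
  }
})

test_that("emitted call contexts agree with classify_context", {
  sim <- simulate_genome(small_cfg())
  m <- simulate_methylome(sim)
  calls <- m$calls[[1]]
  idx <- seq(1, nrow(calls), by = 37)   # spot-check a deterministic subset
  rederived <- classify_context(sim$genome, calls$chrom[idx],
                                calls$pos[idx], calls$strand[idx])
  expect_identical(calls$context[idx], rederived)
})

test_that("methylome counts respect the planted levels and coverage model", {
  sim <- simulate_genome(small_cfg(seed = 9))
  m <- simulate_methylome(sim)
  expect_named(m$calls, c("control", "graft"))
  expect_true(all(m$calls$control$n_total > 0))
  # coverage ~ Poisson(30)
  expect_lt(abs(mean(m$calls$control$n_total) - 30), 1)
  # planted CG DMRs: pooled levels near the configured 0.3 / 0.7
  truth <- m$truth
  lv1 <- region_level(m$calls$control, truth, context = "CG")
  lv2 <- region_level(m$calls$graft, truth, context = "CG")
  expect_true(all(abs(lv1$level - 0.3) < 0.06))
  expect_true(all(abs(lv2$level - 0.7) < 0.06))
  # and there are enough CG sites per planted kb to scan
  expect_true(all(lv1$n_sites >= 8))
})

test_that("a planted DMR outside the genome is rejected", {
  cfg <- small_cfg()
  cfg$planted_dmrs <- tibble::tibble(chrom = "chr1", start = 59500L,
                                     end = 60500L, context = "CG",
                                     level_1 = 0.3, level_2 = 0.7)
  sim <- simulate_genome(cfg)
  expect_error(simulate_methylome(sim, cfg), "outside")
})

test_that("simulation files land in the formats the readers consume", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg())
  m <- simulate_methylome(sim)
  paths <- write_simulation(sim, m, dir)
  expect_true(all(file.exists(paths)))
  back <- read_calls(paths[["calls_control"]])
  expect_equal(nrow(back), nrow(m$calls$control))
  expect_equal(back$n_meth, m$calls$control$n_meth)
  expect_gt(nrow(read_bed(paths[["cpg_islands"]])), 0)
})

test_that("group effects scale gene-body CG methylation", {
  cfg <- small_cfg(groups = c("control", "t1", "t2"),
                   group_effects = c(control = 1, t1 = 0.5, t2 = 1))
  sim <- simulate_genome(cfg)
  m <- simulate_methylome(sim, cfg)
  bodies <- tibble::tibble(chrom = sim$genes$chrom,
                           start = sim$genes$tx_start - 1L,
                           end = sim$genes$tx_end)
  lv <- vapply(m$calls, function(cc) {
    r <- region_level(cc, bodies, context = "CG")
    sum(r$n_meth) / (sum(r$n_meth) + sum(r$n_unmeth))
  }, numeric(1))
  expect_lt(lv[["t1"]], 0.6 * lv[["control"]] + 0.05)
  expect_equal(lv[["t2"]], lv[["control"]], tolerance = 0.05)
})

test_that("the synthetic term map is deterministic and well-formed", {
  genes <- sprintf("gene_%03d", 1:40)
  t1 <- simulate_term_map(genes, seed = 2)
  t2 <- simulate_term_map(genes, seed = 2)
  expect_identical(t1, t2)
  expect_true(all(t1$gene_id %in% genes))
  expect_equal(length(unique(t1$term_id)), 30L)
})
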