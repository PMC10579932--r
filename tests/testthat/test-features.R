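make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      exons, tx_start = min(exons$start),
                      tx_end = max(exons$end)) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    tss = as.integer(if (strand == "-") tx_end else tx_start),
    n_exons = nrow(exons),
    exons = list(if (strand == "-") exons[rev(seq_len(nrow(exons))), ] else exons)
  )
}

test_that("a three-exon gene partitions into first/internal/last features", {
  ex <- tibble::tibble(start = c(3001L, 3501L, 4001L), end = c(3200L, 3700L, 4300L))
  p <- partition_genes(make_gene(exons = ex))
  feat <- function(f) p[p$feature == f, ]
  expect_equal(nrow(feat("internal_exon")), 1L)
  expect_equal(feat("first_exon")$start, 3000)
  expect_equal(feat("last_exon")$end, 4300)
  # intron 1 -> first_intron, intron 2 -> internal_intron
  expect_equal(feat("first_intron")$start, 3200)
  expect_equal(feat("first_intron")$end, 3500)
  expect_equal(feat("internal_intron")$start, 3700)
  expect_equal(feat("internal_intron")$end, 4000)
  expect_equal(feat("upstream")$end, 3000)
  expect_equal(feat("upstream")$start, 1000)
  expect_equal(feat("promoter"), dplyr::mutate(feat("upstream"), feature = "promoter"))
  expect_equal(feat("gene_body")$start, 3000)
  expect_equal(feat("gene_body")$end, 4300)
})

test_that("single- and two-exon genes stay degenerate but disjoint", {
  one <- partition_genes(make_gene(exons = tibble::tibble(start = 5001L, end = 5400L)))
  expect_setequal(unique(one$feature),
                  c("upstream", "promoter", "downstream", "gene_body", "first_exon"))
  two <- partition_genes(make_gene(exons = tibble::tibble(
    start = c(5001L, 6001L), end = c(5400L, 6400L))))
  expect_true(all(c("first_exon", "last_exon", "first_intron") %in% two$feature))
  expect_false(any(c("internal_exon", "internal_intron") %in% two$feature))
})

test_that("exon and intron features within one gene are mutually disjoint", {
  set.seed(31)
  for (i in 1:20) {
    E <- sample(1:6, 1)
    starts <- cumsum(c(2000, sample(200:800, E - 1, replace = TRUE) +
                         sample(100:400, E - 1, replace = TRUE)))
    ex <- tibble::tibble(start = as.integer(starts),
                         end = as.integer(starts + sample(100:400, E, replace = TRUE)))
    strand <- sample(c("+", "-"), 1)
    p <- partition_genes(make_gene(strand = strand, exons = ex))
    p <- p[!p$feature %in% c("promoter", "gene_body"), ]
    gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1, p$end))
    ov <- GenomicRanges::findOverlaps(gr, gr)
    expect_equal(length(ov), nrow(p))   # only self-overlaps
  }
})

test_that("minus-strand flanks reflect transcription orientation and clip", {
  g <- make_gene(strand = "-", exons = tibble::tibble(start = 1000L, end = 2000L))
  p <- partition_genes(g, chrom_lengths = c(chr1 = 3000L))
  up <- p[p$feature == "upstream", ]
  expect_equal(up$start, 2000)          # upstream of the minus-strand TSS
  expect_equal(up$end, 3000)            # clipped at the contig end
  dn <- p[p$feature == "downstream", ]
  expect_equal(c(dn$start, dn$end), c(0, 999))  # clipped at zero
})

test_that("feature_profile equals region_level for a single gene and group", {
  ex <- tibble::tibble(start = c(101L, 301L), end = c(200L, 400L))
  gene <- make_gene(exons = ex)
  set.seed(5)
  calls <- make_calls("chr1", sample(1:600, 80), n_meth = 3, n_total = 10)
  p <- partition_genes(gene, flank = 100)
  prof <- feature_profile(list(g1 = calls), p)
  for (f in unique(p$feature)) {
    direct <- region_level(calls, p[p$feature == f, ], context = "CG")
    expect_equal(prof$level[prof$feature == f],
                 sum(direct$n_meth) / (sum(direct$n_meth) + sum(direct$n_unmeth)))
  }
})

test_that("features with no covered sites are undefined, unknown labels error", {
  gene <- make_gene(exons = tibble::tibble(start = 101L, end = 200L))
  calls <- make_calls("chr1", 150, n_meth = 1, n_total = 2)
  p <- partition_genes(gene, flank = 50)
  prof <- feature_profile(list(a = calls), p)
  expect_true(is.na(prof$level[prof$feature == "downstream"]))
  expect_false(is.na(prof$level[prof$feature == "first_exon"]))
  expect_error(feature_profile(list(a = calls), p, features = "enhancer"),
               "unknown feature")
})

test_that("simulated promoters are hypomethylated relative to gene bodies", {
  cfg <- sim_config(seed = 13, n_chroms = 1, chrom_len = 1e5, n_genes = 8,
                    n_cpg_islands = 4, n_repeats = 4, n_dmrs = 0)
  sim <- simulate_genome(cfg)
  m <- simulate_methylome(sim)
  parts <- partition_genes(sim$genes, sim$chrom_lengths)
  prof <- feature_profile(m$calls["control"], parts)
  promoter <- prof$level[prof$feature == "promoter"]
  body <- prof$level[prof$feature == "gene_body"]
  expect_lt(promoter, body)
  expect_lt(promoter, 0.2)
  expect_gt(body, 0.5)
})
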