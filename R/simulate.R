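#' Default per-feature, per-context methylation baselines
#'
#' Baseline weighted levels used by [simulate_methylome()]. CG
#' methylation follows the mosaic invertebrate pattern: high in gene
#' bodies and repeats, intermediate elsewhere, and lowest in promoters
#' and CpG islands. Non-CG (CHG/CHH) methylation is set at background
#' level, far below CG, so that the context composition of methylated
#' sites matches WGBS observations in molluscs (mCG close to or above
#' 90% of methylated sites).
#'
#' @return A tibble `feature`, `context`, `level`.
#' @export
default_context_levels <- function() {
  features <- c("cpg_island", "promoter", "gene_body", "repeat", "intergenic")
  cg <- c(cpg_island = 0.05, promoter = 0.05, gene_body = 0.7,
          `repeat` = 0.7, intergenic = 0.3)
  tidyr::expand_grid(feature = features, context = CONTEXTS) %>%
    mutate(level = dplyr::case_when(
      .data$context == "CG" ~ unname(cg[.data$feature]),
      .data$context == "CHG" ~ 8e-4,
      .data$context == "CHH" ~ 6e-4
    ))
}

#' Configuration for the synthetic methylome generator
#'
#' Bundles every tunable of [simulate_genome()] and
#' [simulate_methylome()] with defaults sized so the full pipeline runs
#' in minutes on one CPU: 2 chromosomes of 500 kb, 40 genes, 20 planted
#' 1 kb CG DMRs at control level 0.3 versus treatment level 0.7, and
#' Poisson read coverage with mean 30.
#'
#' @param seed Integer master seed; every generator draw derives from it.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param gc_content Genomic GC fraction (default 0.35, an AT-rich
#'   invertebrate genome).
#' @param n_genes Genes placed per genome (non-overlapping).
#' @param exons_per_gene Exons per gene.
#' @param exon_len,intron_len Mean exon/intron lengths (bp).
#' @param n_cpg_islands,cpg_island_len CG-enriched island count/length.
#' @param n_repeats,repeat_len Repeat segment count/length.
#' @param groups Group labels; the first is the control.
#' @param coverage Mean Poisson read depth per cytosine.
#' @param context_levels Baseline levels tibble
#'   (see [default_context_levels()]).
#' @param n_dmrs,dmr_len Number and width of planted DMRs.
#' @param dmr_context Context of planted DMRs (default `"CG"`).
#' @param dmr_level_1,dmr_level_2 True levels inside planted DMRs for the
#'   control and for every treatment group (defaults 0.3 and 0.7).
#' @param planted_dmrs Optional explicit DMR tibble (`chrom`, `start`,
#'   `end`, `context`, `level_1`, `level_2`); `NULL` places `n_dmrs`
#'   automatically.
#' @param group_effects Optional named multipliers on the CG gene-body /
#'   repeat / intergenic baselines per group (default 1 for all), for
#'   simulating global de- and re-methylation across a time course.
#' @param flank Promoter length used for feature assignment (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_len = 5e5,
                       gc_content = 0.35, n_genes = 40, exons_per_gene = 4,
                       exon_len = 300, intron_len = 500,
                       n_cpg_islands = 20, cpg_island_len = 600,
                       n_repeats = 25, repeat_len = 800,
                       groups = c("control", "graft"), coverage = 30,
                       context_levels = default_context_levels(),
                       n_dmrs = 20, dmr_len = 1000, dmr_context = "CG",
                       dmr_level_1 = 0.3, dmr_level_2 = 0.7,
                       planted_dmrs = NULL, group_effects = NULL,
                       flank = 2000) {
  probs <- c(gc_content, context_levels$level, dmr_level_1, dmr_level_2)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (coverage <= 0) abort("coverage must be positive")
  if (length(groups) < 2) abort("at least two groups (control + 1) are required")
  if (is.null(group_effects)) {
    group_effects <- setNames(rep(1, length(groups)), groups)
  }
  structure(list(
    seed = seed, n_chroms = n_chroms, chrom_len = chrom_len,
    gc_content = gc_content, n_genes = n_genes,
    exons_per_gene = exons_per_gene, exon_len = exon_len,
    intron_len = intron_len, n_cpg_islands = n_cpg_islands,
    cpg_island_len = cpg_island_len, n_repeats = n_repeats,
    repeat_len = repeat_len, groups = groups, coverage = coverage,
    context_levels = context_levels, n_dmrs = n_dmrs, dmr_len = dmr_len,
    dmr_context = dmr_context, dmr_level_1 = dmr_level_1,
    dmr_level_2 = dmr_level_2, planted_dmrs = planted_dmrs,
    group_effects = group_effects, flank = flank
  ), class = "sim_config")
}

#' Simulate a genome with gene models and regulatory tracks
#'
#' Generates a random genome at the configured GC content, places
#' non-overlapping multi-exon genes on random strands, inserts
#' CG-enriched CpG islands and marks repeat segments in intergenic space.
#' Fully deterministic under the config seed (two runs produce
#' byte-identical FASTA).
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: list with `genome` (`DNAStringSet`), `genes`
#'   (gene-model tibble as from [read_gene_models()]), `cpg_islands`,
#'   `repeats` (interval tibbles, 0-based half-open), `chrom_lengths`,
#'   and `config`. Raises an error when genes cannot be placed without
#'   overlap at the requested density.
#' @export
simulate_genome <- function(config = sim_config()) {
  with_seed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    gc <- config$gc_content
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- lapply(chroms, function(ch) {
      sample(names(base_p), config$chrom_len, replace = TRUE, prob = base_p)
    })
    names(seqs) <- chroms

    # CpG islands: CG-enriched segments written over the background
    island_p <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
    islands <- place_segments(chroms, config$chrom_len,
                              rep(config$cpg_island_len, config$n_cpg_islands),
                              min_gap = 200)
    for (i in seq_len(nrow(islands))) {
      idx <- (islands$start[i] + 1):islands$end[i]
      seqs[[islands$chrom[i]]][idx] <-
        sample(names(island_p), length(idx), replace = TRUE, prob = island_p)
    }

    # genes: non-overlapping, away from islands, with 2 kb flank margins
    gene_len <- config$exons_per_gene * config$exon_len +
      max(config$exons_per_gene - 1, 0) * config$intron_len
    occupied <- islands
    gene_starts <- place_segments(
      chroms, config$chrom_len,
      rep(gene_len, config$n_genes),
      min_gap = config$flank, avoid = islands,
      what = "genes")
    genes <- purrr::map_dfr(seq_len(nrow(gene_starts)), function(i) {
      g <- gene_starts[i, ]
      strand <- sample(c("+", "-"), 1)
      exon_starts1 <- g$start + 1 +
        (seq_len(config$exons_per_gene) - 1) * (config$exon_len + config$intron_len)
      ex <- tibble(start = as.integer(exon_starts1),
                   end = as.integer(exon_starts1 + config$exon_len - 1))
      if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
      tibble(
        gene_id = sprintf("gene_%03d", i),
        chrom = g$chrom, strand = strand,
        tx_start = as.integer(g$start + 1), tx_end = as.integer(g$end),
        tss = as.integer(if (strand == "-") g$end else g$start + 1),
        n_exons = config$exons_per_gene,
        exons = list(ex)
      )
    })

    # repeats in space not used by genes or islands
    repeats <- place_segments(chroms, config$chrom_len,
                              rep(config$repeat_len, config$n_repeats),
                              min_gap = 100,
                              avoid = bind_rows(islands, gene_starts),
                              what = "repeats")
    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = ""))
    names(genome) <- chroms
    structure(list(
      genome = genome, genes = genes,
      cpg_islands = islands %>% select("chrom", "start", "end"),
      repeats = repeats %>% select("chrom", "start", "end"),
      chrom_lengths = setNames(rep(config$chrom_len, length(chroms)), chroms),
      config = config
    ), class = "sim_genome")
  })
}

#' Place non-overlapping segments on a genome by rejection sampling
#' @noRd
place_segments <- function(chroms, chrom_len, lens, min_gap = 0,
                           avoid = NULL, what = "segments",
                           max_tries = 2000) {
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  placed <- if (is.null(avoid) || nrow(avoid) == 0) {
    empty
  } else {
    avoid %>% select("chrom", "start", "end")
  }
  if (length(lens) == 0) return(empty)
  out <- list()
  for (len in lens) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1)
      s <- sample.int(chrom_len - len, 1) - 1L
      cand <- tibble(chrom = ch, start = s, end = s + len)
      clash <- placed$chrom == ch &
        placed$start < cand$end + min_gap &
        placed$end > cand$start - min_gap
      if (!any(clash)) {
        placed <- bind_rows(placed, cand)
        out <- c(out, list(cand))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf("could not place %s without overlap at the requested density", what))
    }
  }
  bind_rows(out)
}

#' Place segments whose starts are multiples of their width
#' @noRd
place_aligned_segments <- function(chroms, chrom_len, n, len, min_gap = 0,
                                   max_tries = 2000) {
  placed <- tibble(chrom = character(), start = integer(), end = integer())
  n_slots <- (chrom_len - len) %/% len
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1)
      s <- (sample.int(n_slots, 1) - 1L) * len
      clash <- placed$chrom == ch &
        placed$start < s + len + min_gap & placed$end > s - min_gap
      if (!any(clash)) {
        placed <- bind_rows(placed, tibble(chrom = ch, start = s,
                                           end = s + len))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place planted DMRs without overlap")
  }
  placed
}

#' Simulate grouped per-cytosine methylation calls with planted DMRs
#'
#' Every cytosine of the simulated genome (both strands) receives its
#' context from the sequence; its true methylation level is the
#' feature/context baseline of the region it falls in (priority: CpG
#' island > promoter > gene body > repeat > intergenic), overridden
#' inside planted DMRs per group. Read coverage is Poisson with the
#' configured mean (sites drawing zero coverage are absent from the
#' output, so site-count filters are genuinely exercised) and methylated
#' read counts are Binomial(coverage, level). Deterministic under the
#' config seed.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param config A [sim_config()]; defaults to the one inside `sim`.
#' @return A `sim_methylome`: list with `calls` (named list of call
#'   tibbles, one per group), `truth` (planted DMR tibble `chrom`,
#'   `start`, `end`, `context`, `level_1`, `level_2`), `sites` (the
#'   annotated site table with `feature` and per-group true levels
#'   omitted), and `config`.
#' @export
simulate_methylome <- function(sim, config = sim$config) {
  sites <- enumerate_cytosines(sim$genome)
  sites$feature <- assign_site_features(sites, sim, config$flank)

  planted <- config$planted_dmrs
  if (is.null(planted)) {
    # planted DMRs are aligned to multiples of their own width so that
    # recovery benchmarks measure the caller's statistics, not the phase
    # of the analysis grid (a straddling region dilutes below the
    # twofold filter in both windows -- see the methods vignette)
    planted <- with_seed(config$seed + 1000003L,
      place_aligned_segments(names(sim$chrom_lengths), config$chrom_len,
                             n = config$n_dmrs, len = config$dmr_len,
                             min_gap = 3 * config$dmr_len)) %>%
      mutate(context = config$dmr_context,
             level_1 = config$dmr_level_1, level_2 = config$dmr_level_2)
  }
  bad <- !(planted$chrom %in% names(sim$chrom_lengths)) |
    planted$end > unname(sim$chrom_lengths[planted$chrom])
  if (any(bad)) abort("planted DMR outside the simulated genome")

  base <- sites %>%
    left_join(config$context_levels, by = c("feature", "context"))
  if (any(is.na(base$level))) {
    abort("context_levels is missing a (feature, context) combination")
  }
  # site index inside a planted DMR (context-matched), else NA
  hit <- rep(NA_integer_, nrow(base))
  ov <- GenomicRanges::findOverlaps(gr_from_calls(base), gr_from_intervals(planted))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  ctx_ok <- base$context[q] == planted$context[s]
  hit[q[ctx_ok]] <- s[ctx_ok]

  control <- config$groups[1]
  calls <- purrr::imap(setNames(config$groups, config$groups), function(grp, nm) {
    effect <- config$group_effects[[grp]] %||% 1
    lvl <- pmin(base$level * ifelse(base$context == "CG" &
                                      base$feature %in% c("gene_body", "repeat", "intergenic"),
                                    effect, 1), 1)
    dmr_lvl <- if (grp == control) planted$level_1 else planted$level_2
    lvl[!is.na(hit)] <- dmr_lvl[hit[!is.na(hit)]]
    gi <- match(grp, config$groups)
    with_seed(config$seed + 7L * gi, {
      cov <- rpois(nrow(base), config$coverage)
      nm_reads <- rbinom(nrow(base), cov, lvl)
      tibble(chrom = base$chrom, pos = base$pos, strand = base$strand,
             context = base$context, n_meth = nm_reads,
             n_unmeth = cov - nm_reads, n_total = cov) %>%
        filter(.data$n_total > 0) %>%
        arrange(.data$chrom, .data$pos)
    })
  })
  structure(list(calls = calls, truth = planted,
                 sites = sites, config = config),
            class = "sim_methylome")
}

#' @noRd
assign_site_features <- function(sites, sim, flank) {
  feature <- rep("intergenic", nrow(sites))
  gr <- gr_from_calls(sites)
  mark <- function(feature, intervals, label) {
    if (is.null(intervals) || nrow(intervals) == 0) return(feature)
    hits <- GenomicRanges::findOverlaps(gr, gr_from_intervals(intervals))
    feature[unique(S4Vectors::queryHits(hits))] <- label
    feature
  }
  minus <- sim$genes$strand == "-"
  promoters <- tibble(
    chrom = sim$genes$chrom,
    start = pmax(ifelse(minus, sim$genes$tx_end,
                        sim$genes$tx_start - 1L - flank), 0),
    end = pmin(ifelse(minus, sim$genes$tx_end + flank,
                      sim$genes$tx_start - 1L),
               unname(sim$chrom_lengths[sim$genes$chrom]))
  )
  bodies <- tibble(chrom = sim$genes$chrom,
                   start = sim$genes$tx_start - 1L, end = sim$genes$tx_end)
  # priority: lowest first, later marks overwrite earlier ones
  feature <- mark(feature, sim$repeats, "repeat")
  feature <- mark(feature, bodies, "gene_body")
  feature <- mark(feature, promoters, "promoter")
  feature <- mark(feature, sim$cpg_islands, "cpg_island")
  feature
}

#' Write all synthetic inputs to disk
#'
#' Serializes a simulated genome and methylome in exactly the formats the
#' readers consume: genome FASTA, gene GFF3, CpG-island and repeat BED,
#' one call TSV per group, and the planted-DMR ground truth TSV.
#'
#' @param sim A `sim_genome`.
#' @param methylome A `sim_methylome` (optional).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_simulation <- function(sim, methylome = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    cpg_islands = file.path(dir, "cpg_islands.bed"),
    repeats = file.path(dir, "repeats.bed")
  )
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_gff3(sim$genes, paths["genes"])
  write_bed(sim$cpg_islands, paths["cpg_islands"])
  write_bed(sim$repeats, paths["repeats"])
  if (!is.null(methylome)) {
    for (grp in names(methylome$calls)) {
      p <- file.path(dir, sprintf("calls_%s.tsv", grp))
      write_calls(methylome$calls[[grp]], p)
      paths[paste0("calls_", grp)] <- p
    }
    truth_path <- file.path(dir, "planted_dmrs.tsv")
    readr::write_tsv(methylome$truth, truth_path, progress = FALSE)
    paths["truth"] <- truth_path
  }
  paths
}

#' Simulate a BSP experiment
#'
#' Generates (or accepts) a reference amplicon, plants a per-CpG
#' methylation pattern and produces bisulfite-converted clone sequences
#' via [bisulfite_convert()], together with the ground truth.
#'
#' @param reference Optional amplicon sequence; `NULL` generates a random
#'   one of length `amplicon_len`.
#' @param pattern Optional per-CpG methylation probabilities; `NULL`
#'   draws a random binary pattern.
#' @param n_clones,conversion_rate As in [bisulfite_convert()].
#' @param seed Integer seed.
#' @param amplicon_len Length of the generated amplicon (default 200).
#' @return A list: `reference`, `pattern`, `clones` (tibble), `truth`.
#' @export
simulate_bsp <- function(reference = NULL, pattern = NULL, n_clones = 10,
                         conversion_rate = 1, seed = 1, amplicon_len = 200) {
  with_seed(seed, {
    if (is.null(reference)) {
      reference <- paste(sample(c("A", "C", "G", "T"), amplicon_len,
                                replace = TRUE), collapse = "")
    }
    cpg <- find_cpg_sites(reference)
    if (is.null(pattern)) pattern <- sample(c(0, 1), length(cpg), replace = TRUE)
    sim <- bisulfite_convert(reference, pattern,
                             conversion_rate = conversion_rate,
                             n_clones = n_clones, seed = NULL)
    c(list(reference = reference, pattern = pattern), sim)
  })
}

#' Simulate a gene-to-term annotation map
#'
#' Random term assignments for enrichment testing: each term draws a
#' Poisson-sized gene set from the supplied universe.
#'
#' @param gene_ids Universe of gene ids.
#' @param n_terms Number of terms (default 30).
#' @param mean_genes_per_term Mean term size (default 8).
#' @param seed Integer seed.
#' @return A tibble `gene_id`, `term_id`, `term_name`.
#' @export
simulate_term_map <- function(gene_ids, n_terms = 30,
                              mean_genes_per_term = 8, seed = 1) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_terms), function(i) {
      size <- min(max(1, rpois(1, mean_genes_per_term)), length(gene_ids))
      tibble(gene_id = sample(gene_ids, size),
             term_id = sprintf("TERM:%04d", i),
             term_name = sprintf("synthetic term %d", i))
    }) %>% arrange(.data$term_id, .data$gene_id)
  })
}
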