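#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline stages plus the output
#' directory and seed. Validation gathers *all* violations into a single
#' error rather than stopping at the first.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] describing the synthetic inputs (the
#'   pipeline runs on simulated data; real call files can be analysed by
#'   calling the stage functions directly).
#' @param control Label of the control group (must be among
#'   `sim$groups`).
#' @param contexts Contexts for the DMR scan.
#' @param window_bp,min_sites,min_fold,alpha,floor,max_gap,hypo_rule DMR
#'   scan/merge tunables (see [window_scan()]).
#' @param promoter_len Promoter length for DMG assignment (bp).
#' @param flank Feature-partition flank (bp).
#' @param min_cov Coverage threshold for the methylated-site rule.
#' @param tile_bp Chromosome-map tile width (bp).
#' @param min_conversion BSP conversion-rate QC threshold.
#' @param term_map Optional gene-to-term tibble or TSV path; `NULL`
#'   simulates one.
#' @param seed Integer seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sim = sim_config(), control = sim$groups[1],
                       contexts = "CG", window_bp = 1000, min_sites = 5,
                       min_fold = 2, alpha = 0.05, floor = 0.05,
                       max_gap = 1000, hypo_rule = "both",
                       promoter_len = 2000, flank = 2000, min_cov = 4,
                       tile_bp = 10000, min_conversion = 0.95,
                       term_map = NULL, seed = sim$seed) {
  cfg <- list(out_dir = out_dir, sim = sim, control = control,
              contexts = contexts, window_bp = window_bp,
              min_sites = min_sites, min_fold = min_fold, alpha = alpha,
              floor = floor, max_gap = max_gap, hypo_rule = hypo_rule,
              promoter_len = promoter_len, flank = flank, min_cov = min_cov,
              tile_bp = tile_bp, min_conversion = min_conversion,
              term_map = term_map, seed = seed)
  problems <- character()
  if (!inherits(sim, "sim_config")) {
    problems <- c(problems, "sim: must be a sim_config object")
  } else if (!control %in% sim$groups) {
    problems <- c(problems, sprintf(
      "control: group '%s' is not among the configured groups (%s)",
      control, paste(sim$groups, collapse = ", ")))
  }
  bad_ctx <- setdiff(contexts, CONTEXTS)
  if (length(bad_ctx) > 0) {
    problems <- c(problems, sprintf("contexts: unknown context %s",
                                    paste(bad_ctx, collapse = ", ")))
  }
  for (fld in c("window_bp", "min_sites", "min_fold", "max_gap",
                "promoter_len", "flank", "tile_bp")) {
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] <= 0) {
      problems <- c(problems, sprintf("%s: must be a positive number", fld))
    }
  }
  for (fld in c("alpha", "floor", "min_conversion")) {
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 0 || cfg[[fld]] > 1) {
      problems <- c(problems, sprintf("%s: must lie in [0, 1]", fld))
    }
  }
  if (!hypo_rule %in% c("both", "either")) {
    problems <- c(problems, "hypo_rule: must be 'both' or 'either'")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; keys under
#' `sim:` mirror [sim_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$groups)) sim_args$groups <- unlist(sim_args$groups)
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  do.call(run_config, c(list(sim = sim), y))
}

#' Run the methylome analysis pipeline end to end
#'
#' Chains the stages `simulate` (synthetic genome + methylome),
#' `profile` (context proportions, feature profile, chromosome tiles),
#' `dmr` (windowed scan, merging, DMG assignment and per-DMR
#' degree-of-difference scores, control versus every other group),
#' `enrich` (hypergeometric term enrichment of gene-body and promoter
#' DMG sets) and `bsp` (clone simulation and calling). Each stage writes
#' its outputs under `out_dir` and contributes to a machine-readable
#' `summary.json` recording the seed, a configuration hash and the key
#' counts. Identical config + seed give identical summaries.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages, or `"all"`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  all_stages <- c("simulate", "profile", "dmr", "enrich", "bsp")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hashed <- unclass(config)
  hashed$out_dir <- NULL   # identical analyses in different dirs hash alike
  summary <- list(seed = config$seed,
                  config_hash = rlang::hash(hashed),
                  groups = config$sim$groups, control = config$control,
                  stages = stages)
  inform(sprintf("[methylgraft] run %s | seed %d", summary$config_hash,
                 config$seed))

  sim <- simulate_genome(config$sim)
  methylome <- simulate_methylome(sim, config$sim)
  genes <- sim$genes
  control <- config$control
  others <- setdiff(config$sim$groups, control)

  if ("simulate" %in% stages) {
    write_simulation(sim, methylome, file.path(config$out_dir, "sim"))
    summary$n_sites <- purrr::map_int(methylome$calls, nrow)
    summary$n_planted_dmrs <- nrow(methylome$truth)
  }

  if ("profile" %in% stages) {
    pdir <- file.path(config$out_dir, "profile")
    dir.create(pdir, showWarnings = FALSE)
    props <- purrr::imap_dfr(methylome$calls, function(calls, grp) {
      context_proportions(calls, min_cov = config$min_cov) %>%
        mutate(group = grp, .before = 1)
    })
    readr::write_tsv(props, file.path(pdir, "context_proportions.tsv"),
                     progress = FALSE)
    parts <- partition_genes(genes, sim$chrom_lengths, flank = config$flank)
    tracks <- bind_rows(
      sim$cpg_islands %>% mutate(feature = "cpg_island"),
      sim$repeats %>% mutate(feature = "repeat"),
      tibble(chrom = genes$chrom, start = genes$tx_start - 1L,
             end = genes$tx_end, feature = "mRNA")
    )
    prof <- feature_profile(methylome$calls, parts, tracks = tracks,
                            context = "CG")
    readr::write_tsv(prof, file.path(pdir, "feature_profile.tsv"),
                     progress = FALSE)
    kmers <- kmer_preference(methylome$calls[[control]], sim$genome)
    readr::write_tsv(kmers, file.path(pdir, "kmer_preference.tsv"),
                     progress = FALSE)
    for (grp in names(methylome$calls)) {
      tiles <- tile_methylation(methylome$calls[[grp]], sim$chrom_lengths,
                                tile_bp = config$tile_bp, context = "CG")
      write_bedgraph(tiles %>% filter(!is.na(.data$value)),
                     file.path(pdir, sprintf("tiles_%s.bedGraph", grp)),
                     name = sprintf("CG tiles %s", grp))
    }
    summary$context_proportions <- split(
      setNames(props$share_pct, props$context), props$group)
  }

  dmg_sets <- list()
  if ("dmr" %in% stages) {
    ddir <- file.path(config$out_dir, "dmr")
    dir.create(ddir, showWarnings = FALSE)
    summary$comparisons <- list()
    for (grp in others) {
      res <- call_dmrs(methylome$calls[[control]], methylome$calls[[grp]],
                       sim$chrom_lengths, contexts = config$contexts,
                       window_bp = config$window_bp,
                       min_sites = config$min_sites,
                       min_fold = config$min_fold, alpha = config$alpha,
                       floor = config$floor,
                       hypo_rule = config$hypo_rule,
                       max_gap = config$max_gap,
                       groups = c(control, grp))
      tag <- sprintf("%s_vs_%s", control, grp)
      dmrs <- tidy(res) %>%
        mutate(diff_score = degree_of_difference(.data$level_1,
                                                 .data$level_2)$score)
      readr::write_tsv(res$windows, file.path(ddir, sprintf("windows_%s.tsv", tag)),
                       progress = FALSE)
      readr::write_tsv(dmrs, file.path(ddir, sprintf("dmrs_%s.tsv", tag)),
                       progress = FALSE)
      write_dmr_bed(res, file.path(ddir, sprintf("dmrs_%s.bed", tag)))
      dmgs <- assign_dmgs(res, genes, promoter_len = config$promoter_len,
                          chrom_lengths = sim$chrom_lengths)
      readr::write_tsv(dmgs, file.path(ddir, sprintf("dmgs_%s.tsv", tag)),
                       progress = FALSE)
      dmg_sets[[tag]] <- dmgs
      tall <- count_dmgs(dmgs)
      summary$comparisons[[tag]] <- list(
        n_windows_tested = sum(res$windows$eligible),
        n_dmrs = nrow(dmrs),
        n_dmgs = setNames(as.list(tall$n_genes), tall$location)
      )
    }
  }

  if ("enrich" %in% stages) {
    edir <- file.path(config$out_dir, "enrich")
    dir.create(edir, showWarnings = FALSE)
    tm <- config$term_map
    if (is.character(tm)) tm <- read_term_map(tm)
    if (is.null(tm)) {
      tm <- simulate_term_map(genes$gene_id, seed = config$seed)
    }
    summary$enrichment <- list()
    for (tag in names(dmg_sets)) {
      for (loc in c("gene_body", "promoter")) {
        set <- dmg_sets[[tag]] %>%
          filter(.data$location == loc) %>%
          dplyr::pull(.data$gene_id) %>% unique()
        set <- intersect(set, unique(tm$gene_id))
        if (length(set) == 0) next
        res <- enrich_dmgs(set, tm)
        f <- file.path(edir, sprintf("enrich_%s_%s.tsv", tag, loc))
        readr::write_tsv(res, f, progress = FALSE)
        summary$enrichment[[paste(tag, loc, sep = ":")]] <-
          sum(res$significant)
      }
    }
  }

  if ("bsp" %in% stages) {
    bdir <- file.path(config$out_dir, "bsp")
    dir.create(bdir, showWarnings = FALSE)
    bsp <- simulate_bsp(seed = config$seed, conversion_rate = 0.99)
    result <- bsp_analyze(bsp$reference, bsp$clones,
                          min_conversion = config$min_conversion)
    mat <- bsp_matrix(result)
    write_bsp_matrix(mat, file.path(bdir, "matrix.tsv"),
                     file.path(bdir, "summary.tsv"))
    writeLines(format(mat), file.path(bdir, "lollipop.txt"))
    summary$bsp <- list(n_clones_pass = length(mat$clone_ids),
                        n_cpgs = length(mat$cpg_positions))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
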