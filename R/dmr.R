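#' Windowed two-group differential-methylation scan
#'
#' Tiles the genome into non-overlapping windows (optionally sliding by
#' half a window) and, per window, pools read counts for each group,
#' computes weighted levels, a fold change and a two-sided Fisher exact P
#' on the pooled 2x2 read-count table. A window passes — i.e. is a
#' putative differentially methylated region (DMR) — when it has at least
#' `min_sites` covered cytosines of the context in *each* group, at least
#' a `min_fold` change in methylation level, Fisher P below `alpha`, and
#' neither group is hypomethylated (window level below `floor`).
#'
#' The fold change is `max(level) / max(min(level), floor)` — the floor
#' acts as a pseudo-level lower bound so the ratio is always defined.
#' With `hypo_rule = "both"` (the default, the literal reading of
#' "neither group should be hypomethylated") both groups' levels must be
#' at or above `floor`; `"either"` only requires that not both be below.
#'
#' @param calls_g1,calls_g2 Call tibbles for group 1 (control) and
#'   group 2.
#' @param chrom_lengths Named vector of contig lengths.
#' @param context Context to test (one of `"CG"`, `"CHG"`, `"CHH"`).
#' @param window_bp Window width (default 1000).
#' @param sliding If `TRUE`, windows advance by `window_bp / 2`.
#' @param min_sites Minimum covered cytosines per group (default 5).
#' @param min_fold Minimum fold change (default 2).
#' @param alpha Fisher P threshold (default 0.05).
#' @param floor Hypomethylation floor on the window level (default 0.05).
#' @param hypo_rule `"both"` or `"either"` (see Details).
#' @return A tibble of window statistics: `chrom`, `start`, `end`,
#'   `context`, per-group site and read counts (`n_sites_1`, `n_meth_1`,
#'   `n_unmeth_1`, ...), weighted `level_1`, `level_2`, `fold`, `p`,
#'   `direction` (`hyper`/`hypo` in group 2 relative to group 1),
#'   `eligible` (site filter met) and `pass`. P values are computed only
#'   for eligible windows.
#' @export
window_scan <- function(calls_g1, calls_g2, chrom_lengths, context = "CG",
                        window_bp = 1000, sliding = FALSE, min_sites = 5,
                        min_fold = 2, alpha = 0.05, floor = 0.05,
                        hypo_rule = c("both", "either")) {
  hypo_rule <- match.arg(hypo_rule)
  check_context_arg(context)
  windows <- make_windows(chrom_lengths, window_bp)
  if (sliding) {
    half <- purrr::map_dfr(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      s <- seq.int(window_bp %/% 2, L - 1L, by = window_bp)
      tibble(chrom = ch, start = s, end = pmin(s + window_bp, L))
    })
    windows <- bind_rows(windows, half) %>% arrange(.data$chrom, .data$start)
  }
  g1 <- region_level(calls_g1, windows, context = context) %>%
    rename(n_sites_1 = "n_sites", n_meth_1 = "n_meth",
           n_unmeth_1 = "n_unmeth", level_1 = "level")
  g2 <- region_level(calls_g2, windows, context = context) %>%
    select("n_sites", "n_meth", "n_unmeth", "level") %>%
    rename(n_sites_2 = "n_sites", n_meth_2 = "n_meth",
           n_unmeth_2 = "n_unmeth", level_2 = "level")
  w <- bind_cols(g1, g2) %>%
    mutate(
      context = context,
      eligible = .data$n_sites_1 >= min_sites & .data$n_sites_2 >= min_sites &
        !is.na(.data$level_1) & !is.na(.data$level_2),
      fold = fold_change(.data$level_1, .data$level_2, floor),
      direction = if_else(.data$level_2 >= .data$level_1, "hyper", "hypo"),
      p = NA_real_
    )
  idx <- which(w$eligible)
  if (length(idx) > 0) {
    w$p[idx] <- fisher_exact_two_sided(
      w$n_meth_1[idx], w$n_unmeth_1[idx], w$n_meth_2[idx], w$n_unmeth_2[idx])
  }
  w %>%
    mutate(
      hypo_ok = hypo_pass(.data$level_1, .data$level_2, floor, hypo_rule),
      pass = .data$eligible & !is.na(.data$p) & .data$p < alpha &
        .data$fold >= min_fold & .data$hypo_ok
    ) %>%
    select("chrom", "start", "end", "context",
           "n_sites_1", "n_meth_1", "n_unmeth_1", "level_1",
           "n_sites_2", "n_meth_2", "n_unmeth_2", "level_2",
           "fold", "p", "direction", "eligible", "pass")
}

#' @noRd
fold_change <- function(l1, l2, floor) {
  hi <- pmax(l1, l2)
  lo <- pmax(pmin(l1, l2), floor)
  hi / lo
}

#' @noRd
hypo_pass <- function(l1, l2, floor, rule) {
  if (rule == "both") l1 >= floor & l2 >= floor
  else !(l1 < floor & l2 < floor)
}

#' Iteratively merge interdependent DMR windows
#'
#' Two neighbouring passing windows (same chromosome, context and
#' direction, separated by at most `max_gap` bp with no other passing
#' window between them) are *interdependent* when the span from the
#' beginning of the upstream window to the end of the downstream window
#' itself shows at least a `min_fold` methylation change with Fisher
#' P < `alpha` (and satisfies the hypomethylation floor) on counts
#' re-pooled from the raw calls over the whole span. Interdependent pairs
#' are combined into one continuous DMR; merging proceeds strictly left
#' to right per chromosome and restarts after every merge until a full
#' pass makes no change, so the returned set is a fixed point: no
#' neighbouring pair in it satisfies the merge criterion, and re-running
#' the merge changes nothing.
#'
#' @param windows Window table from [window_scan()] (only rows with
#'   `pass = TRUE` are used; a ready-made DMR table is also accepted).
#' @inheritParams window_scan
#' @param max_gap Maximum gap in bp between neighbours (default 1000).
#' @return A DMR tibble: `chrom`, `start`, `end`, `context`, pooled
#'   per-group counts and levels over the final span, `fold`, `p`,
#'   `direction`, `merged_from` (number of windows absorbed).
#' @export
merge_interdependent <- function(windows, calls_g1, calls_g2, max_gap = 1000,
                                 min_fold = 2, alpha = 0.05, floor = 0.05,
                                 hypo_rule = c("both", "either")) {
  hypo_rule <- match.arg(hypo_rule)
  dmrs <- windows
  if ("pass" %in% names(dmrs)) dmrs <- dmrs[dmrs$pass, , drop = FALSE]
  if (nrow(dmrs) == 0) return(empty_dmr_tbl())
  if (!"merged_from" %in% names(dmrs)) dmrs$merged_from <- 1L
  keep <- c("chrom", "start", "end", "context",
            "n_sites_1", "n_meth_1", "n_unmeth_1", "level_1",
            "n_sites_2", "n_meth_2", "n_unmeth_2", "level_2",
            "fold", "p", "direction", "merged_from")
  dmrs <- dmrs[, keep] %>% arrange(.data$context, .data$chrom, .data$start)

  out <- list()
  for (key in unique(paste(dmrs$context, dmrs$chrom))) {
    sub <- dmrs[paste(dmrs$context, dmrs$chrom) == key, , drop = FALSE]
    ctx <- sub$context[1]; ch <- sub$chrom[1]
    c1 <- calls_g1[calls_g1$context == ctx & calls_g1$chrom == ch, , drop = FALSE]
    c2 <- calls_g2[calls_g2$context == ctx & calls_g2$chrom == ch, , drop = FALSE]
    rows <- split(sub, seq_len(nrow(sub)))
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < length(rows)) {
        A <- rows[[i]]; B <- rows[[i + 1]]
        gap <- B$start - A$end
        if (A$direction == B$direction && gap <= max_gap) {
          span <- span_stats(c1, c2, ch, ctx, A$start, B$end, floor)
          ok <- !is.na(span$level_1) && !is.na(span$level_2) &&
            span$fold >= min_fold && span$p < alpha &&
            hypo_pass(span$level_1, span$level_2, floor, hypo_rule)
          if (ok) {
            span$direction <- if (span$level_2 >= span$level_1) "hyper" else "hypo"
            span$merged_from <- A$merged_from + B$merged_from
            rows[[i]] <- span
            rows[[i + 1]] <- NULL
            merged_any <- TRUE
            i <- 1            # restart the pass after any merge
            next
          }
        }
        i <- i + 1
      }
      if (!merged_any) break
    }
    out <- c(out, rows)
  }
  bind_rows(out) %>% arrange(.data$context, .data$chrom, .data$start)
}

#' @noRd
span_stats <- function(c1, c2, chrom, context, start, end, floor) {
  iv <- tibble(chrom = chrom, start = start, end = end)
  s1 <- region_level(c1, iv)
  s2 <- region_level(c2, iv)
  tibble(
    chrom = chrom, start = start, end = end, context = context,
    n_sites_1 = s1$n_sites, n_meth_1 = s1$n_meth, n_unmeth_1 = s1$n_unmeth,
    level_1 = s1$level,
    n_sites_2 = s2$n_sites, n_meth_2 = s2$n_meth, n_unmeth_2 = s2$n_unmeth,
    level_2 = s2$level,
    fold = fold_change(s1$level, s2$level, floor),
    p = fisher_exact_two_sided(s1$n_meth, s1$n_unmeth, s2$n_meth, s2$n_unmeth),
    direction = NA_character_, merged_from = NA_integer_
  )
}

#' @noRd
empty_dmr_tbl <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         context = character(),
         n_sites_1 = integer(), n_meth_1 = integer(), n_unmeth_1 = integer(),
         level_1 = numeric(),
         n_sites_2 = integer(), n_meth_2 = integer(), n_unmeth_2 = integer(),
         level_2 = numeric(),
         fold = numeric(), p = numeric(), direction = character(),
         merged_from = integer())
}

#' Call differentially methylated regions between two groups
#'
#' Convenience wrapper running [window_scan()] and
#' [merge_interdependent()] for one or more contexts and returning a
#' `dmr_result` object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams window_scan
#' @inheritParams merge_interdependent
#' @param contexts Contexts to scan (default `"CG"` only).
#' @param groups Length-2 character vector of group labels
#'   (control first), used in summaries.
#' @return A `dmr_result`: list with `windows` (all window statistics),
#'   `dmrs` (final merged DMR table), `params` and `groups`.
#' @export
call_dmrs <- function(calls_g1, calls_g2, chrom_lengths, contexts = "CG",
                      window_bp = 1000, sliding = FALSE, min_sites = 5,
                      min_fold = 2, alpha = 0.05, floor = 0.05,
                      hypo_rule = c("both", "either"), max_gap = 1000,
                      groups = c("control", "treatment")) {
  hypo_rule <- match.arg(hypo_rule)
  windows <- purrr::map_dfr(contexts, function(ctx) {
    window_scan(calls_g1, calls_g2, chrom_lengths, context = ctx,
                window_bp = window_bp, sliding = sliding,
                min_sites = min_sites, min_fold = min_fold, alpha = alpha,
                floor = floor, hypo_rule = hypo_rule)
  })
  dmrs <- merge_interdependent(windows, calls_g1, calls_g2,
                               max_gap = max_gap, min_fold = min_fold,
                               alpha = alpha, floor = floor,
                               hypo_rule = hypo_rule)
  structure(
    list(windows = windows, dmrs = dmrs,
         params = list(contexts = contexts, window_bp = window_bp,
                       sliding = sliding, min_sites = min_sites,
                       min_fold = min_fold, alpha = alpha, floor = floor,
                       hypo_rule = hypo_rule, max_gap = max_gap),
         groups = groups),
    class = "dmr_result")
}

#' Tally DMRs per context and direction
#'
#' @param x A `dmr_result` or a DMR tibble.
#' @return A tibble `context`, `direction`, `n`.
#' @export
count_dmrs <- function(x) {
  dmrs <- if (inherits(x, "dmr_result")) x$dmrs else x
  dmrs %>%
    group_by(.data$context, .data$direction) %>%
    summarise(n = n(), .groups = "drop")
}

#' Assign DMRs to genes (DMG calling)
#'
#' A gene is a *gene-body* DMR-associated gene (DMG) when at least one
#' DMR overlaps its span from the TSS to the transcript end by >= 1 bp,
#' and a *promoter* DMG when a DMR overlaps the `promoter_len` bp
#' immediately upstream of the TSS (in transcription orientation). One
#' gene can be both.
#'
#' @param x A `dmr_result` or DMR tibble.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param promoter_len Promoter length upstream of the TSS (default 2000).
#' @param chrom_lengths Optional contig lengths for clipping promoters.
#' @return A tibble of DMG records: `gene_id`, `location`
#'   (`gene_body`/`promoter`) and the overlapping DMR's coordinates,
#'   context, levels, P and direction.
#' @export
assign_dmgs <- function(x, genes, promoter_len = 2000, chrom_lengths = NULL) {
  dmrs <- if (inherits(x, "dmr_result")) x$dmrs else x
  empty <- tibble(gene_id = character(), location = character(),
                  chrom = character(), start = integer(), end = integer(),
                  context = character(), direction = character(),
                  level_1 = numeric(), level_2 = numeric(), p = numeric())
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(empty)
  minus <- genes$strand == "-"
  body <- tibble(gene_id = genes$gene_id, location = "gene_body",
                 chrom = genes$chrom,
                 start = genes$tx_start - 1L, end = genes$tx_end)
  prom <- tibble(
    gene_id = genes$gene_id, location = "promoter", chrom = genes$chrom,
    start = ifelse(minus, genes$tx_end, genes$tx_start - 1L - promoter_len),
    end = ifelse(minus, genes$tx_end + promoter_len, genes$tx_start - 1L)
  )
  regions <- bind_rows(body, prom) %>% mutate(start = pmax(.data$start, 0))
  if (!is.null(chrom_lengths)) {
    regions$end <- pmin(regions$end, unname(chrom_lengths[regions$chrom]))
  }
  regions <- regions[regions$start < regions$end, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(gr_from_intervals(dmrs),
                                      gr_from_intervals(regions))
  if (length(hits) == 0) return(empty)
  d <- dmrs[S4Vectors::queryHits(hits), ]
  r <- regions[S4Vectors::subjectHits(hits), ]
  tibble(gene_id = r$gene_id, location = r$location,
         chrom = d$chrom, start = d$start, end = d$end,
         context = d$context, direction = d$direction,
         level_1 = d$level_1, level_2 = d$level_2, p = d$p) %>%
    arrange(.data$gene_id, .data$location, .data$start)
}

#' @describeIn assign_dmgs Count distinct DMGs per location.
#' @param dmg_records Output of `assign_dmgs()`.
#' @export
count_dmgs <- function(dmg_records) {
  dmg_records %>%
    distinct(.data$gene_id, .data$location) %>%
    group_by(.data$location) %>%
    summarise(n_genes = n(), .groups = "drop")
}

#' Write DMRs as a BED6 file
#'
#' Name encodes `context:direction`; score is `-log10(p)` capped at 100;
#' strand is `.`.
#'
#' @param x A `dmr_result` or DMR tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(x, path) {
  dmrs <- if (inherits(x, "dmr_result")) x$dmrs else x
  bed <- dmrs %>%
    mutate(name = paste0(.data$context, ":", .data$direction),
           score = round(pmin(-log10(pmax(.data$p, 1e-100)), 100), 3),
           strand = ".") %>%
    select("chrom", "start", "end", "name", "score", "strand")
  write_bed(bed, path)
}
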