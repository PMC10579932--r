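#' Weighted methylation level of genomic intervals
#'
#' Pools read counts over all covered cytosines of a given context inside
#' each interval and computes the weighted methylation level
#' \eqn{R_m = N_m / (N_m + N_{nm})}, where \eqn{N_m} is the pooled count
#' of reads supporting methylation and \eqn{N_{nm}} the pooled count of
#' unmethylated reads. This is read-weighted pooling, not a mean of
#' per-site fractions, so the level over a union of disjoint intervals
#' equals the level computed from the re-pooled counts of its parts.
#'
#' @param calls A call tibble from [read_calls()].
#' @param intervals Interval tibble with `chrom`, `start`, `end`
#'   (0-based half-open); extra columns are carried through.
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`);
#'   `NULL` pools all contexts.
#' @return `intervals` with added columns `n_sites` (covered cytosines),
#'   `n_meth`, `n_unmeth` (pooled read counts) and `level`; `level` is
#'   `NA` for intervals with no covered site.
#' @export
region_level <- function(calls, intervals, context = NULL) {
  check_intervals(intervals)
  if (!is.null(context)) {
    check_context_arg(context)
    calls <- calls[calls$context %in% context, , drop = FALSE]
  }
  n_sites <- integer(nrow(intervals))
  nm <- integer(nrow(intervals))
  nnm <- integer(nrow(intervals))
  if (nrow(calls) > 0 && nrow(intervals) > 0) {
    hits <- GenomicRanges::findOverlaps(gr_from_calls(calls), gr_from_intervals(intervals))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    covered <- calls$n_total[q] > 0
    q <- q[covered]; s <- s[covered]
    if (length(s) > 0) {
      agg <- rowsum(cbind(site = 1L, nm = calls$n_meth[q], nnm = calls$n_unmeth[q]), s)
      i <- as.integer(rownames(agg))
      n_sites[i] <- agg[, "site"]
      nm[i] <- agg[, "nm"]
      nnm[i] <- agg[, "nnm"]
    }
  }
  intervals %>%
    mutate(
      n_sites = n_sites, n_meth = nm, n_unmeth = nnm,
      level = if_else(nm + nnm > 0, nm / (nm + nnm), NA_real_)
    )
}

#' Degree of difference between two methylation levels
#'
#' Per-site (or per-region) comparison score between a control level
#' `rm1` and a treatment level `rm2`, defined as
#' \eqn{\log_2(R_{m1}) / \log_2(R_{m2})}. A level equal to zero is
#' replaced by 0.001 before taking logs. When `rm2` is 1 the denominator
#' is zero and the score is flagged infinite rather than raising an
#' error.
#'
#' @param rm1,rm2 Numeric vectors of methylation levels in \[0, 1\]
#'   (control and treatment respectively), recycled to a common length.
#' @param zero_sub Replacement value for exact zeros before the log
#'   (default 0.001).
#' @return A tibble with `rm1`, `rm2`, `score`, and flags
#'   `zero_substituted` and `infinite`.
#' @examples
#' degree_of_difference(0.25, 0.5) # score 2
#' @export
degree_of_difference <- function(rm1, rm2, zero_sub = 0.001) {
  n <- max(length(rm1), length(rm2))
  rm1 <- rep_len(as.numeric(rm1), n)
  rm2 <- rep_len(as.numeric(rm2), n)
  if (any(rm1 < 0 | rm1 > 1 | rm2 < 0 | rm2 > 1, na.rm = TRUE)) {
    abort("methylation levels must lie in [0, 1]")
  }
  zsub <- (rm1 == 0) | (rm2 == 0)
  r1 <- if_else(rm1 == 0, zero_sub, rm1)
  r2 <- if_else(rm2 == 0, zero_sub, rm2)
  score <- log2(r1) / log2(r2)
  tibble(
    rm1 = rm1, rm2 = rm2, score = score,
    zero_substituted = zsub,
    infinite = is.infinite(score) | is.nan(score)
  )
}

#' Context composition of methylated cytosines
#'
#' Tallies methylated sites by sequence context and returns the share of
#' mCG, mCHG and mCHH among all methylated sites. A site counts as
#' methylated when it satisfies `site_rule`; the default rule requires at
#' least `min_meth` methylated reads at a coverage of at least `min_cov`
#' reads.
#'
#' @param calls A call tibble.
#' @param min_cov Minimum coverage for a site to be assessed (default 4).
#' @param min_meth Minimum methylated reads to call a site methylated
#'   (default 1).
#' @param site_rule Optional function `calls -> logical` overriding the
#'   default rule.
#' @return A tibble with one row per context: `context`, `n_sites`,
#'   `share_pct` (summing to 100). If no site is methylated the shares
#'   are `NA` and the result carries attribute `undefined = TRUE`.
#' @export
context_proportions <- function(calls, min_cov = 4, min_meth = 1,
                                site_rule = NULL) {
  if (is.null(site_rule)) {
    site_rule <- function(x) x$n_meth >= min_meth & x$n_total >= min_cov
  }
  meth <- calls[site_rule(calls), , drop = FALSE]
  counts <- table(factor(meth$context, levels = CONTEXTS))
  out <- tibble(
    context = CONTEXTS,
    n_sites = as.integer(counts),
    share_pct = if (sum(counts) > 0) 100 * as.integer(counts) / sum(counts)
                else rep(NA_real_, 3)
  )
  if (sum(counts) == 0) attr(out, "undefined") <- TRUE
  out
}

#' Normalize a methylation trajectory to fractions
#'
#' Divides each value of one feature's methylation level across time
#' points by the row total, so the output sums to 1. An all-zero input
#' returns all zeros with attribute `all_zero = TRUE`.
#'
#' @param values Non-negative numeric vector (one feature across T time
#'   points).
#' @return Numeric vector of fractions.
#' @export
normalize_track <- function(values) {
  if (any(values < 0, na.rm = TRUE)) abort("values must be non-negative")
  total <- sum(values, na.rm = TRUE)
  if (total == 0) {
    out <- rep(0, length(values))
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  values / total
}

#' @describeIn normalize_track Normalize a long feature-profile table
#'   (as from [feature_profile()]) so that each feature's levels sum to 1
#'   across groups/time points. Adds a `fraction` column.
#' @param profile A tibble with columns `feature`, `group`, `level`.
#' @export
normalize_profile <- function(profile) {
  profile %>%
    group_by(.data$feature) %>%
    mutate(fraction = {
      v <- .data$level
      v[is.na(v)] <- 0
      tot <- sum(v)
      if (tot == 0) rep(0, length(v)) else v / tot
    }) %>%
    ungroup()
}

#' Tiled chromosome methylation map
#'
#' Computes the weighted methylation level in non-overlapping tiles along
#' each chromosome — the numeric track behind a chromosome-scale
#' methylation heat map. The level is multiplied by `scale` (default 20,
#' i.e. rendered on a 0–20 scale) purely for presentation.
#'
#' @param calls A call tibble.
#' @param chrom_lengths Named integer vector of contig lengths.
#' @param tile_bp Tile width in bp (default 10000).
#' @param context Optional context filter.
#' @param scale Multiplier applied to the level (default 20).
#' @return A tibble `chrom`, `start`, `end`, `value` suitable for
#'   [write_bedgraph()]. Tiles without coverage have `value` `NA`.
#' @export
tile_methylation <- function(calls, chrom_lengths, tile_bp = 10000,
                             context = NULL, scale = 20) {
  tiles <- make_windows(chrom_lengths, tile_bp)
  region_level(calls, tiles, context = context) %>%
    mutate(value = .data$level * scale) %>%
    select("chrom", "start", "end", "value")
}

#' Tile a genome into non-overlapping windows
#'
#' @param chrom_lengths Named integer vector of contig lengths.
#' @param window_bp Window width in bp.
#' @return Interval tibble `chrom`, `start`, `end` (0-based half-open);
#'   the last window of each contig is truncated at the contig end.
#' @export
make_windows <- function(chrom_lengths, window_bp) {
  if (window_bp <= 0) abort("window_bp must be positive")
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(0L, L - 1L, by = window_bp)
    tibble(chrom = ch, start = starts, end = pmin(starts + window_bp, L))
  })
}
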