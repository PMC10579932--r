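#' Partition gene models into methylation-profile features
#'
#' Decomposes each transcript into the features used for gene-region
#' methylation profiling: `upstream` (the `flank` bp 5' of the TSS),
#' `first_exon`, `first_intron`, `internal_exon`, `internal_intron`,
#' `last_exon`, `downstream` (the `flank` bp 3' of the transcript end),
#' plus `promoter` (identical span to `upstream`) and `gene_body` (TSS to
#' transcript end). "First"/"last" are in transcription order, so the
#' genomic order is mirrored for minus-strand genes. A single-exon gene
#' contributes only `first_exon` (plus flanks, promoter and gene body);
#' a two-exon gene has a first and last exon but no internal features.
#' Flanks are clipped at contig bounds when `chrom_lengths` is given.
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param chrom_lengths Optional named vector of contig lengths for
#'   clipping flanks.
#' @param flank Flank length in bp for upstream/downstream/promoter
#'   (default 2000).
#' @return An interval tibble `gene_id`, `chrom`, `strand`, `feature`,
#'   `start`, `end` (0-based half-open). Zero-width clipped flanks are
#'   dropped.
#' @export
partition_genes <- function(genes, chrom_lengths = NULL, flank = 2000) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1]]        # transcription order, 1-based inclusive
    E <- nrow(ex)
    minus <- g$strand == "-"
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[g$chrom]] else Inf

    iv <- function(feature, start0, end0) {
      start0 <- max(start0, 0)
      end0 <- min(end0, L)
      if (start0 >= end0) return(NULL)
      tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             feature = feature, start = start0, end = end0)
    }
    to0 <- function(s1, e1) c(s1 - 1L, e1)  # 1-based inclusive -> 0-based half-open

    rows <- list()
    # flanks in transcription orientation
    if (!minus) {
      up <- c(g$tx_start - 1L - flank, g$tx_start - 1L)
      dn <- c(g$tx_end, g$tx_end + flank)
    } else {
      up <- c(g$tx_end, g$tx_end + flank)
      dn <- c(g$tx_start - 1L - flank, g$tx_start - 1L)
    }
    rows <- c(rows, list(
      iv("upstream", up[1], up[2]),
      iv("promoter", up[1], up[2]),
      iv("downstream", dn[1], dn[2]),
      iv("gene_body", g$tx_start - 1L, g$tx_end)
    ))

    exon_class <- function(j) {
      if (j == 1) "first_exon"
      else if (j == E && E >= 2) "last_exon"
      else "internal_exon"
    }
    for (j in seq_len(E)) {
      z <- to0(ex$start[j], ex$end[j])
      rows <- c(rows, list(iv(exon_class(j), z[1], z[2])))
    }
    # introns between consecutive exons in transcription order
    if (E >= 2) {
      for (j in seq_len(E - 1)) {
        a <- ex[j, ]; b <- ex[j + 1, ]
        lo <- min(a$end, b$end); hi <- max(a$start, b$start)
        cls <- if (j == 1) "first_intron" else "internal_intron"
        rows <- c(rows, list(iv(cls, lo, hi - 1L)))
      }
    }
    bind_rows(rows)
  })
}

#' All feature labels emitted by [partition_genes()]
#' @export
gene_features <- function() {
  c("upstream", "promoter", "first_exon", "first_intron", "internal_exon",
    "internal_intron", "last_exon", "downstream", "gene_body")
}

#' Feature-by-group methylation profile
#'
#' Computes, for every feature label and every sample group, the weighted
#' methylation level pooled over all intervals genome-wide that carry the
#' label (read-weighted pooling, not a mean of per-gene means). Gene
#' features come from [partition_genes()]; additional genome tracks
#' (repeats, CpG islands, mRNA spans, ...) can be appended via `tracks`.
#'
#' @param call_sets Named list of call tibbles, one per group.
#' @param partitions Feature intervals from [partition_genes()].
#' @param tracks Optional interval tibble with columns `chrom`, `start`,
#'   `end`, `feature` for extra genome-wide tracks.
#' @param context Context to profile (default `"CG"`).
#' @param features Optional subset of feature labels to report; labels
#'   absent from `partitions`/`tracks` raise an error.
#' @return A long tibble `feature`, `group`, `context`, `n_sites`,
#'   `n_meth`, `n_unmeth`, `level`; `level` is `NA` for features with no
#'   covered site.
#' @export
feature_profile <- function(call_sets, partitions, tracks = NULL,
                            context = "CG", features = NULL) {
  if (is.data.frame(call_sets)) call_sets <- list(group1 = call_sets)
  if (is.null(names(call_sets)) || any(names(call_sets) == "")) {
    abort("call_sets must be a named list of call tibbles")
  }
  check_context_arg(context)
  iv <- bind_rows(
    partitions %>% select("chrom", "start", "end", "feature"),
    if (!is.null(tracks)) tracks %>% select("chrom", "start", "end", "feature")
  )
  present <- unique(iv$feature)
  if (is.null(features)) features <- present
  unknown <- setdiff(features, present)
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature label(s): %s", paste(unknown, collapse = ", ")))
  }
  iv <- iv[iv$feature %in% features, , drop = FALSE]
  purrr::imap_dfr(call_sets, function(calls, grp) {
    region_level(calls, iv, context = context) %>%
      group_by(.data$feature) %>%
      summarise(n_sites = sum(.data$n_sites),
                n_meth = sum(.data$n_meth),
                n_unmeth = sum(.data$n_unmeth), .groups = "drop") %>%
      mutate(
        group = grp, context = context,
        level = if_else(.data$n_meth + .data$n_unmeth > 0,
                        .data$n_meth / (.data$n_meth + .data$n_unmeth),
                        NA_real_)
      )
  }) %>%
    mutate(feature = factor(.data$feature, levels = union(gene_features(), features))) %>%
    arrange(.data$feature, .data$group) %>%
    mutate(feature = as.character(.data$feature)) %>%
    select("feature", "group", "context", "n_sites", "n_meth", "n_unmeth", "level")
}
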