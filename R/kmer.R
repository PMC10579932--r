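#' Sequence preference of methylation by flanking k-mer
#'
#' Tabulates, for every observed k-mer with the cytosine at a fixed
#' position (default 7-mers with the C at position 4, i.e. three bases of
#' flank on each side, read on the site's own strand), the pooled
#' methylation level and the number of contributing sites, per context.
#' Sites whose flanks run off the contig or contain a non-ACGT base are
#' excluded and tallied in the `n_excluded` attribute, so
#' `sum(n_sites) + n_excluded` always equals the number of input calls.
#'
#' @param calls A call tibble from [read_calls()].
#' @param genome Genome as in [classify_context()].
#' @param k K-mer width (default 7).
#' @param center 1-based position of the cytosine within the k-mer
#'   (default 4).
#' @param measure `"weighted"` (pooled reads, the default) or
#'   `"site_fraction"` (share of sites called methylated under
#'   `site_rule`).
#' @param site_rule Methylated-site rule for `measure =
#'   "site_fraction"`; defaults to >= 1 methylated read at coverage
#'   >= 4.
#' @return A tibble `kmer`, `context`, `n_sites`, `n_meth`, `n_unmeth`,
#'   `level`, sorted by `(context, kmer)`, with attribute `n_excluded`.
#' @export
kmer_preference <- function(calls, genome, k = 7, center = 4,
                            measure = c("weighted", "site_fraction"),
                            site_rule = NULL) {
  measure <- match.arg(measure)
  if (center < 1 || center > k) abort("center must lie within the k-mer")
  genome <- as_genome(genome)
  left <- center - 1L    # bases 5' of the C on its own strand
  right <- k - center    # bases 3'
  kmers <- rep(NA_character_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    seq_chr <- as.character(genome[[ch]])
    L <- nchar(seq_chr)
    pos <- calls$pos[idx]
    plus <- calls$strand[idx] == "+"
    # plus-strand window [pos-left, pos+right]; minus-strand window is the
    # reverse complement of [pos-right, pos+left]
    lo <- ifelse(plus, pos - left, pos - right)
    hi <- ifelse(plus, pos + right, pos + left)
    ok <- lo >= 1 & hi <= L
    sub <- substring(seq_chr, pmax(lo, 1), pmin(hi, L))
    if (any(!plus & ok)) {
      m <- which(!plus & ok)
      sub[m] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(sub[m])))
    }
    ok <- ok & !grepl("[^ACGT]", sub)
    kmers[idx[ok]] <- sub[ok]
  }
  keep <- !is.na(kmers)
  x <- calls[keep, , drop = FALSE]
  x$kmer <- kmers[keep]
  if (is.null(site_rule)) {
    site_rule <- function(cc) cc$n_meth >= 1 & cc$n_total >= 4
  }
  x$site_meth <- site_rule(x)
  out <- x %>%
    group_by(.data$kmer, .data$context) %>%
    summarise(n_sites = n(), n_meth = sum(.data$n_meth),
              n_unmeth = sum(.data$n_unmeth),
              site_frac = mean(.data$site_meth), .groups = "drop") %>%
    mutate(level = if (measure == "weighted") {
      if_else(.data$n_meth + .data$n_unmeth > 0,
              .data$n_meth / (.data$n_meth + .data$n_unmeth), NA_real_)
    } else {
      .data$site_frac
    }) %>%
    select("kmer", "context", "n_sites", "n_meth", "n_unmeth", "level") %>%
    arrange(.data$context, .data$kmer)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
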