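# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: probabilities from log-binomial coefficients, and
# sequence context from a literal double-strand string scan.

# Exhaustive two-sided Fisher P: enumerate every 2x2 table with the observed
# margins, probability from lchoose, sum those no more probable than observed.
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Brute-force context scan: classify position `pos` (1-based, plus-strand
# coordinates) by literal substring inspection; for the minus strand the
# whole sequence is reverse-complemented and the position remapped.
oracle_context <- function(seq_chr, pos, strand) {
  classify_fwd <- function(s, p) {
    L <- nchar(s)
    if (substr(s, p, p) != "C") stop("not a C")
    b1 <- if (p + 1 <= L) substr(s, p + 1, p + 1) else ""
    if (b1 == "G") return("CG")
    if (!b1 %in% c("A", "C", "T")) return(NA_character_)
    b2 <- if (p + 2 <= L) substr(s, p + 2, p + 2) else ""
    if (b2 == "G") return("CHG")
    if (b2 %in% c("A", "C", "T")) return("CHH")
    NA_character_
  }
  if (strand == "+") {
    classify_fwd(seq_chr, pos)
  } else {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
    classify_fwd(rc, nchar(seq_chr) - pos + 1)
  }
}

# random sequence helpers
random_dna <- function(n, gc = 0.4, n_frac = 0) {
  p <- c(A = (1 - gc) / 2 * (1 - n_frac), C = gc / 2 * (1 - n_frac),
         G = gc / 2 * (1 - n_frac), T = (1 - gc) / 2 * (1 - n_frac),
         N = n_frac)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# overlap-based sensitivity/precision against a truth interval table
recovery_stats <- function(called, truth) {
  if (nrow(called) == 0) return(list(sensitivity = 0, precision = NA_real_))
  gr_c <- GenomicRanges::GRanges(called$chrom,
                                 IRanges::IRanges(called$start + 1, called$end))
  gr_t <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start + 1, truth$end))
  ov <- GenomicRanges::findOverlaps(gr_c, gr_t)
  list(
    sensitivity = length(unique(S4Vectors::subjectHits(ov))) / nrow(truth),
    precision = length(unique(S4Vectors::queryHits(ov))) / nrow(called)
  )
}

# tiny call-table constructor
make_calls <- function(chrom, pos, strand = "+", context = "CG",
                       n_meth, n_total) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, n_meth = as.integer(n_meth),
                 n_unmeth = as.integer(n_total - n_meth),
                 n_total = as.integer(n_total))
}
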