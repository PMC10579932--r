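#' Classify the sequence context of cytosines
#'
#' Determines the methylation context — `CG`, `CHG` or `CHH`
#' (H = A, C or T) — of reference cytosines from the genome sequence.
#' The context is read 3' of the cytosine on its own strand: `CG` if the
#' next base is G, `CHG` if the base after next is G, `CHH` otherwise.
#' On the minus strand the cytosine sits opposite a plus-strand G and the
#' downstream bases are the reverse complement of the plus-strand bases
#' to its left.
#'
#' @param genome A named `DNAStringSet`, named character vector, or path
#'   to a FASTA file.
#' @param chrom,pos,strand Vectors (recycled to a common length) giving
#'   the site positions; `pos` is 1-based on the plus strand.
#' @return A character vector of contexts; `NA` where the context is
#'   undefined because a needed base is `N` or lies beyond the contig end.
#'   Sites whose reference base is not a cytosine on the given strand
#'   raise an error.
#' @examples
#' classify_context(c(chrA = "ACGTCAGCAT"), "chrA", c(2, 5), "+")
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  genome <- as_genome(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) abort(sprintf("chromosome '%s' not in genome", ch))
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    L <- length(s)
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (any(p < 1 | p > L)) abort("position outside contig")
    plus <- strand[idx] == "+"
    base <- s[p]
    if (any(plus & base != "C") || any(!plus & base != "G")) {
      abort("reference base is not a cytosine on the requested strand")
    }
    # bases 3' of the cytosine on its own strand
    off1 <- ifelse(plus, p + 1L, p - 1L)
    off2 <- ifelse(plus, p + 2L, p - 2L)
    b1 <- ifelse(off1 >= 1 & off1 <= L, s[pmax(pmin(off1, L), 1L)], NA)
    b2 <- ifelse(off2 >= 1 & off2 <= L, s[pmax(pmin(off2, L), 1L)], NA)
    b1 <- ifelse(plus, b1, chartr("ACGTN", "TGCAN", b1))
    b2 <- ifelse(plus, b2, chartr("ACGTN", "TGCAN", b2))
    ctx <- rep(NA_character_, length(p))
    ctx[!is.na(b1) & b1 == "G"] <- "CG"
    hb1 <- !is.na(b1) & b1 %in% c("A", "C", "T")
    ctx[hb1 & !is.na(b2) & b2 == "G"] <- "CHG"
    ctx[hb1 & !is.na(b2) & b2 %in% c("A", "C", "T")] <- "CHH"
    out[idx] <- ctx
  }
  out
}

#' Enumerate every cytosine in a genome with its context
#'
#' Scans both strands of every contig and returns all reference cytosines
#' (plus-strand C and minus-strand C, i.e. plus-strand G) together with
#' their CG/CHG/CHH context. Sites with undefined context (flanking `N`
#' or contig edge) are dropped.
#'
#' @inheritParams classify_context
#' @return A tibble `chrom`, `pos` (1-based), `strand`, `context`, sorted
#'   by `(chrom, pos, strand)`.
#' @export
enumerate_cytosines <- function(genome) {
  genome <- as_genome(genome)
  purrr::map_dfr(names(genome), function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    L <- length(s)
    # plus strand: C at p, context from s[p+1], s[p+2]
    p <- which(s == "C")
    b1 <- ifelse(p + 1L <= L, s[pmin(p + 1L, L)], NA)
    b2 <- ifelse(p + 2L <= L, s[pmin(p + 2L, L)], NA)
    ctx_p <- context_from_bases(b1, b2)
    # minus strand: C opposite plus-strand G at p; own-strand downstream
    # bases are complements of s[p-1], s[p-2]
    q <- which(s == "G")
    c1 <- ifelse(q - 1L >= 1, chartr("ACGTN", "TGCAN", s[pmax(q - 1L, 1L)]), NA)
    c2 <- ifelse(q - 2L >= 1, chartr("ACGTN", "TGCAN", s[pmax(q - 2L, 1L)]), NA)
    ctx_m <- context_from_bases(c1, c2)
    bind_rows(
      tibble(chrom = ch, pos = p, strand = "+", context = ctx_p),
      tibble(chrom = ch, pos = q, strand = "-", context = ctx_m)
    ) %>%
      filter(!is.na(.data$context)) %>%
      arrange(.data$pos, .data$strand)
  })
}

#' @noRd
context_from_bases <- function(b1, b2) {
  ctx <- rep(NA_character_, length(b1))
  ctx[!is.na(b1) & b1 == "G"] <- "CG"
  h1 <- !is.na(b1) & b1 %in% c("A", "C", "T")
  ctx[h1 & !is.na(b2) & b2 == "G"] <- "CHG"
  ctx[h1 & !is.na(b2) & b2 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

#' Cross-check the context column of a call table against the genome
#'
#' Re-derives every call's context from the reference sequence and
#' reports disagreements. Useful because call files are trusted on read.
#'
#' @param calls A call tibble from [read_calls()].
#' @inheritParams classify_context
#' @return A tibble of mismatching calls with an extra `context_genome`
#'   column (zero rows when everything agrees).
#' @export
verify_context <- function(calls, genome) {
  derived <- classify_context(genome, calls$chrom, calls$pos, calls$strand)
  calls %>%
    mutate(context_genome = derived) %>%
    filter(is.na(.data$context_genome) | .data$context_genome != .data$context)
}
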