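#' Read a per-cytosine methylation call table
#'
#' Reads a tab-separated per-cytosine call file in a CGmap-like dialect:
#' one cytosine per line with columns `chrom`, `pos` (1-based), `strand`
#' (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth` (reads supporting
#' methylation) and `n_total` (all reads covering the site). Lines starting
#' with `#` are comments. Records are validated strictly: a count of
#' methylated reads exceeding the total, an unknown context token, a
#' non-positive position or a bad strand raise an error naming the
#' offending file line rather than being coerced.
#'
#' @param path Path to a tab-separated call file.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `n_meth`, `n_unmeth`, `n_total`, sorted by `(chrom, pos)`. An empty
#'   file (or one containing only comments) yields a zero-row tibble.
#' @seealso [write_calls()]
#' @export
read_calls <- function(path) {
  cols <- readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    strand = readr::col_character(),
    context = readr::col_character(),
    n_meth = readr::col_double(),
    n_total = readr::col_double()
  )
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_names = names(cols$cols), col_types = cols,
    comment = "#", progress = FALSE
  ))
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), n_meth = integer(),
                  n_unmeth = integer(), n_total = integer()))
  }
  bad <- !is.finite(x$pos) | !is.finite(x$n_meth) | !is.finite(x$n_total) |
    x$pos < 1 | x$n_meth < 0 | x$n_total < x$n_meth |
    !(x$context %in% CONTEXTS) | !(x$strand %in% c("+", "-"))
  if (any(bad)) {
    # map record index back to the physical file line for the error message
    lines <- readLines(path)
    data_lines <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
    i <- which(bad)[1]
    abort(sprintf(
      "malformed call record at line %d of %s: '%s' (check context token, strand, and n_meth <= n_total)",
      data_lines[i], path, lines[data_lines[i]]))
  }
  x %>%
    mutate(
      pos = as.integer(.data$pos),
      n_meth = as.integer(.data$n_meth),
      n_total = as.integer(.data$n_total),
      n_unmeth = .data$n_total - .data$n_meth
    ) %>%
    select("chrom", "pos", "strand", "context", "n_meth", "n_unmeth", "n_total") %>%
    arrange(.data$chrom, .data$pos)
}

#' Write a per-cytosine methylation call table
#'
#' Inverse of [read_calls()]: writing and re-reading a valid call table is
#' lossless, and writing the result of `read_calls()` reproduces the input
#' file byte for byte (modulo comment lines).
#'
#' @param calls A call tibble as returned by [read_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls %>%
    arrange(.data$chrom, .data$pos) %>%
    mutate(n_total = .data$n_meth + .data$n_unmeth) %>%
    select("chrom", "pos", "strand", "context", "n_meth", "n_total")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `mRNA` and `exon` features and returns one record per mRNA.
#' Exons are stored 1-based inclusive in transcription order (index 1 is
#' the 5'-most exon, so for minus-strand transcripts the genomic order is
#' reversed), and the TSS is the transcribed 5' end (feature start on `+`,
#' feature end on `-`). Exons whose `Parent` does not match any mRNA are
#' skipped with a warning; overlapping exons within one transcript are an
#' error.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per mRNA: `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` (1-based inclusive), `tss` (1-based), `n_exons`,
#'   and a list-column `exons` of tibbles with `start`, `end` in
#'   transcription order.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), tx_start = integer(),
                  tx_end = integer(), tss = integer(), n_exons = integer(),
                  exons = list())
  if (length(gff) == 0) return(empty)
  type <- as.character(gff$type)
  mrna <- gff[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0) return(empty)
  exon <- gff[type == "exon"]
  mrna_ids <- as.character(mrna$ID)
  exon_parent <- vapply(exon$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                        character(1))
  orphan <- is.na(exon_parent) | !(exon_parent %in% mrna_ids)
  if (any(orphan)) {
    warn(sprintf("%d exon feature(s) without a matching mRNA parent were skipped",
                 sum(orphan)))
    exon <- exon[!orphan]
    exon_parent <- exon_parent[!orphan]
  }
  exon_tbl <- tibble(
    parent = exon_parent,
    start = GenomicRanges::start(exon),
    end = GenomicRanges::end(exon)
  )
  purrr::map_dfr(seq_along(mrna), function(i) {
    id <- mrna_ids[i]
    strand <- as.character(GenomicRanges::strand(mrna[i]))
    ex <- exon_tbl %>% filter(.data$parent == id) %>% arrange(.data$start)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("transcript %s has overlapping exons", id))
    }
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    gene_parent <- mrna[i]$Parent
    gene_id <- if (length(gene_parent[[1]])) gene_parent[[1]][1] else id
    tibble(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(mrna[i])),
      strand = strand,
      tx_start = GenomicRanges::start(mrna[i]),
      tx_end = GenomicRanges::end(mrna[i]),
      tss = if (strand == "-") GenomicRanges::end(mrna[i]) else GenomicRanges::start(mrna[i]),
      n_exons = nrow(ex),
      exons = list(ex %>% select("start", "end"))
    )
  })
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon features (1-based inclusive, per the GFF3
#' standard) for a gene-model table in the layout produced by
#' [read_gene_models()] or [simulate_genome()].
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    base <- paste(g$chrom, "methylgraft", sep = "\t")
    lines <- c(lines,
      sprintf("%s\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s", base, g$tx_start, g$tx_end, g$strand, gid),
      sprintf("%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s", base, g$tx_start, g$tx_end, g$strand, gid, gid))
    ex <- g$exons[[1]]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                                base, ex$start[j], ex$end[j], g$strand, gid, j, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED coordinates are 0-based half-open, matching the package's internal
#' interval convention, so no conversion is applied. Files are written
#' sorted by `(chrom, start)` with a single commented header line, and
#' round-trip losslessly through `read_bed()`.
#'
#' @param regions Interval tibble with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path File path.
#' @return `read_bed()` returns an interval tibble; `write_bed()` returns
#'   `path` invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(regions))
  if (nrow(regions) > 0) check_intervals(regions, "regions")
  out <- regions[do.call(order, regions[c("chrom", "start")]), cols, drop = FALSE]
  lines <- paste0("#", paste(cols, collapse = "\t"))
  if (nrow(out) > 0) {
    lines <- c(lines, do.call(paste, c(as.list(out), sep = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(first) == 1 && startsWith(first, "#")) {
    cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  }
  x <- suppressWarnings(readr::read_tsv(
    path, col_names = cols, comment = "#", progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  ))
  x <- as_tibble(x)
  if (nrow(x) == 0) {
    x <- tibble(chrom = character(), start = integer(), end = integer())
    return(x)
  }
  x %>% mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$chrom, .data$start)
}

#' Write a bedGraph methylation track
#'
#' @param track Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `value`.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "methylation") {
  check_intervals(track, "track")
  out <- track[do.call(order, track[c("chrom", "start")]),
               c("chrom", "start", "end", "value")]
  writeLines(c(sprintf("track type=bedGraph name=\"%s\"", name),
               do.call(paste, c(as.list(out), sep = "\t"))),
             path)
  invisible(path)
}

#' @describeIn write_bedgraph Read a bedGraph track back into a tibble.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", comment = "track", progress = FALSE,
                  skip = 1)
}

#' Read a gene-to-term annotation map
#'
#' @param path Two-column tab-separated file: `gene_id`, `term_id`.
#'   Optional further columns are ignored. Lines starting `#` are comments.
#' @param descriptions Optional path to a term-description table with
#'   columns `term_id`, `term_name` (and optionally `namespace`).
#' @return A tibble with `gene_id`, `term_id` and, when descriptions are
#'   supplied, `term_name`/`namespace`.
#' @export
read_term_map <- function(path, descriptions = NULL) {
  x <- readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                       col_types = "cc", comment = "#", progress = FALSE)
  if (!is.null(descriptions)) {
    d <- readr::read_tsv(descriptions, col_names = TRUE,
                         col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
    if (!all(c("term_id") %in% names(d))) {
      abort("descriptions file must have a term_id column")
    }
    x <- left_join(x, d, by = "term_id")
  }
  x
}
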