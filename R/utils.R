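#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols n distinct across rename if_else
#'   row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats dhyper phyper p.adjust rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# contexts recognised everywhere downstream
CONTEXTS <- c("CG", "CHG", "CHH")

#' Convert a tidy interval table to a GRanges object
#'
#' Internal intervals are 0-based half-open; GRanges is 1-based inclusive.
#' @noRd
gr_from_intervals <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

#' @noRd
gr_from_calls <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos, width = 1L)
  )
}

#' @noRd
check_intervals <- function(intervals, what = "intervals") {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(intervals))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)",
                  what, paste(need, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
  if (length(bad) > 0) {
    abort(sprintf("%s rows %s violate 0 <= start < end",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(intervals)
}

#' @noRd
check_context_arg <- function(context) {
  if (!all(context %in% CONTEXTS)) {
    abort(sprintf("unknown context '%s'; must be one of %s",
                  paste(setdiff(context, CONTEXTS), collapse = ","),
                  paste(CONTEXTS, collapse = ", ")))
  }
  context
}

#' Resolve a genome argument to a named DNAStringSet
#' @noRd
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    abort("genome must be a DNAStringSet, a named character vector, or a FASTA path")
  }
  if (is.null(names(genome))) {
    abort("genome sequences must be named")
  }
  genome
}

#' @noRd
chrom_lengths_of <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Run an expression with a private, restored RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
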