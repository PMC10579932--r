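#' CpG positions within a reference amplicon
#'
#' @param reference Amplicon sequence (character or `DNAString`).
#' @return Integer vector of 1-based positions of the C of each CpG
#'   dinucleotide on the given strand.
#' @export
find_cpg_sites <- function(reference) {
  s <- as.character(reference)
  m <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) return(integer(0))
  as.integer(m)
}

#' Simulate bisulfite-converted clone sequences
#'
#' In-silico bisulfite chemistry on a reference amplicon: for each clone,
#' every CpG cytosine is methylated with its per-position probability
#' from `pattern`; methylated cytosines remain C, while unmethylated CpG
#' cytosines and all non-CpG cytosines convert C to T with probability
#' `conversion_rate` (incomplete conversion leaves residual Cs). Only the
#' top (primer-defined) strand is modelled.
#'
#' @param reference Amplicon sequence.
#' @param pattern Numeric vector of per-CpG methylation probabilities,
#'   one per CpG site of the reference.
#' @param conversion_rate Bisulfite conversion efficiency in \[0, 1\].
#' @param n_clones Number of clones to simulate (default 10, the usual
#'   number of sequenced positive clones per subject).
#' @param seed Optional integer seed; the simulation is deterministic
#'   under a fixed seed.
#' @return A list with `clones` (tibble `clone_id`, `sequence`) and
#'   `truth` (tibble `clone_id`, `cpg_pos`, `methylated`).
#' @export
bisulfite_convert <- function(reference, pattern, conversion_rate = 1,
                              n_clones = 10, seed = NULL) {
  if (conversion_rate < 0 || conversion_rate > 1) {
    abort("conversion_rate must lie in [0, 1]")
  }
  s <- strsplit(as.character(reference), "", fixed = TRUE)[[1]]
  cpg <- find_cpg_sites(reference)
  if (length(pattern) != length(cpg)) {
    abort(sprintf("pattern length (%d) must equal the number of CpG sites (%d)",
                  length(pattern), length(cpg)))
  }
  if (any(pattern < 0 | pattern > 1)) abort("pattern probabilities must lie in [0, 1]")
  c_pos <- which(s == "C")
  noncpg <- setdiff(c_pos, cpg)
  with_seed(seed, {
    res <- purrr::map(seq_len(n_clones), function(i) {
      clone <- s
      meth <- runif(length(cpg)) < pattern
      convert_cpg <- cpg[!meth][runif(sum(!meth)) < conversion_rate]
      convert_non <- noncpg[runif(length(noncpg)) < conversion_rate]
      clone[c(convert_cpg, convert_non)] <- "T"
      list(
        seq = paste(clone, collapse = ""),
        truth = tibble(clone_id = sprintf("clone_%02d", i),
                       cpg_pos = cpg, methylated = meth)
      )
    })
    list(
      clones = tibble(clone_id = sprintf("clone_%02d", seq_len(n_clones)),
                      sequence = purrr::map_chr(res, "seq")),
      truth = purrr::map_dfr(res, "truth")
    )
  })
}

#' @noRd
bisulfite_matrix <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  m["T", "C"] <- 1   # clone T aligned to reference C: bisulfite conversion
  m
}

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Align one clone to the reference and call per-CpG methylation
#'
#' Global (end-to-end) pairwise alignment with bisulfite-aware scoring: a
#' clone T aligned to a reference C scores as a match, since it is the
#' expected product of conversion. At each reference CpG cytosine the
#' aligned clone base gives the call — C is methylated, T unmethylated,
#' anything else (gap, N) missing. The conversion rate is estimated from
#' the non-CpG reference cytosine columns as the fraction read as T, and
#' the clone passes QC when it reaches `min_conversion`. If the direct
#' orientation aligns with bisulfite-aware identity below 0.5 the reverse
#' complement is tried; clones below `min_identity` in both orientations
#' are rejected.
#'
#' @param reference Amplicon sequence.
#' @param clone_seq Clone sequence (post-bisulfite).
#' @param min_conversion QC threshold on the conversion rate
#'   (default 0.95).
#' @param min_identity Minimum bisulfite-aware alignment identity
#'   (default 0.8).
#' @return A list: `calls` (tibble `cpg_pos`, `call` with values
#'   `methylated`/`unmethylated`/`missing`), `conversion_rate` (`NA` when
#'   the amplicon has no non-CpG C), `identity`, `orientation`,
#'   `qc_pass`, `rejected`, `reason`.
#' @export
bsp_call_clone <- function(reference, clone_seq, min_conversion = 0.95,
                           min_identity = 0.8) {
  reference <- as.character(reference)
  clone_seq <- as.character(clone_seq)
  mat <- bisulfite_matrix()
  align <- function(cl) {
    pa <- Biostrings::pairwiseAlignment(cl, reference, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    match <- p == s | (s == "C" & p == "T")
    list(p = p, s = s, identity = mean(match))
  }
  direct <- align(clone_seq)
  orientation <- "forward"
  best <- direct
  if (direct$identity < 0.5) {
    rc <- align(revcomp_chr(clone_seq))
    if (rc$identity > direct$identity) {
      best <- rc
      orientation <- "reverse"
    }
  }
  cpg <- find_cpg_sites(reference)
  if (best$identity < min_identity) {
    return(list(calls = tibble(cpg_pos = cpg, call = "missing"),
                conversion_rate = NA_real_, identity = best$identity,
                orientation = orientation, qc_pass = FALSE, rejected = TRUE,
                reason = sprintf("alignment identity %.2f below %.2f",
                                 best$identity, min_identity)))
  }
  # map alignment columns to reference coordinates
  ref_pos <- cumsum(best$s != "-")
  ref_pos[best$s == "-"] <- NA
  col_of <- match(seq_len(sum(best$s != "-")), ref_pos)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]

  clone_at <- function(pos) best$p[col_of[pos]]
  cpg_base <- vapply(cpg, clone_at, character(1))
  calls <- dplyr::case_when(
    cpg_base == "C" ~ "methylated",
    cpg_base == "T" ~ "unmethylated",
    TRUE ~ "missing"
  )
  noncpg <- setdiff(which(ref_chars == "C"), cpg)
  nb <- vapply(noncpg, clone_at, character(1))
  n_t <- sum(nb == "T", na.rm = TRUE)
  n_c <- sum(nb == "C", na.rm = TRUE)
  conv <- if (n_t + n_c > 0) n_t / (n_t + n_c) else NA_real_
  list(calls = tibble(cpg_pos = cpg, call = calls),
       conversion_rate = conv, identity = best$identity,
       orientation = orientation,
       qc_pass = is.na(conv) || conv >= min_conversion,
       rejected = FALSE, reason = NA_character_)
}

#' Analyse a set of BSP clones against a reference amplicon
#'
#' Runs [bsp_call_clone()] on every clone and collects per-clone QC and
#' per-CpG calls into a `bsp_result`.
#'
#' @param reference Amplicon sequence, `DNAString(Set)` or FASTA path
#'   (first record used).
#' @param clones A tibble with `clone_id`, `sequence`, a named character
#'   vector, a `DNAStringSet`, or a FASTA path.
#' @param min_conversion,min_identity As in [bsp_call_clone()].
#' @return A `bsp_result`: list with `clones` (per-clone
#'   `conversion_rate`, `identity`, `orientation`, `qc_pass`, `rejected`,
#'   `reason`), `calls` (long tibble `clone_id`, `cpg_pos`, `call`),
#'   `cpg_positions` and `reference`.
#' @export
bsp_analyze <- function(reference, clones, min_conversion = 0.95,
                        min_identity = 0.8) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- as.character(Biostrings::readDNAStringSet(reference)[[1]])
  }
  reference <- as.character(reference)
  if (is.character(clones) && length(clones) == 1 && file.exists(clones)) {
    clones <- Biostrings::readDNAStringSet(clones)
  }
  if (methods::is(clones, "DNAStringSet")) {
    clones <- tibble(clone_id = names(clones),
                     sequence = as.character(clones))
  }
  if (is.character(clones)) {
    clones <- tibble(clone_id = names(clones) %||% paste0("clone_", seq_along(clones)),
                     sequence = unname(clones))
  }
  res <- purrr::map(seq_len(nrow(clones)), function(i) {
    bsp_call_clone(reference, clones$sequence[i],
                   min_conversion = min_conversion,
                   min_identity = min_identity)
  })
  structure(list(
    clones = tibble(
      clone_id = clones$clone_id,
      conversion_rate = purrr::map_dbl(res, "conversion_rate"),
      identity = purrr::map_dbl(res, "identity"),
      orientation = purrr::map_chr(res, "orientation"),
      qc_pass = purrr::map_lgl(res, "qc_pass"),
      rejected = purrr::map_lgl(res, "rejected"),
      reason = purrr::map_chr(res, "reason")
    ),
    calls = purrr::map_dfr(seq_along(res), function(i) {
      res[[i]]$calls %>% mutate(clone_id = clones$clone_id[i], .before = 1)
    }),
    cpg_positions = find_cpg_sites(reference),
    reference = reference
  ), class = "bsp_result")
}

#' Build the clone-by-CpG methylation matrix
#'
#' Restricts a `bsp_result` to QC-passing, non-rejected clones and builds
#' the clone x CpG-position matrix behind a lollipop plot, together with
#' the per-position methylated fraction over called (non-missing) cells.
#'
#' @param result A `bsp_result` from [bsp_analyze()].
#' @return A `bsp_matrix`: list with `cells` (tibble `clone_id`,
#'   `cpg_pos`, `call`), `summary` (per-position `n_methylated`,
#'   `n_unmethylated`, `frac_methylated`; `NA` when a position is missing
#'   in every clone), `clone_ids` (sorted) and `cpg_positions`. Raises an
#'   error when no clone passes QC.
#' @export
bsp_matrix <- function(result) {
  keep <- result$clones$clone_id[result$clones$qc_pass & !result$clones$rejected]
  if (length(keep) == 0) abort("no QC-passing clones")
  keep <- sort(keep)
  cells <- result$calls %>%
    filter(.data$clone_id %in% keep) %>%
    arrange(.data$clone_id, .data$cpg_pos)
  summary <- cells %>%
    group_by(.data$cpg_pos) %>%
    summarise(
      n_methylated = sum(.data$call == "methylated"),
      n_unmethylated = sum(.data$call == "unmethylated"),
      .groups = "drop"
    ) %>%
    mutate(frac_methylated = if_else(
      .data$n_methylated + .data$n_unmethylated > 0,
      .data$n_methylated / (.data$n_methylated + .data$n_unmethylated),
      NA_real_))
  structure(list(cells = cells, summary = summary, clone_ids = keep,
                 cpg_positions = result$cpg_positions),
            class = "bsp_matrix")
}

#' @rdname bsp_matrix
#' @param x A `bsp_matrix`.
#' @param ... Unused.
#' @return `format()` returns a character vector: one text lollipop row
#'   per clone (filled circle = methylated, open circle = unmethylated,
#'   dot = missing) plus a summary line of per-position methylated
#'   fractions.
#' @export
format.bsp_matrix <- function(x, ...) {
  glyph <- c(methylated = "●", unmethylated = "○", missing = "·")
  rows <- x$cells %>%
    mutate(g = glyph[.data$call]) %>%
    group_by(.data$clone_id) %>%
    summarise(row = paste(.data$g, collapse = " "), .groups = "drop")
  width <- max(nchar(rows$clone_id))
  out <- sprintf("%-*s  %s", width, rows$clone_id, rows$row)
  frac <- ifelse(is.na(x$summary$frac_methylated), " .",
                 sprintf("%2.0f", 10 * round(x$summary$frac_methylated, 1)))
  c(out, sprintf("%-*s  %s", width, "meth/10",
                 paste(frac, collapse = "")))
}

#' @export
print.bsp_matrix <- function(x, ...) {
  cat(sprintf("<bsp_matrix> %d clones x %d CpG positions\n",
              length(x$clone_ids), length(x$cpg_positions)))
  writeLines(format(x))
  invisible(x)
}

#' @rdname tidy.dmr_result
#' @export
tidy.bsp_matrix <- function(x, ...) x$cells

#' @rdname tidy.dmr_result
#' @export
glance.bsp_matrix <- function(x, ...) {
  tibble(
    n_clones = length(x$clone_ids),
    n_cpgs = length(x$cpg_positions),
    mean_methylation = mean(x$summary$frac_methylated, na.rm = TRUE)
  )
}

#' Lollipop plot of a BSP methylation matrix
#'
#' @param object A `bsp_matrix`.
#' @param ... Unused.
#' @return A ggplot object: clones as rows, CpG positions as columns,
#'   filled points methylated, open points unmethylated.
#' @export
autoplot.bsp_matrix <- function(object, ...) {
  cells <- object$cells %>% filter(.data$call != "missing")
  ggplot(cells, aes(x = .data$cpg_pos,
                    y = factor(.data$clone_id, levels = rev(object$clone_ids)),
                    shape = .data$call)) +
    geom_point(size = 3, fill = "black") +
    scale_shape_manual(values = c(methylated = 19, unmethylated = 1)) +
    labs(x = "CpG position in amplicon", y = NULL, shape = NULL) +
    theme_minimal()
}

#' Write the BSP matrix and per-position summary as TSV
#'
#' Matrix cells use `M` (methylated), `U` (unmethylated), `.` (missing).
#'
#' @param x A `bsp_matrix`.
#' @param matrix_path,summary_path Output paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_bsp_matrix <- function(x, matrix_path, summary_path = NULL) {
  wide <- x$cells %>%
    mutate(code = c(methylated = "M", unmethylated = "U",
                    missing = ".")[.data$call]) %>%
    select("clone_id", "cpg_pos", "code") %>%
    tidyr::pivot_wider(names_from = "cpg_pos", values_from = "code")
  readr::write_tsv(wide, matrix_path, progress = FALSE)
  if (!is.null(summary_path)) {
    readr::write_tsv(x$summary, summary_path, progress = FALSE)
  }
  invisible(c(matrix_path, summary_path))
}
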