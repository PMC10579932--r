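#' Hypergeometric term enrichment of DMR-associated genes
#'
#' Over-representation analysis of a DMG set against gene-to-term
#' annotations (GO terms, KEGG pathways, or any gene-set collection).
#' For a universe of `N` genes of which `K` carry a term, and a DMG set
#' of size `n` containing `k` term genes, the enrichment P value is the
#' hypergeometric upper tail \eqn{P(X \ge k)}. Terms with no universe
#' gene are skipped; results are sorted by P with ties broken by
#' `term_id`, and a Benjamini-Hochberg adjusted column is emitted
#' alongside the raw P.
#'
#' @param dmg_genes Character vector of DMG gene ids (must all be in the
#'   universe).
#' @param term_map Tibble with columns `gene_id`, `term_id` (and
#'   optionally `term_name`, `namespace`), e.g. from [read_term_map()].
#' @param universe Background gene set; defaults to all genes appearing
#'   in `term_map`.
#' @param alpha Significance threshold on the raw P (default 0.05).
#' @return A tibble with `term_id` (and `term_name`/`namespace` when
#'   available), `k`, `n`, `K`, `N`, `p`, `p_adj`, `significant`, sorted
#'   by `(p, term_id)`.
#' @export
enrich_dmgs <- function(dmg_genes, term_map, universe = NULL, alpha = 0.05) {
  if (nrow(term_map) == 0) abort("term_map is empty")
  dmg_genes <- unique(dmg_genes)
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  universe <- unique(universe)
  missing <- setdiff(dmg_genes, universe)
  if (length(missing) > 0) {
    abort(sprintf("DMG gene(s) absent from the universe: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  tm <- term_map %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$gene_id, .data$term_id)
  N <- length(universe)
  n_dmg <- length(dmg_genes)
  per_term <- tm %>%
    group_by(.data$term_id) %>%
    summarise(K = n(), k = sum(.data$gene_id %in% dmg_genes),
              .groups = "drop") %>%
    filter(.data$K > 0)
  res <- per_term %>%
    mutate(
      n = n_dmg, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n_dmg, lower.tail = FALSE),
      p_adj = p.adjust(.data$p, method = "BH"),
      significant = .data$p < alpha
    ) %>%
    arrange(.data$p, .data$term_id) %>%
    select("term_id", "k", "n", "K", "N", "p", "p_adj", "significant")
  desc_cols <- intersect(c("term_name", "namespace"), names(term_map))
  if (length(desc_cols) > 0) {
    res <- left_join(res,
                     distinct(term_map[, c("term_id", desc_cols)]),
                     by = "term_id") %>%
      select("term_id", dplyr::all_of(desc_cols), dplyr::everything())
  }
  res
}
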