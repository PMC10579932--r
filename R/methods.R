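#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_rect geom_step geom_point
#'   geom_col geom_tile facet_wrap facet_grid labs theme_minimal
#'   scale_shape_manual scale_y_continuous
#' @export
ggplot2::autoplot

#' Tidy a DMR result
#'
#' `tidy()` returns the final merged DMR table; `glance()` returns a
#' one-row summary of the scan.
#'
#' @param x A `dmr_result` from [call_dmrs()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dmr_result <- function(x, ...) x$dmrs

#' @rdname tidy.dmr_result
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_eligible = sum(x$windows$eligible),
    n_passing = sum(x$windows$pass),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    n_merged = sum(x$dmrs$merged_from > 1)
  )
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("<dmr_result> %s vs %s | contexts: %s\n",
              x$groups[1], x$groups[2],
              paste(x$params$contexts, collapse = ",")))
  g <- glance(x)
  cat(sprintf("  windows: %d (%d eligible, %d passing) -> %d DMRs (%d hyper, %d hypo, %d merged)\n",
              g$n_windows, g$n_eligible, g$n_passing, g$n_dmrs,
              g$n_hyper, g$n_hypo, g$n_merged))
  invisible(x)
}

#' Plot a DMR scan along the genome
#'
#' Window-level methylation for both groups as step tracks with called
#' DMRs shaded, faceted by chromosome.
#'
#' @param object A `dmr_result`.
#' @param context Context to display (default the first scanned).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_result <- function(object, context = object$params$contexts[1], ...) {
  w <- object$windows %>%
    filter(.data$context == !!context) %>%
    tidyr::pivot_longer(c("level_1", "level_2"),
                        names_to = "group", values_to = "level") %>%
    mutate(group = if_else(.data$group == "level_1",
                           object$groups[1], object$groups[2]))
  d <- object$dmrs %>% filter(.data$context == !!context)
  p <- ggplot(w, aes(x = .data$start / 1e3, y = .data$level,
                     colour = .data$group))
  if (nrow(d) > 0) {
    p <- p + geom_rect(data = d,
                       aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "grey85")
  }
  p + geom_step(na.rm = TRUE) +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (kb)", y = sprintf("%s methylation level", context),
         colour = NULL,
         title = sprintf("Windowed %s methylation, DMRs shaded", context)) +
    theme_minimal()
}

#' Plot a feature-by-group methylation profile
#'
#' @param profile Output of [feature_profile()] (optionally through
#'   [normalize_profile()]; the `fraction` column is used when present).
#' @return A ggplot object.
#' @export
plot_feature_profile <- function(profile) {
  ycol <- if ("fraction" %in% names(profile)) "fraction" else "level"
  ggplot(profile,
         aes(x = factor(.data$feature, levels = unique(.data$feature)),
             y = .data[[ycol]], fill = .data$group)) +
    geom_col(position = "dodge", na.rm = TRUE) +
    labs(x = NULL, y = if (ycol == "fraction") "normalized fraction"
         else "weighted methylation level", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a tiled chromosome methylation map
#'
#' @param tiles Output of [tile_methylation()].
#' @return A ggplot object.
#' @export
plot_chromosome_map <- function(tiles) {
  ggplot(tiles, aes(x = (.data$start + .data$end) / 2e3, y = .data$chrom,
                    fill = .data$value)) +
    geom_tile(height = 0.8, na.rm = TRUE) +
    labs(x = "position (kb)", y = NULL, fill = "level (scaled)") +
    theme_minimal()
}
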