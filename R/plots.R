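# ggplot2 displays for the main result types.

#' Plot ELISA calls: per-subject mean OD against the cutoff
#'
#' Bars are the sensitized subjects' mean ODs; the dashed line is the
#' control mean + 2 SD cutoff, the dotted line the high-binder threshold.
#'
#' @param object A `cpfam_elisa` from [elisa_calls()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpfam_elisa <- function(object, ...) {
  df <- tidy(object)
  df$call <- ifelse(df$high_binder, "high binder",
                    ifelse(df$positive, "positive", "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$mean_od,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "cutoff"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`high binder` = "#c0392b",
                                          positive = "#2980b9",
                                          negative = "grey60")) +
    ggplot2::labs(x = NULL, y = "mean OD450", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-site selection results
#'
#' -log10 p per codon column, colored by selection class.
#'
#' @param object A `cpfam_selection` from [site_selection_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpfam_selection <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon_column,
                                   y = -log10(.data$p_value),
                                   color = .data$class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(positive = "#c0392b",
                                           negative = "#2980b9",
                                           neutral = "grey60")) +
    ggplot2::labs(x = "codon site", y = expression(-log[10] ~ p),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an expression comparison
#'
#' Mean TPM per gene (log scale), with the focal gene highlighted and
#' significantly lower genes marked.
#'
#' @param object A `cpfam_expr` from [compare_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpfam_expr <- function(object, ...) {
  df <- tidy(object)
  focal <- tibble(gene_id = attr(object, "focal_gene"),
                  mean_tpm = attr(object, "focal_mean"),
                  significant = NA)
  df <- dplyr::bind_rows(df, focal)
  df$focal <- df$gene_id == attr(object, "focal_gene")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                      -.data$mean_tpm),
                                   y = .data$mean_tpm + 0.5,
                                   fill = .data$focal)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "mean TPM (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a family tree with clade clusters
#'
#' Thin wrapper over `ape::plot.phylo` coloring tips by cluster label.
#'
#' @param tree A `phylo`.
#' @param clusters Tibble from [extract_clusters()].
#' @param ... Passed to `ape::plot.phylo`.
#' @return Invisibly, the cluster color map.
#' @export
plot_family_tree <- function(tree, clusters = NULL, ...) {
  cols <- "black"
  map <- NULL
  if (!is.null(clusters)) {
    labs <- clusters$cluster[match(tree$tip.label, clusters$id)]
    pal <- grDevices::hcl.colors(max(1L, length(unique(stats::na.omit(labs)))),
                                 "Dark 3")
    map <- setNames(pal, sort(unique(stats::na.omit(labs))))
    cols <- ifelse(is.na(labs), "grey50", map[labs])
  }
  ape::plot.phylo(tree, tip.color = cols, cex = 0.7, ...)
  invisible(map)
}
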