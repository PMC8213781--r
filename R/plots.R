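# ggplot2 views of the main result types.

#' Volcano plot of pfam enrichment
#'
#' Log2 odds ratio against -log10 q, shaped by the core/shell/cloud
#' class. Infinite odds ratios (domains absent from the background) are
#' drawn at the edge of the finite range.
#'
#' @param enrichment Result of [pfam_enrichment()].
#' @param label_top Label the `label_top` most significant pfams (0 for
#'   none).
#' @return A ggplot object.
#' @export
plot_pfam_volcano <- function(enrichment, label_top = 5) {
  df <- enrichment
  finite <- df$log2_odds_ratio[is.finite(df$log2_odds_ratio)]
  edge <- if (length(finite)) max(abs(finite)) + 1 else 1
  df$log2_plot <- pmin(pmax(df$log2_odds_ratio, -edge), edge)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_plot,
                                         y = .data$neg_log10_q,
                                         shape = .data$pan_class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log2 odds ratio", y = "-log10 q",
                  shape = "pan class",
                  title = "Pfam enrichment in eCIS loci") +
    ggplot2::theme_minimal()
  if (label_top > 0 && nrow(df)) {
    top <- utils::head(df[order(df$q), , drop = FALSE], label_top)
    gg <- gg + ggplot2::geom_text(data = top,
                                  ggplot2::aes(label = .data$pfam),
                                  vjust = -0.6, size = 3)
  }
  gg
}

#' Gene map of detected loci
#'
#' Draws each locus as a row of gene arrows along scaffold coordinates,
#' core genes filled by role presence.
#'
#' @param object An `ecis_loci` table from [detect_loci()].
#' @param genes The gene tibble the loci were detected in.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecis_loci <- function(object, genes, ...) {
  if (nrow(object) == 0) abort("No loci to plot.")
  rows <- list()
  for (i in seq_len(nrow(object))) {
    ids <- object$member_gene_ids[[i]]
    gg <- genes[match(ids, genes$gene_id), , drop = FALSE]
    gg$locus_id <- object$locus_id[i]
    gg$core <- gg$gene_id %in% names(object$core_roles[[i]])
    rows[[i]] <- gg[, c("locus_id", "gene_id", "start", "end", "strand", "core")]
  }
  df <- bind_rows(rows)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$locus_id, yend = .data$locus_id,
                   colour = .data$core),
      linewidth = 4, lineend = "butt") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                                 labels = c(`TRUE` = "core", `FALSE` = "accessory"),
                                 name = NULL) +
    ggplot2::labs(x = "scaffold position (bp)", y = NULL,
                  title = "Detected eCIS loci") +
    ggplot2::theme_minimal()
}

#' Bar chart of fiber call counts
#'
#' @param object An `ecis_fibers` table from [classify_fibers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecis_fibers <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "call", y = "genes",
                  title = "Tail-fiber target classification") +
    ggplot2::theme_minimal()
}
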