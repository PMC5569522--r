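# ggplot2 views of the main result types.

#' Histogram of DMR lengths
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param bin_edges Bin edges in kb (left-closed), as in
#'   [dmr_length_histogram()].
#' @return A ggplot object.
#' @export
plot_dmr_lengths <- function(dmrs, bin_edges = seq(0, 5, by = 0.5)) {
  h <- dmr_length_histogram(dmrs, bin_edges)
  h$label <- ifelse(is.finite(h$bin_end),
                    sprintf("%g-%g", h$bin_start, h$bin_end),
                    sprintf(">=%g", h$bin_start))
  h$label <- factor(h$label, levels = h$label)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$label, y = .data$n_dmrs)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "DMR length (kb)", y = "Number of DMRs") +
    ggplot2::theme_minimal()
}

#' Bar chart of CpG-density classes
#'
#' Class 0 is the sub-1-CpG/100 bp "CpG desert" class.
#'
#' @param dmrs Annotated DMR tibble from [annotate_cpg_density()].
#' @return A ggplot object.
#' @export
plot_cpg_density <- function(dmrs) {
  if (!("density_class" %in% names(dmrs))) {
    abort("`dmrs` lacks `density_class`; run annotate_cpg_density() first.")
  }
  tab <- dmrs |> count(.data$density_class, name = "n_dmrs")
  tab$label <- ifelse(tab$density_class == 0, "<1", as.character(tab$density_class))
  tab$label <- factor(tab$label, levels = tab$label[order(tab$density_class)])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$n_dmrs)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "CpG density class (CpG / 100 bp)", y = "Number of DMRs") +
    ggplot2::theme_minimal()
}

#' P-value track along a chromosome
#'
#' Plots -log10(p) per window with the core and extension thresholds marked.
#'
#' @param track Track from [test_windows()].
#' @param chrom Optional single chromosome to show (default: all, faceted).
#' @param config A [dmr_config()] supplying the threshold lines.
#' @return A ggplot object.
#' @export
plot_pvalue_track <- function(track, chrom = NULL, config = dmr_config()) {
  if (!is.null(chrom)) track <- track[track$chrom %in% chrom, , drop = FALSE]
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$start / 1e6,
                                           y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(config$p_core),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(config$p_extend),
                        linetype = "dotted", colour = "blue") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (length(unique(track$chrom)) > 1) {
    p <- p + ggplot2::facet_wrap(~chrom, scales = "free_x")
  }
  p
}
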