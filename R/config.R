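#' Pipeline configuration
#'
#' Collects every threshold the DMR pipeline uses, with defaults matching the
#' standard windowed MeDIP-seq workflow: 100 bp windows, a core significance
#' threshold of 1e-3, edge extension over windows with p < 0.1 lying within
#' 1000 bp of the growing region, a 2 Mb / 50 kb sliding cluster scan, and a
#' 10 kb gene-association flank.
#'
#' @param window_size Window width in bp.
#' @param p_core P-value below which a window is a DMR core window.
#' @param p_extend P-value threshold for windows that extend DMR edges.
#' @param extend_gap Maximum edge-to-edge gap in bp at which a sub-threshold
#'   window still extends a DMR.
#' @param gap_inclusive If `TRUE` (default) a window exactly `extend_gap` bp
#'   away still extends the region ("within 1000 bp" read inclusively).
#' @param merge_touching If `TRUE` (default) DMRs whose extended spans touch
#'   end-to-start are merged into one region.
#' @param cluster_window,cluster_step Sliding-window width and step (bp) for
#'   the DMR cluster scan.
#' @param cluster_alpha Family-wise significance level for the cluster scan.
#' @param cluster_min_dmrs Minimum member DMRs for a reported cluster.
#' @param cluster_p_adjust Multiplicity correction across scan positions:
#'   `"bonferroni"` (default) or `"none"`.
#' @param gene_flank Flank in bp added to each DMR before gene association.
#' @param fragment_extension Fragment length in bp to which reads are extended
#'   from their 5' end before midpoint counting (sonication peak).
#'
#' @return A named list of class `dmr_config`.
#' @examples
#' dmr_config()
#' dmr_config(p_core = 1e-4)
#' @export
dmr_config <- function(window_size = 100,
                       p_core = 1e-3,
                       p_extend = 0.1,
                       extend_gap = 1000,
                       gap_inclusive = TRUE,
                       merge_touching = TRUE,
                       cluster_window = 2e6,
                       cluster_step = 5e4,
                       cluster_alpha = 0.05,
                       cluster_min_dmrs = 3,
                       cluster_p_adjust = c("bonferroni", "none"),
                       gene_flank = 1e4,
                       fragment_extension = 300) {
  cluster_p_adjust <- match.arg(cluster_p_adjust)
  if (!is.numeric(window_size) || window_size <= 0) {
    abort("`window_size` must be a positive number of bp.")
  }
  if (!(p_core > 0 && p_core <= p_extend && p_extend < 1)) {
    abort("thresholds must satisfy 0 < p_core <= p_extend < 1.")
  }
  for (nm in c("extend_gap", "cluster_window", "cluster_step", "gene_flank")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) abort(paste0("`", nm, "` must be positive."))
  }
  if (!(cluster_alpha > 0 && cluster_alpha < 1)) {
    abort("`cluster_alpha` must be in (0, 1).")
  }
  if (fragment_extension < 0) abort("`fragment_extension` must be >= 0.")
  structure(
    list(
      window_size = window_size, p_core = p_core, p_extend = p_extend,
      extend_gap = extend_gap, gap_inclusive = gap_inclusive,
      merge_touching = merge_touching,
      cluster_window = cluster_window, cluster_step = cluster_step,
      cluster_alpha = cluster_alpha, cluster_min_dmrs = cluster_min_dmrs,
      cluster_p_adjust = cluster_p_adjust,
      gene_flank = gene_flank, fragment_extension = fragment_extension
    ),
    class = "dmr_config"
  )
}

#' @export
print.dmr_config <- function(x, ...) {
  cat("<dmr_config>\n")
  cat(sprintf("  windows: %g bp | core p < %g | extend p < %g within %g bp (%s)\n",
              x$window_size, x$p_core, x$p_extend, x$extend_gap,
              if (x$gap_inclusive) "inclusive" else "exclusive"))
  cat(sprintf("  clusters: %g Mb window, %g kb step, alpha %g (%s), >= %d members\n",
              x$cluster_window / 1e6, x$cluster_step / 1e3, x$cluster_alpha,
              x$cluster_p_adjust, x$cluster_min_dmrs))
  cat(sprintf("  gene flank: %g bp | fragment extension: %g bp\n",
              x$gene_flank, x$fragment_extension))
  invisible(x)
}
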