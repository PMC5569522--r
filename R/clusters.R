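# Megabase-scale DMR cluster scan.
#
# DMRs are reduced to midpoints and counted in a sliding window (2 Mb wide,
# 50 kb steps by default). Under a uniform genome-wide DMR rate the count in
# a window is approximately Poisson with mean
# lambda = (total DMRs / total genome length) * window width, and a window is
# over-represented when the exact Poisson upper tail falls below the
# family-wise level: the per-window tail is Bonferroni-corrected for the
# number of scanned positions, so a genome with uniformly placed DMRs yields
# a spurious cluster in at most an alpha fraction of datasets. Overlapping
# significant windows are merged, and merged regions with fewer than
# `cluster_min_dmrs` member DMRs are dropped.

#' Exact Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)` — the over-representation statistic
#' of the cluster scan.
#'
#' @param k Observed count (>= 0, vectorised).
#' @param lambda Poisson mean (> 0).
#' @return Upper-tail probability in (0, 1].
#' @examples
#' cluster_pvalue(0, 2)  # 1
#' cluster_pvalue(5, 0.2)
#' @export
cluster_pvalue <- function(k, lambda) {
  if (any(lambda <= 0)) abort("`lambda` must be > 0.")
  if (any(k < 0)) abort("`k` must be >= 0.")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Scan for over-represented DMR clusters
#'
#' Slides a `cluster_window` bp window along each chromosome in
#' `cluster_step` bp increments, counts DMR midpoints per position, and
#' flags positions whose Poisson upper-tail probability (against the
#' genome-wide DMR rate) clears the family-wise `cluster_alpha` after the
#' configured multiplicity correction. Overlapping significant positions are
#' merged; each merged region is reported as the span from the first to the
#' last member DMR.
#'
#' @param dmrs DMR tibble from [call_dmrs()] (needs `chrom`, `start`, `end`;
#'   `dmr_id` used for member lists when present).
#' @param chrom_lengths Chromosome lengths (see [make_windows()]).
#' @param config A [dmr_config()]; the `cluster_*` fields drive the scan.
#' @return Tibble with one row per cluster: `chrom`, `start`, `end`,
#'   `n_dmrs`, `p_value` (smallest corrected member-window tail), `dmr_ids`.
#' @export
scan_clusters <- function(dmrs, chrom_lengths, config = dmr_config()) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_dmrs = integer(), p_value = numeric(), dmr_ids = character())
  if (nrow(dmrs) == 0) return(empty)
  cl <- as_chrom_lengths(chrom_lengths)
  bad <- setdiff(unique(dmrs$chrom), cl$chrom)
  if (length(bad) > 0) abort(paste0("DMRs on unknown chromosome(s): ", paste(bad, collapse = ", ")))
  if (!("dmr_id" %in% names(dmrs))) dmrs$dmr_id <- as.character(seq_len(nrow(dmrs)))
  lambda <- nrow(dmrs) / sum(cl$length) * config$cluster_window
  m_tests <- sum(vapply(cl$length, function(L) {
    length(seq(0, max(0, L - 1), by = config$cluster_step))
  }, numeric(1)))
  adj <- if (config$cluster_p_adjust == "bonferroni") m_tests else 1

  out <- map(cl$chrom, function(ch) {
    d <- dmrs[dmrs$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d <- d[order(d$start), , drop = FALSE]
    mids <- (d$start + d$end) / 2
    L <- cl$length[cl$chrom == ch]
    st <- seq(0, max(0, L - 1), by = config$cluster_step)
    en <- pmin(st + config$cluster_window, L)
    k <- findInterval(en - 0.5, mids) - findInterval(st - 0.5, mids)
    p_adj <- pmin(cluster_pvalue(k, lambda) * adj, 1)
    sig <- which(p_adj < config$cluster_alpha & k > 0)
    if (length(sig) == 0) return(NULL)
    # merge overlapping/adjacent significant scan windows
    regions <- list()
    ms <- st[sig[1]]; me <- en[sig[1]]; mp <- p_adj[sig[1]]
    for (i in sig[-1]) {
      if (st[i] <= me) {
        me <- max(me, en[i])
        mp <- min(mp, p_adj[i])
      } else {
        regions[[length(regions) + 1]] <- list(s = ms, e = me, p = mp)
        ms <- st[i]; me <- en[i]; mp <- p_adj[i]
      }
    }
    regions[[length(regions) + 1]] <- list(s = ms, e = me, p = mp)
    map(regions, function(r) {
      member <- mids >= r$s & mids < r$e
      if (sum(member) < config$cluster_min_dmrs) return(NULL)
      tibble(
        chrom = ch,
        start = min(d$start[member]),
        end = max(d$end[member]),
        n_dmrs = as.integer(sum(member)),
        p_value = r$p,
        dmr_ids = paste(d$dmr_id[member], collapse = ",")
      )
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0) empty else arrange(out, .data$chrom, .data$start)
}
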