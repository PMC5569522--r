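# DMR calling: core runs -> edge extension -> merging -> classification.

dmr_cols <- function() {
  tibble(
    dmr_id = character(), chrom = character(), start = numeric(), end = numeric(),
    length_bp = numeric(), n_core = integer(), max_core_run = integer(),
    min_p = numeric(), dmr_class = character()
  )
}

#' Find maximal runs of core-significant windows
#'
#' A window with `p_value < p_core` is a core window; maximal runs of
#' strictly adjacent core windows (consecutive on the grid, same chromosome)
#' seed the DMRs.
#'
#' @param track P-value track from [test_windows()] (columns `chrom`,
#'   `start`, `end`, `p_value`).
#' @param p_core Core significance threshold.
#' @return Tibble with one row per run: `chrom`, `start`, `end`, `n_windows`.
#' @export
find_core_runs <- function(track, p_core = 1e-3) {
  track <- arrange(track, .data$chrom, .data$start)
  core <- track[track$p_value < p_core, , drop = FALSE]
  if (nrow(core) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer()))
  }
  brk <- c(TRUE, core$chrom[-1] != core$chrom[-nrow(core)] |
             core$start[-1] != core$end[-nrow(core)])
  core$run <- cumsum(brk)
  core |>
    group_by(.data$run) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), n_windows = n(), .groups = "drop") |>
    select(-"run")
}

# fixed-point edge extension + merging for one chromosome.
# spans: tibble(start, end); cand: candidate windows (p < p_extend).
extend_spans <- function(spans, cand, gap_max, inclusive, merge_touching) {
  s <- spans$start
  e <- spans$end
  repeat {
    changed <- FALSE
    if (nrow(cand) > 0) {
      for (i in seq_along(s)) {
        gap <- pmax(s[i] - cand$end, cand$start - e[i])
        q <- if (inclusive) gap <= gap_max else gap < gap_max
        if (any(q)) {
          ns <- min(s[i], min(cand$start[q]))
          ne <- max(e[i], max(cand$end[q]))
          if (ns != s[i] || ne != e[i]) {
            s[i] <- ns
            e[i] <- ne
            changed <- TRUE
          }
        }
      }
    }
    o <- order(s)
    s <- s[o]
    e <- e[o]
    ms <- s[1]
    me <- e[1]
    out_s <- numeric(0)
    out_e <- numeric(0)
    for (i in seq_along(s)[-1]) {
      joins <- if (merge_touching) s[i] <= me else s[i] < me
      if (joins) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms)
        out_e <- c(out_e, me)
        ms <- s[i]
        me <- e[i]
      }
    }
    out_s <- c(out_s, ms)
    out_e <- c(out_e, me)
    if (length(out_s) < length(s)) changed <- TRUE
    s <- out_s
    e <- out_e
    if (!changed) break
  }
  tibble(start = s, end = e)
}

#' Call DMRs from a p-value track
#'
#' Windows below `p_core` seed core runs; each run's edges are then extended
#' iteratively while any window with `p_value < p_extend` lies within
#' `extend_gap` bp (edge-to-edge, boundary-inclusive by default) of the
#' current span, absorbing chains of sub-threshold windows until a fixed
#' point: afterwards no `p < p_extend` window remains within `extend_gap` of
#' any DMR. Spans that come to touch or overlap are merged, pooling their
#' core windows. A DMR whose longest run of *adjacent* core windows is >= 2
#' is classified `multiple_window`, otherwise `single_window`. Extension
#' never crosses chromosome boundaries.
#'
#' @param track P-value track from [test_windows()].
#' @param config A [dmr_config()].
#' @return Tibble with one row per DMR: `dmr_id`, `chrom`, `start`, `end`,
#'   `length_bp`, `n_core`, `max_core_run`, `min_p`, `dmr_class`.
#' @examples
#' track <- tibble::tibble(
#'   chrom = "chr1", start = seq(0, 400, 100), end = seq(100, 500, 100),
#'   p_value = c(0.5, 1e-4, 1e-4, 0.05, 0.5)
#' )
#' call_dmrs(track) # one DMR [100, 400)
#' @export
call_dmrs <- function(track, config = dmr_config()) {
  track <- arrange(track, .data$chrom, .data$start)
  runs <- find_core_runs(track, config$p_core)
  if (nrow(runs) == 0) return(dmr_cols())
  out <- map(unique(runs$chrom), function(ch) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    spans <- runs[runs$chrom == ch, c("start", "end")]
    cand <- tr[tr$p_value < config$p_extend, c("start", "end")]
    fin <- extend_spans(spans, cand, config$extend_gap,
                        config$gap_inclusive, config$merge_touching)
    pmap(list(fin$start, fin$end), function(s, e) {
      sel <- tr$start >= s & tr$end <= e
      pw <- tr$p_value[sel]
      core <- pw < config$p_core
      r <- rle(core)
      tibble(
        chrom = ch, start = s, end = e, length_bp = e - s,
        n_core = sum(core),
        max_core_run = as.integer(max(r$lengths[r$values])),
        min_p = min(pw)
      )
    }) |> list_rbind()
  }) |> list_rbind()
  out |>
    mutate(
      dmr_id = sprintf("%s:%d-%d", .data$chrom, as.integer(.data$start),
                       as.integer(.data$end)),
      dmr_class = ifelse(.data$max_core_run >= 2, "multiple_window", "single_window")
    ) |>
    select("dmr_id", "chrom", "start", "end", "length_bp", "n_core",
           "max_core_run", "min_p", "dmr_class") |>
    arrange(.data$chrom, .data$start)
}

#' Tabulate DMRs by adjacent-core-run length
#'
#' Counts DMRs by their longest adjacent core-window run (1, 2, 3, 4, 5+),
#' the per-span breakdown used when reporting single- vs multiple-window
#' DMRs.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @return Tibble with `n_windows` (1-5, 5 meaning >= 5) and `n_dmrs`.
#' @export
summarize_dmrs <- function(dmrs) {
  runs <- pmin(dmrs$max_core_run, 5L)
  tibble(n_windows = 1:5, n_dmrs = tabulate(runs, nbins = 5L))
}

#' Sum of multiple-window DMRs
#'
#' The headline count of DMRs detected in two or more adjacent windows.
#' Accepts either a DMR tibble from [call_dmrs()] or a per-run-length summary
#' (columns `n_windows`, `n_dmrs`) such as [summarize_dmrs()] produces or a
#' published table supplies.
#'
#' @param x DMR tibble or run-length summary tibble.
#' @return Integer count.
#' @examples
#' multiple_window_sum(tibble::tibble(n_windows = 1:5, n_dmrs = c(1160, 97, 9, 3, 1)))
#' @export
multiple_window_sum <- function(x) {
  if (all(c("n_windows", "n_dmrs") %in% names(x))) {
    return(as.integer(sum(x$n_dmrs[x$n_windows >= 2])))
  }
  if ("max_core_run" %in% names(x)) {
    return(as.integer(sum(x$max_core_run >= 2)))
  }
  abort("`x` must be a DMR table or a summary with n_windows/n_dmrs.")
}

#' Histogram of DMR lengths
#'
#' Bins DMR extents (kb) into left-closed bins, with a final open-ended bin
#' for lengths beyond the last edge. Returns an empty tibble for an empty
#' DMR set.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param bin_edges Bin edges in kb (left-closed).
#' @return Tibble with `bin_start`, `bin_end` (kb) and `n_dmrs`.
#' @export
dmr_length_histogram <- function(dmrs, bin_edges = seq(0, 5, by = 0.5)) {
  lo <- head(c(bin_edges, Inf), -1)
  hi <- tail(c(bin_edges, Inf), -1)
  if (nrow(dmrs) == 0) {
    return(tibble(bin_start = numeric(), bin_end = numeric(), n_dmrs = integer()))
  }
  kb <- dmrs$length_bp / 1000
  bin <- findInterval(kb, c(bin_edges, Inf))
  bin[kb < bin_edges[1]] <- NA # below the first edge: not binned
  tibble(bin_start = lo, bin_end = hi,
         n_dmrs = tabulate(bin, nbins = length(lo)))
}

#' Write DMRs as a BED-like TSV
#'
#' Columns: chrom, start, end, name, min_p, class, n_core, max_core_run.
#' @param dmrs DMR tibble.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  write_tsv(
    dmrs[c("chrom", "start", "end", "dmr_id", "min_p", "dmr_class",
           "n_core", "max_core_run")],
    path
  )
  invisible(path)
}
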