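# Window grid construction and read-to-window counting.
# Coordinates throughout are 0-based half-open [start, end), BED-style.

# Normalise the many ways a genome can be described (named vector, tibble,
# medip_genome) to a tibble with columns chrom / length.
as_chrom_lengths <- function(x) {
  if (inherits(x, "medip_genome")) x <- x$chromosomes
  if (is.data.frame(x)) {
    if (!all(c("chrom", "length") %in% names(x))) {
      abort("a chromosome table needs columns `chrom` and `length`.")
    }
    out <- tibble(chrom = as.character(x$chrom), length = as.numeric(x$length))
  } else if (is.numeric(x) && !is.null(names(x)) && !any(names(x) == "")) {
    out <- tibble(chrom = names(x), length = as.numeric(x))
  } else {
    abort("supply chromosome lengths as a named numeric vector, a data frame with `chrom`/`length`, or a genome object.")
  }
  if (nrow(out) == 0) abort("at least one chromosome is required.")
  if (anyDuplicated(out$chrom) > 0) abort("chromosome names must be unique.")
  if (any(!is.finite(out$length) | out$length <= 0)) {
    abort("chromosome lengths must be positive and finite.")
  }
  out
}

check_samples <- function(samples) {
  if (!is.data.frame(samples) || !all(c("pool_id", "group") %in% names(samples))) {
    abort("`samples` must be a data frame with columns `pool_id` and `group`.")
  }
  if (anyDuplicated(samples$pool_id) > 0) abort("`pool_id` values must be unique.")
  invisible(samples)
}

# Matrix of counts (windows x pools) in the column order of `samples`.
counts_matrix <- function(counts, samples) {
  check_samples(samples)
  miss <- setdiff(as.character(samples$pool_id), names(counts))
  if (length(miss) > 0) {
    abort(paste0("counts table lacks columns for pools: ", paste(miss, collapse = ", ")))
  }
  m <- as.matrix(counts[as.character(samples$pool_id)])
  if (any(m < 0)) abort("counts must be non-negative.")
  m
}

coord_cols <- function(counts) intersect(c("chrom", "start", "end", "window"), names(counts))

#' Tile chromosomes into fixed-width windows
#'
#' Builds the ordered window grid the whole pipeline operates on. Windows are
#' 0-based half-open, tile each chromosome without gaps or overlaps, and all
#' have width `window_size` except possibly a shorter trailing window per
#' chromosome (trailing partial windows are kept so that every base, and hence
#' every counted read, belongs to exactly one window).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, a
#'   data frame with columns `chrom`/`length`, or a genome object from
#'   [simulate_genome()].
#' @param window_size Window width in bp (default 100).
#'
#' @return A tibble with columns `chrom`, `start`, `end` and the 0-based
#'   per-chromosome window index `window`.
#' @examples
#' make_windows(c(chr1 = 1050), window_size = 100)
#' @export
make_windows <- function(chrom_lengths, window_size = 100) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0) {
    abort("`window_size` must be a single positive number.")
  }
  map2(cl$chrom, cl$length, function(ch, len) {
    start <- seq(0, len - 1, by = window_size)
    tibble(
      chrom = ch,
      start = start,
      end = pmin(start + window_size, len),
      window = seq_along(start) - 1L
    )
  }) |> list_rbind()
}

#' Assign reads to windows by extended-fragment midpoint
#'
#' Each read is extended to `extension_bp` from its 5' end in read orientation
#' (the expected sonication fragment length; `extension_bp = 0` keeps the read
#' as is), clipped to the chromosome, and assigned to the single window
#' containing the fragment midpoint. A midpoint exactly on a window boundary
#' belongs to the right-hand window. Midpoint assignment keeps counts integer,
#' which the downstream exact test requires.
#'
#' @param reads Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand` (`"+"`/`"-"`, default `"+"`).
#' @param chrom_lengths Chromosome lengths (see [make_windows()]).
#' @param window_size Window width in bp.
#' @param extension_bp Fragment extension in bp; 0 disables extension.
#'
#' @return `reads` with added columns `fragment_start`, `fragment_end`,
#'   `midpoint` and the 0-based window index `window`.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 150, end = 200, strand = "-")
#' assign_reads(reads, c(chr1 = 1000), extension_bp = 300)
#' @export
assign_reads <- function(reads, chrom_lengths, window_size = 100, extension_bp = 300) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (!all(c("chrom", "start", "end") %in% names(reads))) {
    abort("`reads` needs columns `chrom`, `start`, `end`.")
  }
  idx <- match(reads$chrom, cl$chrom)
  if (anyNA(idx)) {
    abort(paste0("unknown chromosome(s): ",
                 paste(unique(reads$chrom[is.na(idx)]), collapse = ", ")))
  }
  len <- cl$length[idx]
  if (any(reads$start < 0 | reads$end > len | reads$start >= reads$end)) {
    abort("read coordinates must lie within their chromosome (0-based half-open).")
  }
  strand <- if ("strand" %in% names(reads)) as.character(reads$strand) else rep("+", nrow(reads))
  if (extension_bp > 0) {
    fs <- ifelse(strand == "-", reads$end - extension_bp, reads$start)
    fe <- ifelse(strand == "-", reads$end, reads$start + extension_bp)
  } else {
    fs <- reads$start
    fe <- reads$end
  }
  fs <- pmax(fs, 0)
  fe <- pmin(fe, len)
  mid <- (fs + fe) %/% 2
  reads |>
    mutate(
      fragment_start = fs,
      fragment_end = fe,
      midpoint = mid,
      window = as.integer(mid %/% window_size)
    )
}

#' Count reads per window and pool
#'
#' Converts labelled aligned reads into the window-by-pool count matrix on
#' which differential coverage is tested. Reads are assigned by extended
#' fragment midpoint (see [assign_reads()]); column sums therefore equal the
#' number of assigned reads per pool.
#'
#' @param reads Tibble of reads with a `pool_id` column plus the columns
#'   required by [assign_reads()].
#' @param windows Window grid from [make_windows()].
#' @param samples Tibble with one row per pool: `pool_id` and `group`. Pools
#'   listed here but absent from `reads` are retained as all-zero columns
#'   with a warning.
#' @param extension_bp Fragment extension in bp.
#'
#' @return A list with `counts` (the `windows` tibble plus one integer column
#'   per pool, in `samples` order) and `samples` with an added/updated
#'   `library_size` column (the column sums).
#' @export
count_reads <- function(reads, windows, samples, extension_bp = 300) {
  check_samples(samples)
  if (!("pool_id" %in% names(reads))) abort("`reads` needs a `pool_id` column.")
  bad <- setdiff(unique(as.character(reads$pool_id)), as.character(samples$pool_id))
  if (length(bad) > 0) {
    abort(paste0("reads contain pools not listed in `samples`: ", paste(bad, collapse = ", ")))
  }
  empty <- setdiff(as.character(samples$pool_id), unique(as.character(reads$pool_id)))
  if (length(empty) > 0) {
    warn(paste0("pool(s) with zero reads retained with library_size 0: ",
                paste(empty, collapse = ", ")))
  }
  w <- max(windows$end - windows$start)
  cl <- windows |> group_by(.data$chrom) |> summarise(length = max(.data$end), .groups = "drop")
  n_win <- nrow(windows)
  pools <- as.character(samples$pool_id)
  mat <- matrix(0L, nrow = n_win, ncol = length(pools), dimnames = list(NULL, pools))
  if (nrow(reads) > 0) {
    asn <- assign_reads(reads, cl, window_size = w, extension_bp = extension_bp)
    i <- match(paste(asn$chrom, asn$window), paste(windows$chrom, windows$window))
    j <- match(as.character(asn$pool_id), pools)
    tab <- table(factor(i, levels = seq_len(n_win)), factor(j, levels = seq_along(pools)))
    mat <- matrix(as.integer(tab), nrow = n_win, dimnames = list(NULL, pools))
  }
  counts <- bind_cols(windows, as_tibble(mat))
  samples$library_size <- as.integer(colSums(mat))
  list(counts = counts, samples = as_tibble(samples))
}

#' Read aligned reads from a SAM file
#'
#' Imports mapped primary alignments (unmapped and secondary records are
#' dropped) and returns them as 0-based half-open intervals ready for
#' [count_reads()]. The reference span is taken as the read width on the
#' query; for the short single-end reads this pipeline consumes the
#' difference from the CIGAR-projected span is immaterial to midpoint
#' assignment.
#'
#' @param path Path to a SAM file with an `@SQ` header.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_reads_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE),
    what = c("rname", "strand", "pos", "qwidth")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble(
    chrom = as.character(x$rname),
    start = x$pos - 1,
    end = x$pos - 1 + x$qwidth,
    strand = as.character(x$strand)
  )
}

#' Read intervals from a BED file
#'
#' @param path Path to a BED3+/BED6 file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand` (0-based half-open, as in the file).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  sc <- gr$score
  if (!is.null(sc)) out$score <- sc
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", "+", st)
  out
}
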