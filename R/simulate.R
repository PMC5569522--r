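# Synthetic data: toy genomes, gene annotations, and pooled MeDIP-like
# window counts with planted DMRs and clusters plus a truth table, so every
# downstream stage can be exercised and benchmarked without external data.

#' Simulate a toy genome with controllable CpG density
#'
#' Generates random chromosome sequences in which CpG dinucleotides are
#' planted at a controlled per-bp rate, so that CpG-dense and CpG-poor
#' regions ("CpG deserts", < 1 CpG / 100 bp) can both be populated. The
#' background sequence is scrubbed of accidental CG dinucleotides before
#' planting, so the realised CpG count of a region is exactly the planted
#' number: a `cpg_rate` of 0.5 yields uninterrupted CG repeats.
#'
#' @param chrom_lengths Named numeric vector or `chrom`/`length` data frame.
#' @param gc_profile Optional tibble with columns `chrom`, `start`, `end`,
#'   `cpg_rate` giving per-segment CpG rates (CpG starts per bp, at most 0.5);
#'   regions not covered use `base_cpg_rate`.
#' @param base_cpg_rate Default CpG rate outside profiled segments.
#' @param seed Optional integer seed; fixed seeds give bit-identical genomes.
#' @param with_sequence If `FALSE`, only chromosome lengths are stored (enough
#'   for count-level simulations, much cheaper for large genomes).
#'
#' @return An object of class `medip_genome`: a list with `chromosomes`
#'   (tibble `chrom`/`length`) and `sequence` (named character vector or
#'   `NULL`).
#' @examples
#' g <- simulate_genome(c(chr1 = 1000), seed = 1)
#' substr(g$sequence[["chr1"]], 1, 30)
#' @export
simulate_genome <- function(chrom_lengths, gc_profile = NULL, base_cpg_rate = 0.01,
                            seed = NULL, with_sequence = TRUE) {
  cl <- as_chrom_lengths(chrom_lengths)
  if (base_cpg_rate < 0 || base_cpg_rate > 0.5) {
    abort("`base_cpg_rate` must be in [0, 0.5] (a CpG occupies 2 bp).")
  }
  if (!is.null(gc_profile)) {
    if (!all(c("chrom", "start", "end", "cpg_rate") %in% names(gc_profile))) {
      abort("`gc_profile` needs columns chrom, start, end, cpg_rate.")
    }
    if (any(gc_profile$cpg_rate < 0 | gc_profile$cpg_rate > 0.5)) {
      abort("`cpg_rate` must be in [0, 0.5].")
    }
  }
  seqs <- NULL
  if (with_sequence) {
    seqs <- with_opt_seed(seed, function() {
      setNames(purrr::map2_chr(cl$chrom, cl$length, function(ch, len) {
        segs <- if (is.null(gc_profile)) {
          tibble(start = 0, end = len, cpg_rate = base_cpg_rate)
        } else {
          prof <- gc_profile[gc_profile$chrom == ch, , drop = FALSE]
          fill_profile(prof, len, base_cpg_rate)
        }
        simulate_chrom_seq(len, segs)
      }), cl$chrom)
    })
  }
  structure(list(chromosomes = cl, sequence = seqs), class = "medip_genome")
}

# complete a per-chromosome profile so segments tile [0, len)
fill_profile <- function(prof, len, base_rate) {
  prof <- prof[order(prof$start), , drop = FALSE]
  out <- list()
  pos <- 0
  for (i in seq_len(nrow(prof))) {
    s <- max(0, prof$start[i]); e <- min(len, prof$end[i])
    if (s > pos) out[[length(out) + 1]] <- tibble(start = pos, end = s, cpg_rate = base_rate)
    if (e > s) out[[length(out) + 1]] <- tibble(start = s, end = e, cpg_rate = prof$cpg_rate[i])
    pos <- max(pos, e)
  }
  if (pos < len) out[[length(out) + 1]] <- tibble(start = pos, end = len, cpg_rate = base_rate)
  list_rbind(out)
}

simulate_chrom_seq <- function(len, segs) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # remove accidental CG so planted CpGs are the only ones
  if (len > 1) {
    cg <- which(base[-len] == "C" & base[-1] == "G")
    if (length(cg) > 0) base[cg + 1] <- "A"
  }
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]; rate <- segs$cpg_rate[i]
    if (rate <= 0 || e - s < 2) next
    slots <- seq(s + 1, e - 1, by = 2) # 1-based start positions of CG pairs
    k <- min(length(slots), round(rate * (e - s)))
    if (k <= 0) next
    pick <- sort(slots[sample.int(length(slots), k)])
    base[pick] <- "C"
    base[pick + 1] <- "G"
  }
  paste(base, collapse = "")
}

#' @export
print.medip_genome <- function(x, ...) {
  cat(sprintf("<medip_genome> %d chromosome(s), %s bp total, sequence %s\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ","),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Write / read a genome as FASTA
#'
#' @param genome A `medip_genome` with sequence.
#' @param path Output / input FASTA path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a `medip_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) abort("genome has no sequence to write.")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequence), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  structure(
    list(
      chromosomes = tibble(chrom = names(seqs), length = as.numeric(nchar(seqs))),
      sequence = seqs
    ),
    class = "medip_genome"
  )
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` non-overlapping gene intervals uniformly on the genome by
#' rejection sampling, for exercising flank-based gene association.
#'
#' @param genome `medip_genome` or chromosome lengths.
#' @param n_genes Number of genes (>= 0).
#' @param gene_length Length range in bp genes are drawn from.
#' @param seed Optional integer seed.
#' @param max_tries Consecutive rejected placements before giving up (the
#'   requested genes then do not fit).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `name`.
#' @export
simulate_genes <- function(genome, n_genes, gene_length = c(500, 5000),
                           seed = NULL, max_tries = 1000) {
  cl <- as_chrom_lengths(genome)
  if (n_genes < 0) abort("`n_genes` must be >= 0.")
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), name = character())
  if (n_genes == 0) return(empty)
  with_opt_seed(seed, function() {
    placed <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample.int(nrow(cl), 1, prob = cl$length)
        len <- floor(runif(1, gene_length[1], gene_length[2] + 1))
        L <- cl$length[ci]
        if (L < len) next
        s <- floor(runif(1, 0, L - len + 1))
        e <- s + len
        prev <- placed[seq_len(i - 1)]
        clash <- any(vapply(prev, function(g) {
          g$chrom == cl$chrom[ci] && s < g$end && g$start < e
        }, logical(1)))
        if (!clash) {
          placed[[i]] <- list(chrom = cl$chrom[ci], start = s, end = e)
          ok <- TRUE
          break
        }
      }
      if (!ok) abort(sprintf("could not place gene %d of %d: genes do not fit.", i, n_genes))
    }
    tibble(
      chrom = vapply(placed, `[[`, character(1), "chrom"),
      start = vapply(placed, `[[`, numeric(1), "start"),
      end = vapply(placed, `[[`, numeric(1), "end"),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      name = paste0("gene", seq_len(n_genes))
    ) |> arrange(.data$chrom, .data$start)
  })
}

#' Write genes as BED6 / read a gene annotation
#'
#' `read_genes()` accepts BED or GFF3 (format inferred from the extension)
#' and returns 0-based half-open gene bodies.
#'
#' @param genes Tibble as returned by [simulate_genes()].
#' @param path File path.
#' @return `write_genes_bed()` returns `path` invisibly; `read_genes()` a
#'   tibble with `chrom`, `start`, `end`, `strand`, `name`.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$name, score = 0L,
    strand = if ("strand" %in% names(genes)) genes$strand else "+"
  )
  write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  nm <- gr$name %||% gr$ID %||% gr$Name %||% paste0("gene", seq_along(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", "+",
                    as.character(GenomicRanges::strand(gr))),
    name = as.character(nm)
  )
}

#' Simulation parameters for pooled MeDIP-like counts
#'
#' Describes the pooled two-group study design the simulator emulates:
#' two localities, each sequenced as `pools_per_group` pools of
#' `birds_per_pool` individuals. Window counts are negative-binomial around a
#' CpG-density-dependent baseline with pool-specific size factors, and
#' planted DMRs shift the mean of one group.
#'
#' @param pools_per_group Pools per group (default 3, the pooled design).
#' @param birds_per_pool Individuals contributing to each pool (metadata).
#' @param mean_depth Baseline mean reads per window per pool.
#' @param dispersion NB dispersion phi, parameterised as
#'   `var = mu + phi * mu^2`; 0 gives Poisson counts.
#' @param cpg_effect Multiplicative effect on the baseline mean per unit of
#'   CpG density (CpG per 100 bp): `mu_w = mean_depth * (1 + cpg_effect * density_w)`.
#' @param size_factor_range Pool size factors are drawn log-uniform on this
#'   range so the normalisation stage has real work to do.
#' @param planted Tibble of planted DMRs from [plant_dmrs()] /
#'   [plant_cluster()] (columns `chrom`, `core_start`, `n_core_windows`,
#'   `log2_fold_change`, `direction`), or `NULL`.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(pools_per_group = 3, birds_per_pool = 5,
                       mean_depth = 100, dispersion = 0.3, cpg_effect = 0,
                       size_factor_range = c(0.7, 1.4), planted = NULL) {
  if (pools_per_group < 1) abort("`pools_per_group` must be >= 1.")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      size_factor_range[1] > size_factor_range[2]) {
    abort("`size_factor_range` must be an increasing positive pair.")
  }
  if (!is.null(planted)) {
    need <- c("chrom", "core_start", "n_core_windows", "log2_fold_change", "direction")
    if (!all(need %in% names(planted))) {
      abort("`planted` needs columns chrom, core_start, n_core_windows, log2_fold_change, direction.")
    }
    if (any(planted$n_core_windows < 1)) abort("planted DMRs need n_core_windows >= 1.")
  }
  structure(
    list(
      pools_per_group = pools_per_group, birds_per_pool = birds_per_pool,
      mean_depth = mean_depth, dispersion = dispersion, cpg_effect = cpg_effect,
      size_factor_range = size_factor_range, planted = planted
    ),
    class = "sim_params"
  )
}

#' Describe planted DMRs
#'
#' Builds the truth rows consumed by [sim_params()]. Vectorised; `direction`
#' defaults to the sign of `log2_fold_change` ("up" means the second group
#' gains coverage).
#'
#' @param chrom,core_start Chromosome and 0-based start of the first core
#'   window; `core_start` must sit on the window grid.
#' @param n_core_windows Number of consecutive core windows (1-5 typical).
#' @param log2_fold_change Effect magnitude on the log2 scale.
#' @param direction `"up"` or `"down"` (effect applied to the second group).
#' @param window_size Grid width used for validation.
#' @return Tibble with one row per planted DMR.
#' @export
plant_dmrs <- function(chrom, core_start, n_core_windows = 2,
                       log2_fold_change = 3,
                       direction = ifelse(log2_fold_change >= 0, "up", "down"),
                       window_size = 100) {
  out <- tibble(
    chrom = as.character(chrom), core_start = core_start,
    n_core_windows = as.integer(n_core_windows),
    log2_fold_change = abs(log2_fold_change),
    direction = direction
  )
  if (any(out$core_start %% window_size != 0)) {
    abort("`core_start` must be a multiple of `window_size` (cores align to the grid).")
  }
  if (any(!out$direction %in% c("up", "down"))) abort("`direction` must be 'up' or 'down'.")
  if (any(out$n_core_windows < 1)) abort("`n_core_windows` must be >= 1.")
  out
}

#' Plant a cluster of DMRs
#'
#' Spreads `n_dmrs` planted DMRs evenly across `span_bp`, emulating the
#' megabase-scale DMR clusters (3-10 DMRs over 2-7 Mb) the cluster scan is
#' meant to find.
#'
#' @inheritParams plant_dmrs
#' @param start 0-based start of the cluster.
#' @param n_dmrs Number of member DMRs (3-10).
#' @param span_bp Total span of the cluster in bp.
#' @return Tibble of planted DMRs (rows as in [plant_dmrs()]).
#' @export
plant_cluster <- function(chrom, start, n_dmrs = 5, span_bp = 2e6,
                          n_core_windows = 2, log2_fold_change = 3,
                          window_size = 100) {
  if (n_dmrs < 3 || n_dmrs > 10) abort("clusters contain 3-10 DMRs.")
  pos <- start + seq(0, span_bp - n_core_windows * window_size, length.out = n_dmrs)
  pos <- round(pos / window_size) * window_size
  plant_dmrs(chrom, pos, n_core_windows, log2_fold_change, window_size = window_size)
}

#' Simulate pooled MeDIP-like window counts with planted DMRs
#'
#' Draws each window/pool count from a negative binomial with mean
#' `mu_w * s_j` and dispersion `phi` (`var = mu + phi mu^2`), where `mu_w`
#' is the CpG-density-modulated baseline and `s_j` a pool size factor. For
#' pools of the second group, windows inside a planted core have their mean
#' multiplied by `2^log2_fold_change` ("up") or divided by it ("down").
#' Fixed seeds give bit-identical output.
#'
#' @param genome `medip_genome` (sequence optional) or chromosome lengths.
#' @param params A [sim_params()] object.
#' @param windows Optional precomputed grid; defaults to
#'   `make_windows(genome, window_size)`.
#' @param window_size Grid width when `windows` is not supplied.
#' @param seed Optional integer seed.
#'
#' @return A list of class `medip_sim` with elements `counts` (grid plus one
#'   integer column per pool), `samples` (pool metadata incl. true size
#'   factors and library sizes) and `truth` (one row per planted DMR with its
#'   core span in bp).
#' @export
simulate_counts <- function(genome, params = sim_params(), windows = NULL,
                            window_size = 100, seed = NULL) {
  cl <- as_chrom_lengths(genome)
  if (is.null(windows)) windows <- make_windows(cl, window_size)
  w <- max(windows$end - windows$start)
  n_win <- nrow(windows)
  has_seq <- inherits(genome, "medip_genome") && !is.null(genome$sequence)
  density <- if (has_seq && params$cpg_effect != 0) {
    seqs <- genome_subseq(genome, windows$chrom, windows$start, windows$end)
    cpg_count(seqs) * 100 / (windows$end - windows$start)
  } else {
    rep(0, n_win)
  }
  mu_base <- pmax(params$mean_depth * (1 + params$cpg_effect * density), 1e-6)

  # per-window fold-change multiplier for the second group
  fc <- rep(1, n_win)
  truth <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_core_windows = integer(), log2_fold_change = numeric(),
                  direction = character())
  if (!is.null(params$planted) && nrow(params$planted) > 0) {
    pl <- params$planted
    key <- paste(windows$chrom, windows$start)
    for (i in seq_len(nrow(pl))) {
      starts <- pl$core_start[i] + w * (seq_len(pl$n_core_windows[i]) - 1)
      idx <- match(paste(pl$chrom[i], starts), key)
      if (anyNA(idx)) {
        abort(sprintf("planted core on %s at %g falls outside the window grid.",
                      pl$chrom[i], pl$core_start[i]))
      }
      mult <- 2^(ifelse(pl$direction[i] == "up", 1, -1) * abs(pl$log2_fold_change[i]))
      fc[idx] <- fc[idx] * mult
    }
    truth <- tibble(
      chrom = pl$chrom,
      start = as.numeric(pl$core_start),
      end = as.numeric(pl$core_start + w * pl$n_core_windows),
      n_core_windows = as.integer(pl$n_core_windows),
      log2_fold_change = abs(pl$log2_fold_change),
      direction = pl$direction
    )
  }

  npool <- params$pools_per_group
  samples <- tibble(
    pool_id = c(paste0("A", seq_len(npool)), paste0("B", seq_len(npool))),
    group = rep(c("A", "B"), each = npool),
    birds_per_pool = params$birds_per_pool
  )
  sim <- with_opt_seed(seed, function() {
    sf <- exp(runif(nrow(samples), log(params$size_factor_range[1]),
                    log(params$size_factor_range[2])))
    mat <- matrix(0L, n_win, nrow(samples), dimnames = list(NULL, samples$pool_id))
    for (j in seq_len(nrow(samples))) {
      mu <- mu_base * sf[j]
      if (samples$group[j] == "B") mu <- mu * fc
      mat[, j] <- if (params$dispersion == 0) {
        rpois(n_win, mu)
      } else {
        rnbinom(n_win, mu = mu, size = 1 / params$dispersion)
      }
    }
    list(sf = sf, mat = mat)
  })
  samples$size_factor <- sim$sf
  samples$library_size <- as.numeric(colSums(sim$mat))
  structure(
    list(
      counts = bind_cols(windows, as_tibble(sim$mat)),
      samples = samples,
      truth = truth,
      params = params
    ),
    class = "medip_sim"
  )
}

#' @export
print.medip_sim <- function(x, ...) {
  cat(sprintf("<medip_sim> %d windows x %d pools (%d planted DMR(s))\n",
              nrow(x$counts), nrow(x$samples), nrow(x$truth)))
  invisible(x)
}

#' Emit BED-style reads that reproduce simulated window counts
#'
#' For each simulated count, one read of `read_length` bp is emitted whose
#' midpoint falls inside the intended window, exercising the read-counting
#' path: counting these reads with `extension_bp = 0` recovers the simulated
#' count matrix exactly.
#'
#' @param counts Count tibble (grid columns plus pool columns).
#' @param samples Pool metadata (`pool_id`, `group`).
#' @param read_length Read length in bp (even, smaller than the window size).
#' @param seed Optional integer seed.
#' @return Tibble of reads: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `pool_id`.
#' @export
simulate_reads <- function(counts, samples, read_length = 50, seed = NULL) {
  check_samples(samples)
  if (read_length %% 2 != 0) abort("`read_length` must be even.")
  m <- counts_matrix(counts, samples)
  cl <- counts |> group_by(.data$chrom) |> summarise(length = max(.data$end), .groups = "drop")
  half <- read_length / 2
  with_opt_seed(seed, function() {
    out <- map(seq_len(ncol(m)), function(j) {
      n_per <- m[, j]
      idx <- rep.int(seq_along(n_per), n_per)
      if (length(idx) == 0) return(NULL)
      lo <- pmax(counts$start[idx], half)
      hi <- pmin(counts$end[idx], cl$length[match(counts$chrom[idx], cl$chrom)] - half)
      if (any(hi <= lo)) {
        abort("windows too close to a chromosome end to hold a full read; use a longer chromosome or shorter reads.")
      }
      mid <- lo + floor(runif(length(idx)) * (hi - lo))
      tibble(
        chrom = counts$chrom[idx],
        start = mid - half,
        end = mid + half,
        strand = sample(c("+", "-"), length(idx), replace = TRUE),
        pool_id = colnames(m)[j]
      )
    })
    reads <- list_rbind(out[!vapply(out, is.null, logical(1))])
    reads |>
      mutate(name = paste0("read", dplyr::row_number()), score = 0L) |>
      select("chrom", "start", "end", "name", "score", "strand", "pool_id")
  })
}

#' Write reads as BED6 (one file for all pools; pool id in the name field)
#' @param reads Tibble from [simulate_reads()].
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  bed <- tibble(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = paste(reads$pool_id, reads$name, sep = ":"),
    score = 0L, strand = reads$strand
  )
  write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Serialise / restore the planted-DMR truth table
#'
#' Plain TSV with fixed column types so the table round-trips unchanged.
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_tsv(path, col_types = cols(
    chrom = col_character(), start = col_double(), end = col_double(),
    n_core_windows = col_integer(), log2_fold_change = col_double(),
    direction = col_character()
  ))
}
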