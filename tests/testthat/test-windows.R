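test_that("window tiling follows the fixed-width remainder rule", {
  w <- make_windows(c(chr1 = 1000), 100)
  expect_equal(nrow(w), 10)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[1], 100)
  expect_equal(w$start[10], 900)
  expect_equal(w$end[10], 1000)

  w2 <- make_windows(c(chr1 = 1050), 100)
  expect_equal(nrow(w2), 11)
  expect_equal(c(w2$start[11], w2$end[11]), c(1000, 1050))

  w3 <- make_windows(c(chr1 = 50), 100)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0, 50))
})

test_that("the grid partitions every chromosome exactly", {
  set.seed(11)
  for (rep in 1:5) {
    lens <- sample(50:2000, 3)
    names(lens) <- paste0("chr", 1:3)
    ws <- sample(c(37, 100, 250), 1)
    grid <- make_windows(lens, ws)
    for (ch in names(lens)) {
      g <- grid[grid$chrom == ch, ]
      # contiguous, ordered, non-overlapping cover of [0, L)
      expect_equal(g$start, c(0, head(g$end, -1)))
      expect_equal(max(g$end), unname(lens[ch]))
      expect_true(all(g$end > g$start))
      expect_true(all(g$end - g$start <= ws))
    }
  }
})

test_that("invalid grid inputs are rejected", {
  expect_error(make_windows(c(chr1 = 0), 100), "positive")
  expect_error(make_windows(setNames(numeric(0), character(0)), 100))
  expect_error(make_windows(c(chr1 = 1000), 0), "positive")
  expect_error(make_windows(c(chr1 = 100, chr1 = 200), 100), "unique")
})

test_that("reads are assigned by extended-fragment midpoint with clipping", {
  cl <- c(chr1 = 1000)
  r1 <- assign_reads(tibble::tibble(chrom = "chr1", start = 150, end = 200, strand = "+"),
                     cl, extension_bp = 0)
  expect_equal(r1$midpoint, 175)
  expect_equal(r1$window, 1L) # [100, 200)

  # extension to 300 bp from the 5' end; midpoint on a boundary goes right
  r2 <- assign_reads(tibble::tibble(chrom = "chr1", start = 150, end = 200, strand = "+"),
                     cl, extension_bp = 300)
  expect_equal(c(r2$fragment_start, r2$fragment_end), c(150, 450))
  expect_equal(r2$midpoint, 300)
  expect_equal(r2$window, 3L) # [300, 400)

  # minus-strand fragment clipped at the chromosome start
  r3 <- assign_reads(tibble::tibble(chrom = "chr1", start = 150, end = 200, strand = "-"),
                     cl, extension_bp = 300)
  expect_equal(c(r3$fragment_start, r3$fragment_end), c(0, 200))
  expect_equal(r3$window, 1L) # midpoint 100 -> [100, 200)

  expect_error(
    assign_reads(tibble::tibble(chrom = "chrX", start = 0, end = 50), cl),
    "unknown chromosome"
  )
})

test_that("read counting conserves reads and keeps pools independent", {
  grid <- make_windows(c(chr1 = 1000), 100)
  samples <- tibble::tibble(pool_id = c("P1", "P2"), group = c("A", "B"))
  reads <- tibble::tibble(
    chrom = "chr1", start = c(10, 20, 30), end = c(60, 70, 80),
    strand = "+", pool_id = "P1"
  )
  expect_warning(cm <- count_reads(reads, grid, samples, extension_bp = 0),
                 "zero reads")
  expect_equal(cm$counts$P1[1], 3L)
  expect_equal(sum(cm$counts$P1), 3L)
  expect_equal(sum(cm$counts$P2), 0L)
  expect_equal(cm$samples$library_size, c(3L, 0L))

  # identical read sets give identical columns
  reads2 <- dplyr::bind_rows(reads, dplyr::mutate(reads, pool_id = "P2"))
  cm2 <- count_reads(reads2, grid, samples, extension_bp = 0)
  expect_identical(cm2$counts$P1, cm2$counts$P2)

  # empty read set: all-zero matrix
  expect_warning(
    cm0 <- count_reads(reads[0, ], grid, samples, extension_bp = 0),
    "zero reads"
  )
  expect_true(all(cm0$counts$P1 == 0) && all(cm0$counts$P2 == 0))
})

test_that("simulated reads counted with no extension reproduce the count matrix", {
  g <- simulate_genome(c(chr1 = 20000), seed = 5, with_sequence = FALSE)
  sim <- simulate_counts(g, sim_params(mean_depth = 5, dispersion = 0.2), seed = 9)
  reads <- simulate_reads(sim$counts, sim$samples, seed = 10)
  cm <- count_reads(reads, sim$counts[c("chrom", "start", "end", "window")],
                    sim$samples, extension_bp = 0)
  for (p in sim$samples$pool_id) {
    expect_identical(as.integer(cm$counts[[p]]), as.integer(sim$counts[[p]]))
  }
  # conservation: column sums equal reads per pool
  expect_equal(unname(cm$samples$library_size),
               unname(as.integer(table(reads$pool_id)[cm$samples$pool_id])))
})

test_that("SAM input yields the same intervals as the equivalent BED", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t151\t42\t50M\t*\t0\t0\t*\t*",   # fwd, 0-based [150, 200)
    "r2\t16\tchr1\t301\t42\t50M\t*\t0\t0\t*\t*",  # rev
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",           # unmapped: dropped
    "r4\t256\tchr1\t401\t42\t50M\t*\t0\t0\t*\t*"  # secondary: dropped
  ), sam)
  reads <- read_reads_sam(sam)
  expect_equal(nrow(reads), 2)
  expect_equal(reads$start, c(150, 300))
  expect_equal(reads$end, c(200, 350))
  expect_equal(reads$strand, c("+", "-"))

  bed <- tempfile(fileext = ".bed")
  readr::write_tsv(
    tibble::tibble(chrom = "chr1", start = c(150, 300), end = c(200, 350),
                   name = c("r1", "r2"), score = 0L, strand = c("+", "-")),
    bed, col_names = FALSE
  )
  from_bed <- read_reads_bed(bed)
  expect_equal(from_bed$start, reads$start)
  expect_equal(from_bed$end, reads$end)
  expect_equal(from_bed$strand, reads$strand)
})
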