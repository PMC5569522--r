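test_that("genome simulation is reproducible and honours the CpG profile", {
  g1 <- simulate_genome(c(chr1 = 1000), seed = 1)
  g2 <- simulate_genome(c(chr1 = 1000), seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence[["chr1"]]), 1000)

  # a rate of 0.5 forces uninterrupted CG repeats: exactly 50 CpGs in [0, 100)
  prof <- tibble::tibble(chrom = "chr1", start = 0, end = 100, cpg_rate = 0.5)
  g3 <- simulate_genome(c(chr1 = 1000), gc_profile = prof, base_cpg_rate = 0,
                        seed = 2)
  first100 <- substr(g3$sequence[["chr1"]], 1, 100)
  expect_equal(cpg_count(first100), 50L)
  # zero base rate: no CpG outside the profiled segment
  expect_equal(cpg_count(g3$sequence[["chr1"]]), 50L)

  expect_error(simulate_genome(setNames(numeric(0), character(0))))
  expect_error(simulate_genome(c(chr1 = -5)), "positive")
})

test_that("genome FASTA round-trips through Biostrings", {
  g <- simulate_genome(c(chrA = 300, chrB = 150), seed = 4)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$chromosomes$length, c(300, 150))
})

test_that("simulated counts match the negative-binomial moment structure", {
  grid <- make_windows(c(chr1 = 1e6), 100) # 1e4 windows

  # Poisson limit: dispersion 0, equal size factors -> variance ~ mean
  sim0 <- simulate_counts(c(chr1 = 1e6), sim_params(
    mean_depth = 50, dispersion = 0, size_factor_range = c(1, 1)
  ), windows = grid, seed = 21)
  m <- as.matrix(sim0$counts[sim0$samples$pool_id])
  pooled_mean <- mean(m)
  pooled_var <- mean(apply(m, 2, stats::var)) # within-column variance
  expect_equal(pooled_var / pooled_mean, 1, tolerance = 0.05)

  # overdispersed: var ~ mu + phi mu^2 at phi = 0.5
  sim1 <- simulate_counts(c(chr1 = 1e6), sim_params(
    mean_depth = 50, dispersion = 0.5, size_factor_range = c(1, 1)
  ), windows = grid, seed = 22)
  m1 <- as.matrix(sim1$counts[sim1$samples$pool_id])
  v <- stats::var(as.vector(m1))
  mu <- mean(m1)
  expect_equal(v / (mu + 0.5 * mu^2), 1, tolerance = 0.1)
})

test_that("count simulation is seed-reproducible and planting shifts one group only", {
  g <- c(chr1 = 50000)
  pl <- plant_dmrs("chr1", 10000, n_core_windows = 3, log2_fold_change = 2)
  s1 <- simulate_counts(g, sim_params(planted = pl), seed = 33)
  s2 <- simulate_counts(g, sim_params(planted = pl), seed = 33)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  # planted windows: group B elevated ~4x relative to group A
  idx <- which(s1$counts$start >= 10000 & s1$counts$end <= 10300)
  a <- rowMeans(s1$counts[idx, s1$samples$pool_id[s1$samples$group == "A"]])
  b <- rowMeans(s1$counts[idx, s1$samples$pool_id[s1$samples$group == "B"]])
  expect_gt(mean(b) / mean(a), 2)

  # a zero fold change leaves the groups exchangeable
  pl0 <- plant_dmrs("chr1", 10000, n_core_windows = 3, log2_fold_change = 0)
  s0 <- simulate_counts(g, sim_params(planted = pl0, dispersion = 0,
                                      size_factor_range = c(1, 1)), seed = 34)
  a0 <- rowMeans(s0$counts[idx, s0$samples$pool_id[s0$samples$group == "A"]])
  b0 <- rowMeans(s0$counts[idx, s0$samples$pool_id[s0$samples$group == "B"]])
  expect_equal(mean(b0) / mean(a0), 1, tolerance = 0.15)

  # cores must sit on the grid and inside the genome
  expect_error(plant_dmrs("chr1", 10050), "multiple")
  bad <- plant_dmrs("chr1", 49900, n_core_windows = 5)
  expect_error(simulate_counts(g, sim_params(planted = bad), seed = 1),
               "outside")
  expect_error(sim_params(dispersion = -1), ">= 0")
})

test_that("planted clusters expand to 3-10 evenly spaced DMRs", {
  pl <- plant_cluster("chr2", 1e6, n_dmrs = 5, span_bp = 2e6)
  expect_equal(nrow(pl), 5)
  expect_true(all(pl$core_start %% 100 == 0))
  expect_true(max(pl$core_start) - min(pl$core_start) <= 2e6)
  expect_error(plant_cluster("chr2", 0, n_dmrs = 2), "3-10")
  expect_error(plant_cluster("chr2", 0, n_dmrs = 11), "3-10")
})

test_that("the truth table round-trips through TSV unchanged", {
  pl <- plant_dmrs("chr1", c(1000, 5000), n_core_windows = c(2, 4),
                   log2_fold_change = c(3, 1.5), direction = c("up", "down"))
  sim <- simulate_counts(c(chr1 = 20000), sim_params(planted = pl), seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))
})

test_that("gene simulation places non-overlapping genes reproducibly", {
  g <- c(chr1 = 10000)
  genes <- simulate_genes(g, 4, gene_length = c(500, 1500), seed = 7)
  expect_equal(nrow(genes), 4)
  expect_true(all(genes$start >= 0 & genes$end <= 10000))
  o <- order(genes$start)
  expect_true(all(genes$end[o][-4] <= genes$start[o][-1])) # non-overlap
  expect_identical(genes, simulate_genes(g, 4, gene_length = c(500, 1500), seed = 7))

  expect_equal(nrow(simulate_genes(g, 0, seed = 1)), 0)
  # one gene inside a 1000-bp genome
  g1 <- simulate_genes(c(chr1 = 1000), 1, gene_length = c(200, 400), seed = 2)
  expect_true(g1$start >= 0 && g1$end <= 1000)
  # genes that cannot fit
  expect_error(
    simulate_genes(c(chr1 = 1000), 5, gene_length = c(900, 950), seed = 3,
                   max_tries = 50),
    "fit"
  )
})

test_that("gene annotations round-trip through BED", {
  genes <- simulate_genes(c(chr1 = 10000), 3, seed = 12)
  bed <- tempfile(fileext = ".bed")
  write_genes_bed(genes, bed)
  back <- read_genes(bed)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$name, genes$name)
  expect_equal(back$strand, genes$strand)
})
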