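iv <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = starts, end = ends)
}

test_that("set overlap counts shared and exclusive DMRs from both sides", {
  ov <- overlap_sets(iv(100, 200), iv(150, 300))
  expect_equal(c(ov$a_shared, ov$a_only, ov$b_shared, ov$b_only), c(1, 0, 1, 0))

  ov2 <- overlap_sets(iv(c(0, 1000), c(100, 1100)),
                      iv(c(5000, 6000, 7000), c(5100, 6100, 7100)))
  expect_equal(c(ov2$a_only, ov2$b_only, ov2$a_shared), c(2, 3, 0))

  same <- iv(c(0, 500), c(100, 600))
  ov3 <- overlap_sets(same, same)
  expect_equal(ov3$a_shared, 2L)
  expect_equal(ov3$b_only, 0L)

  # partitions always sum to the set sizes
  set.seed(5)
  for (rep in 1:5) {
    a <- iv(sort(sample(0:10000, 8)) * 1.0, numeric(8))
    a$end <- a$start + sample(50:500, 8, replace = TRUE)
    b <- iv(sort(sample(0:10000, 6)) * 1.0, numeric(6))
    b$end <- b$start + sample(50:500, 6, replace = TRUE)
    ov <- overlap_sets(a, b)
    expect_equal(ov$a_shared + ov$a_only, nrow(a))
    expect_equal(ov$b_shared + ov$b_only, nrow(b))
  }
})

test_that("pairwise within-group comparison runs every pool pair", {
  grid <- make_windows(c(chr1 = 3000), 100)
  set.seed(13)
  counts <- dplyr::bind_cols(grid, tibble::tibble(
    A1 = rpois(30, 50), A2 = rpois(30, 50), A3 = rpois(30, 50),
    B1 = rpois(30, 50), B2 = rpois(30, 50), B3 = rpois(30, 50)
  ))
  samples <- tibble::tibble(
    pool_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
    group = rep(c("A", "B"), each = 3)
  )
  res <- pairwise_within_group(counts, samples, "A", phi = 0.2)
  expect_equal(nrow(res), 3) # choose(3, 2)
  expect_setequal(paste(res$pool_1, res$pool_2),
                  c("A1 A2", "A1 A3", "A2 A3"))

  # identical pools yield no DMRs
  counts$A2 <- counts$A1
  res2 <- pairwise_within_group(counts, samples, "A", phi = 0.2)
  expect_equal(res2$n_dmrs[res2$pool_1 == "A1" & res2$pool_2 == "A2"], 0L)

  one <- samples[samples$pool_id == "A1", ]
  expect_error(pairwise_within_group(counts, one, "A", phi = 0.2), ">= 2 pools")
})

test_that("between-group DMRs are not explained by within-group variation", {
  # exchangeable pools within each group, strong planted between-group
  # signal; the claim is about the reproducible multiple-window class
  pl <- plant_dmrs("chr1", seq(50000, 950000, by = 100000), n_core_windows = 2)
  sim <- simulate_counts(c(chr1 = 1e6), sim_params(planted = pl), seed = 44)
  norm <- normalize_counts(sim$counts, sim$samples)
  fit <- estimate_common_dispersion(norm, sim$samples)
  between <- call_dmrs(test_windows(norm, sim$samples, fit))
  multi <- between[between$max_core_run >= 2, ]
  expect_gte(nrow(multi), 8)

  within_multi <- list()
  for (g in c("A", "B")) {
    res <- pairwise_within_group(sim$counts, sim$samples, g, fit)
    within_multi <- c(within_multi,
                      lapply(res$dmrs, function(d) d[d$max_core_run >= 2, ]))
  }
  within_multi <- dplyr::bind_rows(within_multi)
  hit <- if (nrow(within_multi) == 0) 0 else {
    overlap_sets(multi, within_multi)$a_shared
  }
  expect_lte(hit / nrow(multi), 0.1)
})

test_that("chi-square on category tables matches hand computation", {
  flat <- chisq_table(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  skew <- chisq_table(rbind(c(20, 5), c(5, 20)))
  expect_equal(skew$statistic, 18) # sum((O-E)^2/E), E = 12.5 throughout
  expect_equal(skew$df, 1)

  # invariant under row/column permutation
  m <- rbind(c(12, 3, 9), c(4, 18, 6))
  expect_equal(chisq_table(m)$statistic, chisq_table(m[, c(3, 1, 2)])$statistic)
  expect_equal(chisq_table(m)$statistic, chisq_table(m[c(2, 1), ])$statistic)

  expect_error(chisq_table(matrix(1:3, nrow = 1)), "two rows")
  expect_error(chisq_table(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, 9), 0.09)
  expect_equal(bonferroni(0.5, 9), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("noncentral-t power behaves like a power function", {
  # null effect: power equals the level
  expect_equal(power_two_sample_t(0, 20, 20, alpha = 0.05)$power, 0.05,
               tolerance = 1e-10)
  # monotone in effect size, sample size and level
  p_d <- power_two_sample_t(c(0.1, 0.3, 0.5, 0.8), 30, 30)$power
  expect_true(all(diff(p_d) > 0))
  expect_gt(power_two_sample_t(0.4, 60, 60)$power,
            power_two_sample_t(0.4, 30, 30)$power)
  expect_gt(power_two_sample_t(0.4, 30, 30, alpha = 0.1)$power,
            power_two_sample_t(0.4, 30, 30, alpha = 0.01)$power)
  # two-sided is symmetric in the sign of d
  two <- power_two_sample_t(c(-0.4, 0.4), 25, 35, alternative = "two.sided")$power
  expect_equal(two[1], two[2], tolerance = 1e-12)
  expect_error(power_two_sample_t(0.3, 1, 10), ">= 2")
})

test_that("noncentral-t power matches a Monte-Carlo t-test", {
  set.seed(99)
  d <- 0.5
  n1 <- 25
  n2 <- 40
  nsim <- 20000
  x <- matrix(rnorm(nsim * n1, mean = 0), ncol = n1)
  y <- matrix(rnorm(nsim * n2, mean = d), ncol = n2)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  sp <- sqrt(((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2))
  tstat <- (my - mx) / (sp * sqrt(1 / n1 + 1 / n2))
  crit <- qt(0.95, n1 + n2 - 2)
  mc_power <- mean(tstat > crit)
  expect_equal(power_two_sample_t(d, n1, n2)$power, mc_power, tolerance = 0.015)
})
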