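# Set-level comparisons between DMR analyses, within-population pairwise
# validation, and the small statistics used around them.

#' Overlap between two DMR sets
#'
#' A DMR is "shared" when it overlaps any DMR of the other set by at least
#' `min_overlap` bp. Shared counts are reported from both sides (the two can
#' differ when several DMRs of one set hit a single DMR of the other); each
#' set's shared + only partition sums to its size.
#'
#' @param set_a,set_b DMR tibbles (`chrom`, `start`, `end`) on the same
#'   genome coordinates.
#' @param min_overlap Minimum overlap in bp to count as shared.
#' @return One-row tibble: `n_a`, `n_b`, `a_shared`, `a_only`, `b_shared`,
#'   `b_only`.
#' @export
overlap_sets <- function(set_a, set_b, min_overlap = 1) {
  lv <- union(unique(as.character(set_a$chrom)), unique(as.character(set_b$chrom)))
  a_shared <- if (nrow(set_a) == 0 || nrow(set_b) == 0) 0L else {
    sum(GenomicRanges::countOverlaps(regions_granges(set_a, lv),
                                     regions_granges(set_b, lv),
                                     minoverlap = min_overlap) > 0)
  }
  b_shared <- if (nrow(set_a) == 0 || nrow(set_b) == 0) 0L else {
    sum(GenomicRanges::countOverlaps(regions_granges(set_b, lv),
                                     regions_granges(set_a, lv),
                                     minoverlap = min_overlap) > 0)
  }
  tibble(
    n_a = nrow(set_a), n_b = nrow(set_b),
    a_shared = as.integer(a_shared), a_only = nrow(set_a) - as.integer(a_shared),
    b_shared = as.integer(b_shared), b_only = nrow(set_b) - as.integer(b_shared)
  )
}

#' Pairwise within-group validation
#'
#' Repeats the full test-and-call pipeline on every unordered pair of pools
#' *within* one group (1-vs-1), using a supplied dispersion (a single pair
#' carries no replication to estimate one). DMRs recurring between pools of
#' the same population reflect within-population variation; comparing them
#' with the between-group DMR set shows whether the main analysis is an
#' artifact of that variation.
#'
#' @param counts Count tibble (grid plus pool columns), un-normalized.
#' @param samples Pool metadata (`pool_id`, `group`).
#' @param group Which group's pools to compare among themselves.
#' @param phi Common dispersion to reuse (number or `dispersion_fit`).
#' @param config A [dmr_config()].
#' @param reference Optional DMR tibble (e.g. the between-group multiple
#'   window DMRs); each pair then also reports how many reference DMRs its
#'   own DMRs overlap.
#' @return Tibble with one row per pool pair: `pool_1`, `pool_2`, `n_dmrs`,
#'   `n_multiple_window`, list-column `dmrs`, and `n_reference_shared` when
#'   `reference` is given.
#' @export
pairwise_within_group <- function(counts, samples, group, phi,
                                  config = dmr_config(), reference = NULL) {
  if (inherits(phi, "dispersion_fit")) phi <- phi$phi
  check_samples(samples)
  pools <- as.character(samples$pool_id[samples$group == group])
  if (length(pools) < 2) abort("need >= 2 pools in the group for pairwise comparison.")
  prs <- combn(pools, 2)
  cc <- coord_cols(counts)
  map(seq_len(ncol(prs)), function(k) {
    p1 <- prs[1, k]
    p2 <- prs[2, k]
    sub_samples <- tibble(pool_id = c(p1, p2), group = c("g1", "g2"))
    sub_counts <- counts[c(cc, p1, p2)]
    norm <- normalize_counts(sub_counts, sub_samples)
    dm <- call_dmrs(test_windows(norm, sub_samples, phi), config)
    row <- tibble(
      pool_1 = p1, pool_2 = p2,
      n_dmrs = nrow(dm),
      n_multiple_window = sum(dm$max_core_run >= 2),
      dmrs = list(dm)
    )
    if (!is.null(reference)) {
      ov <- overlap_sets(reference, dm)
      row$n_reference_shared <- ov$a_shared
    }
    row
  }) |> list_rbind()
}

#' Pearson chi-square test on a category table
#'
#' Classic chi-square comparison of two or more count profiles (e.g. gene
#' category counts of two species), without continuity correction.
#'
#' @param table Integer matrix (or data frame) of non-negative counts with
#'   at least two rows and two columns; all expected counts must be positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chisq_table(rbind(c(20, 5), c(5, 20))) # statistic 18, df 1
#' @export
chisq_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(m < 0) || any(!is.finite(m))) {
    abort("`table` must contain finite non-negative counts.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("`table` needs at least two rows and two columns.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate table: a row or column sums to zero (expected counts must be > 0).")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for `m` tests.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of tests (>= 1); defaults to `length(p)`.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1].")
  if (m < 1) abort("`m` must be >= 1.")
  pmin(1, p * m)
}

#' Power of the two-sample t-test
#'
#' Exact noncentral-t power for a standardized effect size `d` (Cohen's d)
#' with group sizes `n1`, `n2`: noncentrality `d / sqrt(1/n1 + 1/n2)` on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Standardized effect size(s); vectorised.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Significance level.
#' @param alternative `"one.sided"` or `"two.sided"`.
#' @return Tibble with one row per `d`: `d`, `n1`, `n2`, `alpha`,
#'   `alternative`, `power`.
#' @examples
#' power_two_sample_t(c(0.256, 0.358), n1 = 171, n2 = 121)
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05,
                               alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n1 < 2 || n2 < 2) abort("`n1` and `n2` must be >= 2.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  power <- if (alternative == "one.sided") {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  }
  tibble(d = d, n1 = n1, n2 = n2, alpha = alpha,
         alternative = alternative, power = power)
}
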