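# Two-group negative-binomial exact test per window.
#
# Under the null each pool count in window w is NB(mu, phi) with
# var = mu + phi mu^2. The group totals are then NB with sizes n_A/phi and
# n_B/phi sharing the same success probability, so the distribution of the
# first group's total Y_A conditional on the grand total s = Y_A + Y_B is
# free of mu and can be enumerated exactly:
#
#   P(Y_A = y | s) = C(y + r_A - 1, y) C(s - y + r_B - 1, s - y)
#                    / C(s + r_A + r_B - 1, s),   r_g = n_g / phi,
#
# reducing to Binomial(s, n_A/(n_A+n_B)) in the Poisson limit phi -> 0. The
# two-sided p-value follows the minimum-likelihood rule: the summed
# conditional probability of all outcomes no more likely than the observed
# split, capped at 1.

# relative tolerance when deciding "no more likely than the observed
# outcome": protects exact symmetry ties from floating-point noise
PMF_TIE_TOL <- 1e-8

nb_cond_log_pmf <- function(s, n_a, n_b, phi) {
  if (s < 0) abort("`s` must be >= 0.")
  if (phi < 0) abort("`phi` must be >= 0.")
  y <- 0:s
  if (phi == 0) {
    lp <- dbinom(y, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    ra <- n_a / phi
    rb <- n_b / phi
    # log rising factorials as cumulative sums of log(r + i): stable for any
    # r, in particular the huge r of the phi -> 0 limit where lgamma
    # differences lose all precision
    i <- seq_len(s) - 1
    ca <- c(0, cumsum(log(ra + i)))
    cb <- c(0, cumsum(log(rb + i)))
    lf <- lfactorial(0:s)
    lp <- ca[y + 1] - lf[y + 1] + cb[s - y + 1] - lf[s - y + 1]
    m <- max(lp)
    lp <- lp - (m + log(sum(exp(lp - m))))
  }
  lp
}

# p-value lookup for every possible value of Y_A given one log-pmf
pvals_from_log_pmf <- function(lp, tol = PMF_TIE_TOL) {
  ord <- order(lp)
  slp <- lp[ord]
  cum <- cumsum(exp(slp))
  cum <- cum / cum[length(cum)] # total mass exactly 1 despite rounding
  idx <- findInterval(slp + tol, slp)
  out <- numeric(length(lp))
  out[ord] <- pmin(cum[idx], 1)
  out
}

#' Conditional distribution behind the exact test
#'
#' Enumerates the exact distribution of the first group's total count given
#' the grand total `s`, for `n_a` and `n_b` pools per group and common NB
#' dispersion `phi` (`phi = 0` gives the conditional binomial of the Poisson
#' limit). The probabilities sum to 1.
#'
#' @param s Grand total count across both groups.
#' @param n_a,n_b Number of pools in each group.
#' @param phi Common NB dispersion (>= 0).
#' @return Tibble with columns `y` (0..s) and `prob`.
#' @examples
#' nb_cond_pmf(10, 3, 3, 0)   # Binomial(10, 1/2)
#' @export
nb_cond_pmf <- function(s, n_a, n_b, phi) {
  tibble(y = 0:s, prob = exp(nb_cond_log_pmf(s, n_a, n_b, phi)))
}

#' Exact-test p-values for every possible split of a total
#'
#' The full p-value profile of the conditional exact test at grand total `s`:
#' row `y` gives the two-sided minimum-likelihood p-value that would be
#' reported had the first group's total been `y`.
#'
#' @inheritParams nb_cond_pmf
#' @return Tibble with columns `y` and `p_value`.
#' @export
nb_exact_pvalues <- function(s, n_a, n_b, phi) {
  tibble(y = 0:s, p_value = pvals_from_log_pmf(nb_cond_log_pmf(s, n_a, n_b, phi)))
}

#' Two-group NB exact test for one window
#'
#' Tests whether normalized counts differ between two groups of pools using
#' the exact conditional distribution of the first group's total given the
#' grand total (see [nb_cond_pmf()]). With a grand total of zero there is no
#' information and p = 1. The reported fold change is
#' `log2((mean_b + 0.5) / (mean_a + 0.5))`, the pseudo-count guarding against
#' division by zero.
#'
#' @param y_a,y_b Non-negative integer count vectors (one entry per pool).
#' @param phi Common NB dispersion (>= 0; 0 = Poisson / conditional binomial).
#' @return One-row tibble: `p_value`, `log2_fc`, `mean_a`, `mean_b`.
#' @examples
#' nb_exact_test(c(10, 0, 0), c(0, 0, 0), phi = 0)  # p = 2/1024
#' @export
nb_exact_test <- function(y_a, y_b, phi) {
  if (any(y_a < 0) || any(y_b < 0)) abort("counts must be non-negative.")
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0) abort("`phi` must be a single number >= 0.")
  ya <- sum(y_a)
  yb <- sum(y_b)
  n_a <- length(y_a)
  n_b <- length(y_b)
  s <- ya + yb
  p <- if (s == 0) 1 else pvals_from_log_pmf(nb_cond_log_pmf(s, n_a, n_b, phi))[ya + 1]
  tibble(
    p_value = p,
    log2_fc = log2((yb / n_b + 0.5) / (ya / n_a + 0.5)),
    mean_a = ya / n_a,
    mean_b = yb / n_b
  )
}

#' Per-window differential coverage track
#'
#' Runs the NB exact test on every window and returns the p-value track the
#' DMR caller consumes. The two group labels are taken in sorted order: the
#' first is the reference ("A") and `log2_fc` is second-vs-first. Windows
#' with a grand total of 0 get p = 1. Tests are pooled by grand total, so a
#' full genome scan costs one enumeration per distinct total rather than per
#' window.
#'
#' @param counts Count tibble (grid columns plus one column per pool),
#'   normally from [normalize_counts()].
#' @param samples Pool metadata with `pool_id` and `group` (exactly two
#'   groups).
#' @param phi Common NB dispersion: a number or a fit from
#'   [estimate_common_dispersion()].
#' @return Tibble in grid order: grid columns plus `p_value`, `log2_fc`,
#'   `mean_a`, `mean_b`.
#' @export
test_windows <- function(counts, samples, phi) {
  if (inherits(phi, "dispersion_fit")) phi <- phi$phi
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0) abort("`phi` must be a single number >= 0.")
  check_samples(samples)
  grp <- sort(unique(as.character(samples$group)))
  if (length(grp) != 2) abort("`samples` must contain exactly two groups.")
  m <- counts_matrix(counts, samples)
  a_cols <- which(as.character(samples$group) == grp[1])
  b_cols <- which(as.character(samples$group) == grp[2])
  n_a <- length(a_cols)
  n_b <- length(b_cols)
  ya <- rowSums(m[, a_cols, drop = FALSE])
  yb <- rowSums(m[, b_cols, drop = FALSE])
  s <- ya + yb
  p <- rep(1, length(s))
  by_s <- split(seq_along(s), s)
  for (sv in names(by_s)) {
    sn <- as.numeric(sv)
    if (sn == 0) next
    look <- pvals_from_log_pmf(nb_cond_log_pmf(sn, n_a, n_b, phi))
    idx <- by_s[[sv]]
    p[idx] <- look[ya[idx] + 1]
  }
  bind_cols(
    counts[coord_cols(counts)],
    tibble(
      p_value = p,
      log2_fc = log2((yb / n_b + 0.5) / (ya / n_a + 0.5)),
      mean_a = ya / n_a,
      mean_b = yb / n_b
    )
  )
}

#' Normalize pool columns to a common library size
#'
#' Scales every pool column proportionally to the mean library size and
#' rounds half-to-even back to integers, preserving the integer counts the
#' exact test requires. Columns whose sum is zero are left as zeros. This is
#' a deliberately simple, fully specified alternative to quantile or TMM
#' adjustment.
#'
#' @param counts Count tibble (grid columns plus pool columns).
#' @param samples Pool metadata (`pool_id`, `group`).
#' @return The counts tibble with scaled pool columns; scaling factors are
#'   attached as attribute `"scale_factors"` and the post-scaling column sums
#'   as `"library_size"`.
#' @examples
#' counts <- tibble::tibble(chrom = "chr1", start = 0, end = 100, P1 = 4, P2 = 12)
#' samples <- tibble::tibble(pool_id = c("P1", "P2"), group = c("A", "B"))
#' lib <- c(100, 300) # pretend library sizes via extra mass elsewhere
#' @export
normalize_counts <- function(counts, samples) {
  m <- counts_matrix(counts, samples)
  lib <- colSums(m)
  if (all(lib == 0)) abort("all counts are zero; nothing to normalize.")
  target <- mean(lib)
  f <- ifelse(lib > 0, target / lib, 1)
  mm <- round(sweep(m, 2, f, `*`))
  out <- counts
  out[colnames(m)] <- as_tibble(mm)
  attr(out, "scale_factors") <- setNames(f, colnames(m))
  attr(out, "library_size") <- setNames(colSums(mm), colnames(m))
  out
}
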