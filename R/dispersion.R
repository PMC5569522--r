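# Common NB dispersion by conditional maximum likelihood.
#
# Conditioning each group's window counts on their group total removes the
# window mean from the likelihood, leaving a function of the dispersion
# alone. With n pools of NB(mu, phi) counts and r = 1/phi,
#
#   P(y_1..y_n | sum = s) = prod_j C(y_j + r - 1, y_j) / C(s + n r - 1, s),
#
# summed in log form over all windows and all groups with >= 2 pools.

#' Estimate the common NB dispersion
#'
#' Maximizes the within-group conditional NB log-likelihood, summed over
#' windows, over the dispersion `phi`; a single dispersion is shared by all
#' windows. The likelihood is profiled on a logarithmic grid spanning
#' `phi_range` and the best bracket refined with a golden-section style 1-D
#' search. All-zero windows carry no information and are excluded.
#'
#' @param counts Normalized count tibble (grid columns plus pool columns).
#' @param samples Pool metadata; at least one group needs >= 2 pools (a
#'   1-vs-1 design cannot separate dispersion from signal — supply `phi`
#'   explicitly downstream instead).
#' @param phi_range Search range for `phi`.
#' @param grid_length Number of log-grid points profiled before refinement.
#'
#' @return An object of class `dispersion_fit`: `phi`, `log_lik`,
#'   `n_windows_used`, `n_samples`, `method`. Supports [tidy()] and
#'   [glance()].
#' @export
estimate_common_dispersion <- function(counts, samples, phi_range = c(1e-6, 5),
                                       grid_length = 30) {
  check_samples(samples)
  m <- counts_matrix(counts, samples)
  groups <- split(seq_len(nrow(samples)), as.character(samples$group))
  usable <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(usable) == 0) {
    abort("no group has >= 2 pools; the dispersion cannot be estimated - supply `phi` explicitly.")
  }
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) abort("all windows are zero; cannot estimate dispersion.")

  group_parts <- lapply(usable, function(cols) {
    y <- m[, cols, drop = FALSE]
    list(y = y, s = rowSums(y), n = length(cols))
  })
  cond_ll <- function(phi) {
    r <- 1 / phi
    tot <- 0
    for (g in group_parts) {
      tot <- tot +
        sum(lgamma(g$y + r)) - length(g$y) * lgamma(r) - sum(lfactorial(g$y)) -
        sum(lgamma(g$s + g$n * r)) + length(g$s) * lgamma(g$n * r) + sum(lfactorial(g$s))
    }
    tot
  }

  grid <- exp(seq(log(phi_range[1]), log(phi_range[2]), length.out = grid_length))
  ll <- vapply(grid, cond_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_length, i + 1L)]
  opt <- optimize(function(lp) cond_ll(exp(lp)), interval = log(c(lo, hi)),
                  maximum = TRUE, tol = 1e-8)
  phi <- exp(opt$maximum)
  log_lik <- opt$objective
  if (ll[i] > log_lik) {
    phi <- grid[i]
    log_lik <- ll[i]
  }
  structure(
    list(
      phi = phi, log_lik = log_lik, n_windows_used = sum(keep),
      n_samples = nrow(samples), method = "conditional-ML"
    ),
    class = "dispersion_fit"
  )
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit> phi = %.4g (%s, %d windows, %d pools)\n",
              x$phi, x$method, x$n_windows_used, x$n_samples))
  invisible(x)
}

#' Tidy a dispersion fit
#' @param x A `dispersion_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term` and `estimate`.
#' @export
tidy.dispersion_fit <- function(x, ...) {
  tibble(term = "dispersion", estimate = x$phi)
}

#' @rdname tidy.dispersion_fit
#' @return `glance()` returns a one-row tibble with `phi`, `log_lik`,
#'   `n_windows_used`, `n_samples`, `method`.
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble(
    phi = x$phi, log_lik = x$log_lik, n_windows_used = x$n_windows_used,
    n_samples = x$n_samples, method = x$method
  )
}
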