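# Independent oracles used to verify the implementation by a different route.

# Conditional pmf of the first group's total given the grand total, via
# binomial coefficients and the analytic Vandermonde normalizer (the
# implementation normalizes numerically in log space instead).
oracle_cond_pmf <- function(s, n_a, n_b, phi) {
  y <- 0:s
  if (phi == 0) {
    exp(lchoose(s, y) + y * log(n_a / (n_a + n_b)) + (s - y) * log(n_b / (n_a + n_b)))
  } else {
    ra <- n_a / phi
    rb <- n_b / phi
    exp(lchoose(y + ra - 1, y) + lchoose(s - y + rb - 1, s - y) -
          lchoose(s + ra + rb - 1, s))
  }
}

# Minimum-likelihood two-sided p for every possible first-group total, by
# naive enumeration: sum the probabilities of all outcomes no more likely
# than the observed one (same published tie rule as the implementation,
# relative tolerance 1e-8).
oracle_exact_pvalues <- function(s, n_a, n_b, phi) {
  pr <- oracle_cond_pmf(s, n_a, n_b, phi)
  vapply(seq_along(pr), function(i) {
    min(1, sum(pr[pr <= pr[i] * (1 + 1e-8)]))
  }, numeric(1))
}

# Regex-free sliding-window CpG counter.
oracle_cpg_count <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 2) return(0L)
  sum(chars[-n] == "C" & chars[-1] == "G")
}

# Handcrafted genome object for annotation tests.
toy_genome <- function(seqs) {
  structure(
    list(
      chromosomes = tibble::tibble(chrom = names(seqs), length = nchar(seqs)),
      sequence = seqs
    ),
    class = "medip_genome"
  )
}

# A 100-bp-window p-value track on one chromosome from a bare p vector.
toy_track <- function(p, chrom = "chr1", w = 100) {
  tibble::tibble(
    chrom = chrom,
    start = (seq_along(p) - 1) * w,
    end = seq_along(p) * w,
    p_value = p
  )
}
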