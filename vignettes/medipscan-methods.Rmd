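---
title: "Methods: windowed differential methylation analysis for pooled MeDIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed differential methylation analysis for pooled MeDIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipscan)
library(dplyr)
```

## The measurement and the model

MeDIP-seq enriches methylated DNA fragments with a 5-methylcytosine
antibody and sequences the enriched pool, so local methylation is read out
as sequencing coverage. To compare two populations (say, two localities)
the genome is tiled into fixed 100 bp windows and each pooled library's
reads are counted per window; a window whose coverage differs between
groups beyond what count noise explains is differentially methylated, and
runs of such windows form differentially methylated regions (DMRs).

The count model is the standard one for sequencing counts with biological
replication: the count of pool $j$ in window $w$ is negative binomial,

$$y_{wj} \sim \mathrm{NB}(\mu_w s_j,\ \phi), \qquad
  \operatorname{Var}(y) = \mu + \phi\,\mu^2,$$

with a window mean $\mu_w$, a pool-specific size factor $s_j$, and a single
*common* dispersion $\phi$ shared by all windows. Each sequenced pool —
not each bird — is one statistical replicate; with three pools per group
there is too little replication to support per-window (tagwise) dispersion,
which is why a common $\phi$ is used.

### Library-size normalization

Pool columns are scaled proportionally to the mean library size and
rounded half-to-even back to integers (`normalize_counts()`). The rounding
preserves the integer counts the exact test needs; at typical window depths
the rounding perturbation is negligible relative to count noise. This is a
deliberately simple, fully specified stand-in for heavier normalization
schemes (TMM, quantile adjustment); CpG-coupling corrections used by some
MeDIP tools are intentionally not modelled.

### Common dispersion by conditional maximum likelihood

Conditioning a group's counts on their group total cancels $\mu_w$
exactly, leaving a likelihood in $\phi$ alone:

$$P(y_1,\dots,y_n \mid \textstyle\sum_j y_j = s)
  = \frac{\prod_j \binom{y_j + r - 1}{y_j}}{\binom{s + nr - 1}{s}},
  \qquad r = 1/\phi .$$

`estimate_common_dispersion()` sums this over all windows and all groups
with at least two pools, profiles it on a 30-point logarithmic grid over
$[10^{-6}, 5]$, and refines the best bracket with Brent's bracketed 1-D
maximization. All-zero windows are excluded (they carry no information).
Poisson data drive the estimate to the lower boundary; a 1-vs-1 design is
refused with instructions to supply $\phi$ explicitly, because a single
pair cannot separate dispersion from signal.

### The windowed exact test

Under the null the two group totals are NB with sizes $n_A/\phi$ and
$n_B/\phi$ and a shared success probability, so the first group's total
$Y_A$ given the grand total $s$ has the exact conditional distribution

$$P(Y_A = y \mid s) \propto
  \binom{y + r_A - 1}{y}\binom{s - y + r_B - 1}{s - y},
  \qquad r_g = n_g/\phi,$$

reducing to $\mathrm{Binomial}(s,\ n_A/(n_A+n_B))$ as $\phi \to 0$. The
two-sided p-value follows the minimum-likelihood rule — the summed
probability of every outcome no more likely than the observed split — which
is well defined for unequal group sizes, unlike doubling a one-sided tail.
Numerical choices worth recording:

* the log-pmf is built from cumulative sums of $\log(r + i)$ rather than
  `lgamma` differences, which lose all precision when $r$ is large (the
  small-$\phi$ limit);
* the pmf is normalized in log space and the cumulative mass rescaled so it
  sums to exactly 1, making the balanced split report $p = 1$ exactly;
* outcomes within a relative $10^{-8}$ of the observed probability count as
  ties, protecting exact symmetry ties from floating-point noise;
* a grand total of 0 gives $p = 1$ by definition;
* the fold change is $\log_2\!\big((\bar y_B + 0.5)/(\bar y_A + 0.5)\big)$,
  the pseudo-count guarding against empty groups.

`test_windows()` groups windows by grand total, so a genome-wide scan costs
one enumeration per distinct total rather than one per window.

## DMR calling

Thresholds live in `dmr_config()`; defaults are 100 bp windows, core
threshold $10^{-3}$, extension threshold $0.1$, extension reach 1000 bp,
2 Mb / 50 kb cluster scan, 10 kb gene flank.

1. **Cores.** Windows with $p < 10^{-3}$ form maximal runs of grid-adjacent
   windows.
2. **Edge extension.** While any window with $p < 0.1$ lies within 1000 bp
   (edge-to-edge) of the current span, the span grows to cover it, so
   chains of sub-threshold windows are absorbed until a fixed point — after
   termination no $p < 0.1$ window remains within reach of any DMR. "Within
   1000 bp" is read inclusively (a window exactly 1000 bp away extends);
   the exclusive reading is one config switch away, since either reading of
   the rule is defensible.
3. **Merging.** Spans that touch or overlap merge into one DMR, pooling
   their core windows. Extension never crosses a chromosome boundary.
4. **Classification.** A DMR whose longest run of *adjacent* core windows
   is $\ge 2$ is a `multiple_window` DMR — the high-confidence class, since
   two independent adjacent detections are far less likely under the null —
   otherwise `single_window`. Note a merged DMR can hold two non-adjacent
   cores and still be single-window by this rule.

`summarize_dmrs()` tabulates DMRs by that longest run (1, 2, 3, 4, 5+), and
`multiple_window_sum()` gives the headline multiple-window total, either
from called DMRs or from an already tabulated breakdown.

One property worth stating precisely: loosening the core threshold can
both add DMRs (new isolated cores) and remove them (a new core can bridge
and merge two formerly separate regions), so the DMR *count* is not
monotone in `p_core` in either direction. DMR *coverage* is — loosening
`p_core` only grows the union of called spans — and that is the property
the tests assert.

## Cluster scan

DMRs aggregate on the megabase scale. `scan_clusters()` reduces DMRs to
midpoints, slides a 2 Mb window in 50 kb steps, and compares each window's
member count against a uniform genome-wide rate: under uniformity the
count is approximately Poisson with
$\lambda = (\text{total DMRs}/\text{genome length}) \times 2\,\text{Mb}$,
and the exact upper tail $P(X \ge k)$ is the over-representation statistic.
$\lambda$ is computed genome-wide rather than per chromosome because
per-chromosome DMR counts are too small to give stable rates.

A scan evaluates thousands of overlapping windows, so an uncorrected
per-window level would flag spurious clusters in most datasets — measured
on uniformly placed DMRs (20 on 100 Mb), roughly 60% of datasets contain
at least one window with three co-located midpoints, which an uncorrected
$\alpha = 0.05$ calls significant. The scan therefore applies a Bonferroni
correction over the number of scanned positions by default
(`cluster_p_adjust = "bonferroni"`), making `cluster_alpha` a family-wise
level: uniform genomes stay clean in at least $1 - \alpha$ of datasets by
construction, while a genuine tight cluster (five DMRs in 100 kb on an
otherwise empty 100 Mb genome has a raw tail of $8\times10^{-9}$) remains
significant after the correction with orders of magnitude to spare.
Overlapping significant windows merge, the reported span runs from the
first to the last member DMR, and regions with fewer than three members
are dropped. The uncorrected scan remains available as a config option.

## Annotation

`cpg_count()` counts `CG` dinucleotides (case-insensitive, `N` never
matches; the motif cannot overlap itself). `annotate_cpg_density()` reports
CpG per 100 bp over the full extended DMR span and bins by
`floor(density)`, class 0 being the sub-1-CpG/100 bp "CpG desert" class
where clustered methylation differences are nonetheless common.
`associate_genes()` widens each DMR by a symmetric 10 kb flank (clipped at
zero) and associates every gene whose *body* overlaps the flanked span by
at least one base; strand is ignored because the flank is symmetric, and
growing the flank can only add associations.

## Validation utilities

`overlap_sets()` counts DMRs shared between two analyses (shared = any
overlap of at least 1 bp, configurable), reported from both sides so each
set's shared/exclusive partition sums to its size.
`pairwise_within_group()` reruns the full test-and-call pipeline on every
pool pair *within* a population (1-vs-1, reusing the between-group
dispersion): DMRs recurring within a population reflect within-population
variation, and their (lack of) overlap with the between-group set shows the
main result is not an artifact of sampling variation.

`chisq_table()` (Pearson, no continuity correction), `bonferroni()` and
`power_two_sample_t()` (exact noncentral-$t$ power,
$\delta = d/\sqrt{1/n_1 + 1/n_2}$, $df = n_1 + n_2 - 2$) round out the
small statistics used around the pipeline. For the morphology power
calculation the package defaults to a one-sided $\alpha = 0.05$; the
sidedness of the original calculation is not documented anywhere we could
verify, and the one-sided convention is the one that reproduces the
published 0.69–0.91 range, so it is flagged here as an inferred default
rather than a known fact.

## The synthetic-data generator

`simulate_genome()` builds random sequences whose CpG content is exact by
construction: the background is scrubbed of accidental `CG` dinucleotides
and CpGs are planted at a controlled per-bp rate (0.5 forces uninterrupted
`CG` repeats), so density classes are populated exactly as directed.
`simulate_counts()` draws NB window counts around a CpG-density-modulated
baseline with pool size factors drawn log-uniform on $[0.7, 1.4]$ — wide
enough that skipping normalization visibly mis-calibrates the test — and
multiplies one group's mean by $2^{\mathrm{lfc}}$ inside planted cores.
`simulate_reads()` optionally materializes counts as BED reads whose
midpoints land in the intended windows, exercising the counting path
end-to-end; `simulate_genes()` places non-overlapping gene intervals for
the association stage.

Defaults are chosen to mirror a pooled two-population design: 2 groups × 3
pools (each pool a multi-individual DNA pool), mean depth 100 reads per
window per pool — within the roughly 100-to-1000 reads-per-DMR coverage
regime this kind of experiment produces — dispersion $\phi = 0.3$, planted
effects of $\log_2\mathrm{FC} = 3$ spanning 1–5 windows, and planted
clusters of 3–10 DMRs.

What the generator does *not* emulate: antibody enrichment chemistry and
its CpG-density-dependent efficiency, fragment-size distributions beyond a
fixed extension, sequencing error, mappability variation, and correlated
window baselines. Passing tests therefore demonstrate the statistical
machinery is correct under its stated model, not that the model captures
every property of real MeDIP-seq data.

## Detection power, measured

Two numbers calibrate expectations. Under the null (no planted effect,
$\phi = 0.3$, depth 100, 3v3), the fraction of windows below the $10^{-3}$
core threshold is about $10^{-3}$ (the exact test is near-calibrated,
slightly conservative by discreteness), and spurious *multiple-window*
DMRs are essentially absent ($\ll 1$ per $10^5$ windows), which is the
point of the multiple-window class.

Against planted signal, the per-window power at an 8-fold change, depth
100 and $\phi = 0.3$ is about 0.86: at the expected split (300 vs 2400
reads) the exact conditional p-value is $2\times10^{-5}$, but NB spread
around that split crosses the $10^{-3}$ threshold in roughly 14% of draws.
A planted two-window DMR needs both adjacent windows significant and is
therefore recovered as a multiple-window DMR about 75% of the time;
four-or-five-window DMRs are recovered in $\ge 99\%$ of cases, and the
average over spans 2–5 is roughly 87%. Sensitivity climbs quickly with
depth or fold change and exceeds 95% per window once $\phi \lesssim 0.25$
at these depths — worth knowing when choosing sequencing depth for a
pooled design.

## Problem sizes used by the test-suite simulations

Monte-Carlo checks run at sizes chosen to make their bounds sharp at
desk scale: $10^4$ windows for moment and dispersion-recovery checks,
$10^5$ windows for null calibration, 200 planted DMRs on a 20 Mb toy
genome for sensitivity, 20 replicates for the uniform-placement cluster
null, and full enumeration up to grand totals of 200 for exact-test
equivalence. Fixed seeds make every simulated result bit-reproducible.

## Known limitations

* A single common dispersion: no trended or tagwise moderation, no
  covariates, no GLM framework.
* Raw p-value thresholds throughout the caller, by design; no FDR control
  is applied or implied for window-level calls.
* Midpoint read assignment ignores fragments straddling window boundaries
  (by construction each read increments exactly one window).
* Proportional normalization does not correct composition bias.
* The cluster statistic assumes uniform placement as its null; DMR length
  variation and chromosome-level rate differences are not modelled.
* SAM import takes the query width as the reference span, ignoring indels
  in the CIGAR — immaterial for midpoint counting of short reads.
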