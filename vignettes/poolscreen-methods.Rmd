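---
title: "Models and methods behind poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The measurement model

A pooled shRNA screen measures fitness indirectly: each cell carries one
integrated hairpin, and a hairpin that speeds or slows its host's growth
changes in relative abundance between an early timepoint (T2) and a late
one (T14). Sequencing the hairpin amplicons gives, per sample, a vector of
counts over the pool's 19–22 nt antisense sequences. Three features of this
measurement drive every modelling choice in the package:

1. **Counts are compositional.** A sample is sequenced to a depth set by
   the machine, not by the biology; only relative abundances are
   observable. The simulator therefore renormalizes T14 proportions after
   applying fitness folds, and the test works conditionally on totals.
2. **Counts are overdispersed.** Biological replicates disagree more than
   Poisson sampling allows. We use the standard negative binomial
   parameterization with variance μ + φμ², where a single *common
   dispersion* φ is shared by all hairpins of a pool; φ = 0 recovers
   Poisson. A common φ is a deliberate bias/variance trade-off: with three
   replicates per arm, per-hairpin dispersions are essentially
   unestimable.
3. **Matching is exact.** The PCR product has fixed geometry — index,
   constant primer region, hairpin — so the counter compares fixed-offset
   substrings and tolerates no mismatches. A read with any error in the
   index or hairpin span is simply not counted; the counting report keeps
   the arithmetic honest (`total = matched + index_only + hairpin_only +
   unmatched`).

## Conditional inference

### Common dispersion

For hairpin *h* with counts *y₁…yₙ* in one group, all NB(μ, φ), the
distribution of the counts *conditional on their sum* is negative
hypergeometric (Dirichlet-multinomial with equal shapes 1/φ) and does not
involve μ. Summing these conditional log-likelihoods over all hairpins and
both groups gives a one-parameter criterion ℓ(φ) that `common_dispersion()`
maximizes over φ ∈ [10⁻⁸, 20] (Brent search, tolerance 10⁻⁸). Depth is
first equalized by linear scaling to the geometric-mean library size
(`equalize_libsizes()`), and pseudo-counts are rounded, because the
conditional argument needs exchangeable integer counts. The linear scaling
is a declared simplification of quantile-based depth adjustment; the two
coincide exactly at equal depths, and the package's cross-checks against an
independent implementation show agreement to ~10⁻³ in φ at realistic depth
spreads.

### The exact test

Under the null, the T2 group sum A (n₁ samples) and T14 group sum B (n₂
samples) are NB(n₁μ, φ/n₁) and NB(n₂μ, φ/n₂) — aggregation is exact for NB
with common success probability, which also handles unequal replicate
numbers. Given S = A + B, the law of A is free of μ:

P(A = a | S) ∝ C(a + r₁ − 1, a) · C(S − a + r₂ − 1, S − a),  rᵢ = nᵢ/φ,

a Binomial(S, n₁/(n₁+n₂)) in the φ → 0 limit. The two-sided p-value follows
the minimum-likelihood convention: the sum of P(a′|S) over every split a′
whose probability does not exceed the observed one (ties included, with a
relative slack of 10⁻¹⁰ so that floating-point twins of exact mirror ties
are kept together). Enumeration runs over 0…S in log space and is shared
between hairpins with equal S; totals above 10⁶ raise an error asking for
downsampling rather than silently approximating.

Reported per hairpin: `logFC = log2((B/n₂ + c)/(A/n₁ + c))` with prior
count c = 0.5 (finite at zero counts; configurable), `logCPM` on the common
library size, the exact p-value, and BH FDR — computed within each pool by
default, since each pool is an independently designed experiment; a global
mode exists. S = 0 rows get p = 1 and logFC = 0 by convention.

### Hit calling

`classify_hits()` applies the screen's published rule: FDR ≤ 0.01
(*inclusive* — this reproduces the 80-row published table, whose caption
uses ≤ while the text says <) and linear fold-change *strictly* above 1.5
(or below 1/1.5). Unique genes are counted case-insensitively because
screen tables mix symbol capitalisations.

## The synthetic screen

`simulate_truth()` draws, per pool: log-normal baseline proportions
(`baseline_sdlog`, default 0.5 — hairpin abundances in a well-constructed
library mostly span under an order of magnitude, and this keeps the most
abundant hairpin's pooled total comfortably inside the exact test's direct
enumeration range at the default million-read depth); a planted hit set
(`hit_fraction`, default 0.1, split half enriched at fold 3, half depleted
at fold 1/3); optionally Poisson founder-cell counts (`bottleneck_mean`,
default 77 when enabled, the screen's expected per-hairpin representation)
that multiply the baseline weights and can drop hairpins entirely; and
log-normal per-sample depths around `mean_libsize` (default 10⁶,
`libsize_sdlog` 0.2). `simulate_counts()` then draws NB counts with the
common φ (default 0.1, a typical replicate-level biological CV of ~0.32),
renormalizing T14 proportions within pool. `emit_fastq()` inverts the
counter: exactly count(h, s) reads of layout index + spacer + antisense +
random filler, constant quality `I` (the pipeline is quality-blind),
optional uniform per-base substitution errors, and read ids that encode
nothing. All randomness flows from one integer seed and the caller's RNG
state is restored.

What the generator deliberately does *not* emulate: PCR amplification
jackpots, GC- or position-dependent error profiles, index hopping,
chimeric reads, and per-hairpin dispersion heterogeneity. Passing recovery
tests therefore demonstrate correctness of the analysis under its own
model assumptions, not robustness to every artefact of real sequencing.

## Numerical and degenerate-input choices

* Depth equalization excludes all-zero columns from the geometric mean and
  leaves them zero; an entirely zero matrix errors.
* The read layout is fully configurable (`read_structure()`); the default
  places the 5 bp index at the read start followed by the 20 nt common
  primer region — the original run's sequencer-facing orientation is a
  convention, not a claim.
* Library validation rejects a pool in which one antisense is a prefix of
  another: with 19–22 nt hairpins at a fixed offset, a prefix collision
  would let a single read match two hairpins.
* MDS QC uses leading log-fold-change distances (root-mean-square of the
  top-k largest per-hairpin log2 differences of 0.5-offset CPMs) with
  classical scaling; samples beyond 5 MADs on either axis are *flagged*,
  never dropped — outlier removal is the analyst's decision.
* The limiting-dilution estimator maximizes the single-hit binomial
  likelihood on the log-frequency scale, polishes the root of the score to
  ~10⁻¹² relative, and inverts the likelihood ratio at χ²₁(0.95) for the
  CI. All-negative assays return f = 0 with a finite upper limit;
  all-positive assays error (f is unbounded above).
* Probe collapse breaks exact mean ties by the lexicographically smallest
  probe id, a declared convention.

## Validation strategy and known limitations

The test suite validates each layer against an independent route: the
counter against per-read string comparison; the exact test against direct
enumeration of the conditional law for every split of every total up to
200 at several φ and group sizes (agreement to 10⁻¹² relative), and
against an established NB screen-analysis implementation on equal-depth
data; the dispersion estimator against exhaustive grid search and
parameter-recovery simulations; TMM against an independent reference
implementation; and the full pipeline against its own simulator's ground
truth, including null calibration (type-I error and super-uniformity of
p-values).

Two limitations deserve mention. First, linear depth equalization is
slightly cruder than quantile adjustment when depths differ several-fold;
for the screen's designs the difference is negligible, but extremely
unbalanced depths deserve the cross-check. Second, recovery power under
the default simulation is asymmetric: because T14 proportions are
renormalized, planted enrichment is partially absorbed by the pool
(a fold-3 hit among 88 hairpins with ~10% hits is observed at ≈ 3/1.08 ≈
2.8-fold) while depletion is slightly amplified. In the packaged 50-screen
recovery test this yields an overall planted-hit sensitivity just under
0.8 at per-pool FDR ≤ 0.01 — with depleted hairpins recovered at a
markedly higher rate than enriched ones — while the false-discovery
proportion stays near 0.01. Screens whose primary interest is enrichment
should expect this compositional power loss, which is a property of pooled
sequencing itself rather than of the estimator.
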