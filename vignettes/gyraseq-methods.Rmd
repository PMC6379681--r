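---
title: "Calling gyrase cleavage sites from strand-aware end coverage: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gyrase cleavage sites from strand-aware end coverage: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyraseq)
```

## The measurement model

Gyrase cleaves both strands of its bound G segment, producing a 4-bp
5'-overhang whose ends stay covalently bound to the enzyme. With a
single-strand sequencing protocol only the free chains are read, so the
fragment 3' ends of forward-aligned reads accumulate at the left wall `i`
of the gap and those of reverse-aligned reads at the right wall `i + 5`;
the overhang `[i+1, i+5)` is depleted of 3' ends on both strands. `gyraseq`
treats the per-position, per-orientation 3'-end count (N3E) as the primary
signal; 5'-end counts are carried along for diagnostics, since they vary
with sonication rather than cleavage.

All coordinates are 0-based half-open internally; WIG output is 1-based
fixedStep, matching genome-browser conventions. The chromosome is circular
by default; every operation that touches coordinates (end counting, window
extraction, smoothing) wraps at the origin, and a linear mode is available
for fragments or plasmids.

## Normalization and the paired-wall test

Calling uses a quartet of samples per replicate: treated IP, treated mock,
untreated IP, untreated mock. Three stages:

* **Library scaling.** Each profile is divided by its own fragment total and
  multiplied by the smallest total of the quartet. The smallest library is
  unchanged and the transform is idempotent. After this step all four
  library sizes are equal, so the count test below reduces to its
  equal-size form.
* **Mock normalization.** Replication in exponentially growing cells makes
  DNA near the origin about twice as abundant as near the terminus. The
  mock samples measure exactly this background, so each IP track is divided
  by its own mock track smoothed with a centered moving average (default
  200 kb, the scale over which the gradient is locally flat while
  individual cleavage peaks average out). Positions where the smoothed mock
  is at or below `epsilon` (default 1e-6; deletions, unmappable runs) are
  masked rather than divided. The window must stay well below the genome
  length: on the small genomes used in tests it is scaled down accordingly,
  since a window comparable to the genome circumference reduces the mock to
  its global mean and no longer tracks the gradient.
* **Audic–Claverie wall test.** At each unmasked `i`, the treated value is
  tested against the untreated-IP control at the same position, and likewise
  at `i + 5`; both upper tails must fall below `alpha` (default 0.0025 —
  the analysis threshold reported with the published site counts; the
  method description also mentions 0.05, and `alpha` is configurable). The
  test's posterior predictive is a negative binomial with size `x + 1` and
  success probability `n1/(n1+n2)`, so the tail is the regularized
  incomplete beta `I_{n2/(n1+n2)}(y, x+1)` — algebraically identical to
  summing the published formula, numerically stable, and defined for
  non-integer values. That last point matters because normalized signals
  are real-valued: the default `continuous` count policy evaluates the
  log-gamma extension directly, avoiding quantization artifacts at low
  coverage, while the `rounded` policy (round-half-even first) is provided
  for strict integer-fidelity checks. Whether the original analysis rounded
  is not documented; both routes are first-class and tested.

Calls are emitted at every passing `i` with walls `(i, i+5)`, canonical
position `p0 = i + 1`, and strength equal to the arithmetic mean of the two
wall heights (the source text says wall heights estimate trapping frequency
but does not choose mean versus sum; the mean keeps strengths on the
per-wall scale). Adjacent passing positions are not merged — the method is
single-nucleotide by construction, and merging policy in the original site
lists is undocumented. Replicate merging requires an exact `p0` match in at
least `min_replicate_support` (default 2) replicates, with no tolerance
window, again because the signature is single-nucleotide.

By default both walls are tested on the strand-summed N3E track; a
`split` mode tests the left wall on forward-strand 3' ends only and the
right wall on reverse-strand 3' ends only, which matches the peak-shape
physics more literally at the cost of halving per-wall counts (each mock
half gets half the smoothed background).

## The motif model

Windows of 130 bp (offsets −63..66 relative to `p0`) are extracted on the
genome forward strand only: the binding site is dyad-symmetric around the
cleavage axis, so no orientation step is applied. Column-wise base
frequencies give the PPM (N bases are dropped from the column denominator),
and the GC% track is the G+C row sum. The combined cross-drug motif takes
the `top_n` (default 732, the published per-condition depth) strongest
calls per condition, pools them with deduplication by genomic position
(which reproduces pooled counts below the naive sum, as with the published
1828-of-2196 set; by-sequence deduplication is an option), and overwrites
the overhang columns 0–3 — where the trapping drug intercalates and biases
base frequencies — with the genome composition.

The PWM is `log2((ppm + c) / (bg + c))` with pseudocount `c = 1e-4` and a
uniform 0.25 background by default (the convention of the standard motif
library named by the source; genome-composition background is a flag).
Scanning computes, per window start, the forward sum of matched cells and
the same quantity on the reverse complement of the window, reporting the
strand maximum; ambiguous bases contribute the background-weighted column
average. The per-sequence score is therefore invariant under
reverse-complementing the input, which the tests assert.

GC periodicity is estimated by least squares: for each candidate period on
a grid (8–14 bp, step 0.01) the model `a cos(2πx/P) + b sin(2πx/P) + c` is
fitted over the flank offsets (−63..−17 and 20..66; the central region is
excluded because cleavage chemistry, not wrapping, shapes it), and the
residual-minimizing `P` is returned. Significance is a permutation test:
the flank values are shuffled 1000 times, each shuffle refitted over the
whole grid, and the observed amplitude is compared with the 95th percentile
of the null's best amplitudes. A constant track is flagged undefined.

## Enrichment statistics

All count tests are exact, not asymptotic — site counts per feature class
are often small:

* interval enrichment: `k` of `n` sites in merged intervals covering
  fraction `p` of the genome, binomial tails plus the minimum-likelihood
  two-sided p-value;
* genome bin scan: 10 equal bins (the last absorbs the remainder), envelope
  from the exact `Binomial(n, 1/bins)` inverse CDF at quantiles
  0.0005/0.9995;
* Fisher 2×2 by full hypergeometric enumeration; conditional Poisson
  comparison of two counts via the binomial reduction given the total;
* transcription-unit association with strand-aware compartments — upstream,
  first and second body halves, downstream (upstream/downstream widths
  default to 5 kb, the only width the source prints, for rRNA-operon
  downstream regions; the body split at the midpoint is this package's
  choice) — with conflicts resolved to the nearest gene boundary and exact
  ties counted in both TUs but flagged;
* a sign-type binomial test on strength ratios of sites shared between two
  conditions, with exact ties dropped.

Welch t-tests and Pearson correlations used in score-set comparisons are
deliberately left to `stats`; they carry no method-specific content.

## What the simulator states, and what a green test means

The generator draws i.i.d. genome sequence from a stated composition
(default: E. coli-like, GC 50.8%), optionally redraws 130-bp windows from
planted PPMs, and produces quartets with:

* sonication fragment lengths uniform on 200–700 bp (the documented
  shearing range);
* signal fragments that choose a site by weight, an orientation 50/50, and
  pin their 3' end at the corresponding wall, leaving the overhang empty;
* background fragments placed under a piecewise-linear ori–ter copy-number
  gradient (default ratio 2→1, the replication-driven abundance difference);
* mocks as pure background, and a residual untreated-IP signal fraction of
  0.02 — weak trapping exists without poison but no magnitude is printed,
  so this value is a declared free parameter, not a fit.

This emulates the statistical structure the caller relies on — wall
pinning, the 4-bp void, the gradient, library-size imbalance — but not
sequence-dependent mappability, PCR duplication, base-calling error,
drug-specific central-sequence preferences, or overlapping sites. A green
end-to-end test therefore establishes that the pipeline inverts its own
generative model at realistic depths (recall/precision ≥ 0.95 at 1 Mb, 100
sites, 3 replicates, 5×10⁵ fragments per sample), not that it is robust to
every artifact of real libraries.

## Numerical choices and degenerate inputs

* Audic–Claverie tails via `pbeta`, never by summation; `ac_min_significant`
  resolves the strict-inequality boundary exactly (e.g. the smallest
  significant count over a zero control at equal library sizes and
  `alpha = 0.0025` is 9, since `2^-9 < 0.0025 ≤ 2^-8`).
* Even smoothing windows are widened by one to stay centered (shrunk at the
  genome-length boundary); circular smoothing preserves the mean exactly.
* Zero-total libraries, all-masked mocks, gaps other than 4 bp, empty call
  lists, all-zero contingency tables, and constant GC tracks are all
  explicit errors or flagged degenerate results, not silent numbers.
* Tie-breaks: consensus takes the first base on PPM ties; compartment ties
  at exactly equal boundary distance are double-counted and flagged.

## Known limitations

* Overlapping cleavage sites are reported separately per passing position;
  no peak-shape deconvolution is attempted.
* SAM export represents origin-spanning fragments with an unwrapped end
  coordinate past the reference length (re-wrapped on reading); use the TSV
  interchange format where strict SAM validity matters.
* The published fragment scores (37 / 14.3 / 2.5) cannot be reproduced here
  because the supplementary PPM and fragment sequences are not
  redistributable inside this package; the scanning arithmetic they
  exercise is verified against independent per-window oracles instead.
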