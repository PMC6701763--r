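---
title: "Methods: haplotype diversity and travelling outbreak waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity and travelling outbreak waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothwaves)
```

## The scientific problem

Outbreaking forest defoliators such as the gypsy moth (*Lymantria dispar*)
pose a puzzle when their outbreak fronts move across a landscape faster than
the adults can fly. Two kinds of evidence bear on it, and this package
implements the analysis chain for both:

* **Population genetics.** If local populations exchange migrants freely,
  mitochondrial (maternally inherited) variation should be uniform across the
  region: few haplotypes, low differentiation, and a star-like haplotype
  network. The package collapses aligned mtDNA COI sequences into haplotype
  tables and computes the standard diversity and neutrality statistics, a
  Hudson-type pairwise Fst matrix, and a statistical-parsimony (TCS-style)
  haplotype network.
* **Outbreak time series.** A travelling wave of outbreaks shows up as a
  consistent temporal lag between the annual defoliated-area series of
  neighbouring regions, on top of a common multi-year cycle. The package
  implements the log transform, three-point smoothing, stationarization,
  smoothed-periodogram cyclicity estimate, and lagged cross-correlation
  with t-based significance.

A packaged fixture carries the per-locality haplotype counts of a 2015-2016
West Siberian survey (220 specimens, 18 localities, 6 populations, 16
haplotypes of a 590-bp COI fragment); seeded generators supply
sequence-level and time-series data with known ground truth, so every stage
is testable offline.

## Diversity and neutrality statistics

All sequence statistics share a **site-deletion policy** (default: complete
deletion, dropping every alignment column with `N` or `-` in any sequence)
applied *before* haplotype collapsing, so the segregating-site count `S`,
mean pairwise differences `k`, per-site diversity `Pi = k / effective_length`
and the haplotype counts all refer to the same effective sites. This mirrors
the convention of the desktop tools that produce the survey's published
numbers.

* **Haplotype diversity** uses the unbiased estimator
  `Hd = (n/(n-1)) (1 - sum p_i^2)`. From the packaged survey counts
  (98, 74, 33, 2, 2 and eleven singletons; n = 220) it gives 0.669.
* **Tajima's D** is `(k - S/a1) / sqrt(e1 S + e2 S(S-1))` with the standard
  sample-size constants. No p-value is computed: the published analysis
  reports only a coarse beta-approximation bound from an external tool, and
  reimplementing that approximation would add a dependency on an unstated
  convention without adding information. `S = 0` yields `NA` with a classed
  warning rather than a number.
* **Fu's Fs** is `ln(S'/(1-S'))` where `S' = P(K >= h_obs)` under the Ewens
  sampling formula with `theta = k` (the diversity-based estimate; no
  alternative estimator is offered). Two independent numerical routes are
  provided and cross-checked to 1e-10: a log-space recurrence for unsigned
  Stirling numbers of the first kind, and an exact forward probability
  recurrence (the Chinese-restaurant-process dynamic program). An
  arbitrary-precision integer route is not available in this toolchain;
  exact integer Stirling numbers are representable in doubles only to
  n of about 18, and the test suite uses them as a third oracle there.
  Boundary tail probabilities (0 or 1) return signed infinity with a
  `boundary` flag.

## Pairwise Fst

Fst between two populations is Hudson-type `1 - Hw/Hb`: `Hw` is the
unweighted mean of the two within-population mean pairwise differences, `Hb`
the mean between-population pairwise difference, all on sites retained after
applying the deletion policy to the combined pair. The within-population
means are **plug-in** (with-replacement over haplotype frequencies, i.e.
divided by `n^2` rather than `n(n-1)`). The choice is deliberate: it makes
Fst *exactly* zero for two samples with identical haplotype composition — a
clean algebraic contract — at the price of a small positive finite-sample
offset, approximately `(1/nA + 1/nB)/2`, under panmixia. For that reason the
panmixia check offered by the package is the label-permutation test
(`fst_permutation_test()`), which is calibrated regardless of the offset;
raw near-zero thresholds on small samples are not meaningful under either
convention. Negative estimates are reported as computed, never truncated.
The estimator variant is recorded in the `method` field of every
`fst_matrix`.

## The statistical-parsimony network

The connection limit is the largest number of mutational steps `j` whose
*parsimony probability* still reaches `alpha` (default 0.95). The package's
probability model is explicit: sites mutate independently with Poisson
counts and a Jukes-Cantor base chain; the per-site rate is set by matching
the expected number of visibly differing sites to `j`; the parsimony
probability is then `P(true mutations = j | j sites differ)` — no differing
site hides a multiple hit, no identical site hides a reversion. Beyond the
Jukes-Cantor saturation ceiling (`j >= 3/4 * length`) the probability is
defined as 0. For the 590-bp COI fragment at `alpha = 0.95` the limit is
**7 steps**, in the range TCS-family tools report for fragments of this
length; the exact published estimator is ambiguous in the secondary
literature, so this package treats its own formulation as the definition and
freezes the 590-bp value as a regression constant in the tests. Note the
limit approaches "everything connectable" only in the true `alpha -> 0`
limit; for any fixed tiny `alpha` the probability underflows first.

Network construction joins haplotype pairs in ascending-distance order (ties:
higher combined frequency first, then table order), inserting abstract
inferred intermediates so every edge spans exactly one step. A pair already
connected by a path no longer than its observed distance is skipped, which
retains alternative equal-length connections as reticulations. Inferred
intermediates are *not* reconstructed base by base — the published use of
such networks is descriptive (star topology, one-to-two-step separation of
the dominant haplotypes), not nested-clade analysis, and their displayed
content is node frequencies and step counts only.

## The travelling-wave chain

The preprocessing order is `log(x+1)` → Hunn filter → stationarization,
matching the narrative order of the source procedure (the source does not
state filter/stationarization order explicitly).

* **`log(x+1)`** maps zero-defoliation years to exactly 0.
* **Hunn filter** `0.24 x(i-1) + 0.52 x(i) + 0.24 x(i+1)` on interior
  points; endpoints are copied unfiltered. Renormalizing truncated weights
  at the ends was rejected so the printed interior formula is applied
  exactly; the filter suppresses components above 0.25 cycles/year.
* **Stationarization** removes a least-squares linear trend, then centers
  and scales to unit variance (first-differencing offered as an option).
  A detrended-constant series becomes all zeros with a `constant` flag.
* **Spectral density** is the periodogram on a zero-padded grid (default
  256 points, so a 25-year series can express peaks such as 0.045
  cycles/year that are not Fourier frequencies of n = 25), smoothed with a
  modified Daniell window of width 3 (weights 1/4, 1/2, 1/4). The flat
  1/3-window was rejected because it turns a single-bin spike into a
  three-bin tie and biases the argmax to the lower frequency. The peak
  search excludes frequency 0 and everything above 0.25 cycles/year (the
  band the filter removes); the cycle length is `L = 1/f_max`.
* **Cross-correlation** at lag `k` correlates `x(t-k)` with `y(t)` over the
  overlap; best lag `+d` means the wave arrives in `y` d years *after* `x`.
  Published tables of this kind mix sign conventions, so the convention is
  fixed and documented on the function. Significance is
  `t = r sqrt(n_overlap - 2) / sqrt(1 - r^2)` against the two-sided 5%
  critical value; the exact criterion behind published stars is unstated,
  so this closed form is this package's convention. One caution the package
  enforces only through documentation: for a periodic signal, lags are
  identifiable only within half a period (lag +3 of an 11-year cycle is
  indistinguishable from lag -8), so `max_lag` should be kept below
  `period/2` when cycles dominate.

## What the generators state, and what a green test establishes

`simulate_haplotypes()` plants a star genealogy under the infinite-sites
approximation: a random founder, each variant a configured number of
mutational steps away at distinct sites, no back-mutation. Defaults are the
surveyed world: 220 samples, 590 bp, haplotype spectrum
{98 at 0 steps, 74 at 1, 33 at 2, two doubletons, eleven singletons at 1-2
steps}, six demes with the survey's sample sizes (50, 21, 58, 15, 64, 12).
Panmixia is a random shuffle of one pool across demes; isolation resamples
deme haplotype frequencies by Wright-Fisher drift (deme size = effective
size) for a configured number of generations. The planted `S`, spectrum and
`Hd` are exact oracles. What the generator does **not** emulate: recurrent
mutation at a site, recombination (absent in mtDNA anyway), within-deme
genealogical structure, or a neutral-equilibrium genealogy — so a green test
shows the statistics and network recover a planted expansion-like truth, not
that they would date or parameterize a real demographic history.

`simulate_outbreaks()` plants a raised-cosine pulse train (period default 11
years) with a fixed per-region delay (default +1 year/region), multiplicative
lognormal noise (sigma 0.3) and a reporting floor (2500 ha, 5% of the 50 000
ha peak amplitude) subtracted before clamping at zero, so troughs are exactly
zero as in real defoliation records. The floor was raised from an initial
500 ha when testing showed the raised-cosine troughs (~1000 ha) never reached
zero — the generator's zero-inflation is part of its stated world. Real
records additionally contain trend, observation gaps and non-stationary
amplitude that the generator does not emulate.

## Numerical choices and degenerate inputs

* Undefined statistics signal: classed warnings + `NA` (Tajima's D at
  `S = 0`, Fu's Fs at `k <= 0`), classed errors for unusable inputs (empty
  alignments, unequal lengths, unmapped ids, constant series for spectra),
  and flags for boundary values (infinite Fs, constant stationarized
  series, zero-variance cross-correlation overlaps).
* Haplotype naming is `H1, H2, ...` by descending total count, ties by
  first occurrence in input order — deterministic, and invariant under
  record shuffling when counts are distinct. A `names` mapping can impose a
  published labelling (the packaged fixture keeps its Roman numerals, which
  encode network adjacency the counts alone cannot).
* Counts-only haplotype tables (like the packaged fixture, whose source
  prints no sequences) support only count-based statistics; every
  sequence-requiring operation rejects them with a classed error rather
  than guessing.
* Ties in the cross-correlation argmax break toward smaller lag magnitude,
  then the negative lag.
* The Ewens distribution vector sums to 1 within 1e-12 by construction of
  the probability recurrence; the Stirling route normalizes through the
  log rising factorial.

## Known limitations

* The parsimony probability is this package's explicit model, not a
  byte-level reimplementation of any particular network program; loop
  handling in reticulate cases may differ from published figures drawn with
  other tools.
* Tajima's D and Fu's Fs p-values are out of scope (documented above).
* Spectral peak *heights* depend on normalization conventions that differ
  across software; only peak locations (and hence periods) are treated as
  comparable quantities.
* The pairwise Fst of very small samples (a dozen sequences) is dominated
  by sampling noise under any estimator convention; use the permutation
  test, not raw thresholds.
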