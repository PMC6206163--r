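---
title: "Predicting enhancers from the DNA random walk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancers from the DNA random walk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerwalk)
```

## The problem and the representation

Enhancers are distal, orientation-flexible regulatory elements whose
sequence code — if a general one exists — is weak and poorly conserved.
Classifiers built on cell-type-specific assays (histone marks, TFBS,
chromatin accessibility) inherit that specificity; a sequence-only
classifier does not. This package implements a sequence-only approach:
a DNA sequence is mapped to a one-dimensional *purine/pyrimidine random
walk*, and classification features are drawn from both sequence
composition (k-mers) and the dynamics of the walk.

The walk assigns each base a step: pyrimidines (C, T) step $+1$,
purines (A, G) step $-1$; the walk is the running sum, starting at
`walk[1] = steps[1]` with no leading zero. The final displacement is
therefore $(\#C + \#T) - (\#A + \#G)$. Long-range correlations in
non-coding DNA show up as persistence in this walk, which the nonlinear
descriptors below quantify. (The classic description of the rule in the
literature garbles one sign in passing; the operative convention —
pyrimidine $+1$, purine $-1$ — is the only internally consistent one
and is fixed throughout this package, so all oracles and expected
values refer to it.)

## The feature vector

Each sequence yields exactly **5468 features**:

* **5460 k-mer counts** — raw overlapping occurrence counts of every
  word of length 1 to 6 ($\sum_{k=1}^{6} 4^k = 5460$), ordered by
  ascending $k$ and alphabetically within $k$. Counts are raw rather
  than length-normalized: the reference group statistics for words
  such as `GGCAG` (class means near 2.9 vs 2.0) and `TGTT` (10.8 vs
  9.5) on sequences capped at 1500 bp are count-scale numbers, and on
  a fixed-length design the two differ only by a constant per-k factor.
  Counting is strand-specific; no canonical (strand-collapsed) merging
  is done.
* **8 walk descriptors**, in fixed order `sd`, `dfa`, `ac`, `ac_200`,
  `ac_300`, `sampen`, `hurst`, `rvntsl`:
  * `sd` — sample standard deviation of the walk;
  * `dfa` — detrended fluctuation analysis exponent of the walk;
  * `ac`, `ac_200`, `ac_300` — sample autocorrelation of the walk at
    lags 100, 200, 300;
  * `sampen` — sample entropy of the walk;
  * `hurst` — rescaled-range Hurst exponent of the *step* series;
  * `rvntsl` — number of distinct walk values over the walk length.

Which series each estimator sees matters. DFA is applied to the walk
itself (the pipeline's natural object); since the walk is already the
integral of the steps, an uncorrelated sequence gives
$\alpha \approx 1.5$, matching the $\approx 1.57$–$1.60$ reported for
real enhancer/background data. R/S analysis, by contrast, takes the
step (increment) series — the classical input for which uncorrelated
data give $K = 0.5$. Mixing these up shifts both exponents by 1 and is
the most common implementation error for this family of features.

Extended statistics (max, min, skewness, kurtosis, interquartile
range, zero/mean crossing rates, spectral entropy) are available via
`extended_stats()` for exploratory comparison, but they are *not* part
of the canonical vector: $5460 + 8 = 5468$ fixes the membership. The
largest Lyapunov exponent (`lyapunov_max()`) is likewise provided as a
standalone estimator of walk chaoticity but excluded from the
canonical 8 for the same dimensional reason.

## Estimator details and numerical choices

**Hurst (R/S).** Chunk sizes are powers of two from 8 up to $L/2$
(at least four sizes required, so $L \ge 128$). Per chunk the range of
the mean-adjusted cumulative sum is divided by the chunk SD; zero-SD
chunks are skipped; the per-size means are fitted in log–log space.
The naive OLS slope of this curve is known to be biased upward at
these series lengths (small chunks have inflated expected R/S), giving
$\approx 0.57$ on 1500-step Brownian input. We therefore debias with
the standard Anis–Lloyd/Peters expected-R/S curve for uncorrelated
series: $K = 1/2 + (b_{\text{emp}} - b_{\text{iid}})$, where
$b_{\text{iid}}$ is the slope of the theoretical expectation over the
same chunk grid. With the correction, simulation gives mean
$K = 0.49$ on Brownian $\pm 1$ walks of length 1500 and recovers
fractional Gaussian noise with $H \in \{0.3, 0.5, 0.8\}$ to within
$\pm 0.1$ at length 4096 (both checked in the test suite).

**DFA.** Order-1 detrending on ~12 geometrically spaced window sizes
in $[4, L/4]$; the profile is the cumulative sum of the mean-centered
input; per window size, the RMS residual around the per-window
polynomial fit is the fluctuation; the exponent is the log–log OLS
slope. Window sizes with exactly zero fluctuation (e.g. a perfect
linear ramp under order-1 detrending) are dropped with a warning, and
fewer than four usable sizes is an error. Grid and order are exposed
as arguments.

**Sample entropy.** $\mathrm{SampEn}(m, r) = -\ln(A/B)$ with template
length $m = 2$ and tolerance $r = 0.2 \times$ series SD by default —
the field-standard choice; the source method does not state its
values, so both are explicit arguments. Self-matches are excluded;
$A = 0$ or $B = 0$ yields `NA` (an undefined-entropy sentinel, never a
fake 0). The $O(N^2)$ template count is compiled (Rcpp) and verified
against an exhaustive R oracle and `pracma::sample_entropy`.

**Lyapunov.** Rosenstein-style: delay embedding (default
`emb_dim = 10`; `lag` defaults to the first autocorrelation minimum,
capped so the embedding retains at least 40 points — DNA walks have
slowly decaying autocorrelation and would otherwise exhaust the
series), nearest Euclidean neighbour with a Theiler exclusion of
`min_tsep = lag`, then the slope of the mean log-divergence curve over
its initial `1..min(20, len)` steps. All parameters are arguments; the
logistic-map sanity check in the tests uses `emb_dim = 2, lag = 1`,
appropriate for a one-dimensional map, and recovers
$\lambda = \ln 2$ to three decimals.

**rvntsl.** A $\pm 1$-step walk visits every integer level between
its minimum and maximum, so `rvntsl` is (range + 1)/length. For
*uncorrelated* walks of length 1500 its expectation is
$\approx \sqrt{8L/\pi}/L \approx 0.04$; the values near 0.07–0.10
observed on real enhancer/background data reflect shorter sequences
(428–1500 bp) and the persistence of genomic composition, not the
uncorrelated baseline. The tests therefore assert the formula exactly
and the magnitude band only on length-mixed simulations.

**Length policy.** Reference positives range from 428 to 8061 bp;
sequences are truncated to 1500 bp keeping the **5' prefix** (the
source method says only "truncated"; a deterministic, orientation-
stable anchor was chosen and is flagged here as a design decision).
Ambiguous bases are stripped when they make up at most 5% of the
sequence, otherwise the record is rejected — reference elements are
nearly N-free, and stripping preserves walk continuity better than
placeholder steps. Below 302 bases the lag-300 autocorrelation is
undefined and the record is rejected; below 400 a warning is issued.

## Dataset assembly

**Null sequences.** Negatives are genomic windows matched to each
positive in exact length and in GC content within a tolerance
(default $\pm 0.02$), sampled uniformly over the genome by rejection,
never overlapping a positive interval, and skipped with a warning when
the budget (default 1000 tries) is exhausted. Repeat-content matching
— part of the full published recipe via gkmSVM's null generator — is
deliberately out of the core: it requires an external repeat
annotation. GC + length matching with non-overlap is the implemented
contract; the interface accepts arbitrary positive BED input, so a
repeat-aware pipeline can pre-filter.

**Synthetic data.** `simulate_labeled_set()` is the package's
test-bed generator and defines its study conditions: positives are
i.i.d. bases at GC 0.55 with a Poisson(5) number of planted `GGCAG`
copies; negatives are i.i.d. bases at GC 0.40; sequence length
1500 bp; the class imbalance mirrors the reference regime of
1,798 : 13,790 $\approx$ 1 : 7.7 (the pipeline condition uses
200 : 1540). This emulates the *separability structure* of the real
problem — composition shift plus motif enrichment under heavy
imbalance — but not its difficulty: real enhancers are not i.i.d.
sequences, their GC shift is far subtler, and no single motif carries
the signal. A high held-out AUC on this generator validates the
plumbing (features carry class signal end to end; no leakage;
imbalance handled), not genomic performance. The headline published
numbers (AUC 0.91 on held-out reference enhancers, 0.86–0.89 on
histone-mark validation sets) require the VISTA/ENCODE downloads and
are out of desk-scale scope.

**Group comparison.** `compare_groups()` reports per-feature class
means/SDs with an unpaired two-tailed *Welch* t-test — the unequal-
variance form, chosen because the class sizes and variances differ
markedly in this design.

## Classifiers

Both ensembles operate on PCA scores. PCA is fit on the **training
partition only** (the source describes PCA preprocessing without
stating the partitioning; refitting inside the fold avoids leakage and
is the package's choice, applied in `split`-based training and per
fold in `cross_validate()`). Features are centered but **not**
standardized by default: on raw count features the leading component
dominates (the reference run reports 82.5% for the first component),
which is characteristic of unstandardized counts; a `standardize` flag
is available. Components are kept until cumulative explained variance
reaches 95% — the stated rule; the same source also says "3 components
were kept", which matches 95% only as 82.5 + 8.7 + 4.3 = 95.5, so the
rule, not the count, is implemented.

**Bagged trees** (default): 30 full-depth `rpart` trees (Gini, no
pruning, `cp = 0`), each on a bootstrap resample of size $n$ drawn
with replacement; the positive score is the fraction of trees voting
positive, thresholded at 0.5.

**RUSBoost**: up to 30 AdaBoost.M1 rounds with learning rate 0.1
multiplying the learner weights. Each round keeps *all* minority
samples plus a uniform random majority subset of exactly equal size
(exact 1 : 1 balance, recorded per round in `$rounds`), fits a
weighted full-depth tree on the selected samples, and updates weights
on the full training set; a round with weighted error $\ge 0.5$ halts
boosting with the remaining learners unused. Prediction is the
normalized weighted vote.

**Evaluation.** The ROC sweeps every distinct score as a threshold,
from (0, 0) to (1, 1); AUC is the trapezoidal area, which equals the
Mann–Whitney concordance probability with ties counted one half — the
suite asserts this equivalence to $10^{-12}$ against an exhaustive
pair-count oracle. Accuracy is reported at the 0.5 threshold.

## Degenerate inputs and missing-value policy

Homopolymeric (e.g. poly-C) sequences produce monotone walks with
zero-variance steps: R/S is degenerate and DFA detrends the ramp
exactly, so feature extraction errors. Under `strict = FALSE`
(training assembly, prediction) such sequences are dropped or emitted
as `no-call` rows; `strict = TRUE` raises. An undefined sample entropy
is an `NA` sentinel, never zero.

## Problem sizes used in testing

The suite checks Brownian Hurst calibration with 200 replicates of
length 1500; fGn recovery with 100 replicates of length 4096 per
$H \in \{0.3, 0.5, 0.8\}$; DFA calibration with 100 white-noise series
of length 2000 and 60 walks of length 1500; all brute-force oracle
comparisons on fixtures of length $\le 500$; and the full pipeline at
the 200/1540 $\times$ 1500 bp study condition with a 75/25 stratified
split. These sizes give sub-0.01 Monte-Carlo standard errors on the
calibration means while keeping the suite routinely runnable.

## Known limitations

* The generator's i.i.d.-base model lacks the long-range correlations
  the nonlinear features were designed for; those features are
  validated against analytic anchors (Brownian 0.5, fGn, white noise,
  logistic map) rather than against the generator.
* Null generation matches GC and length but not repeat content.
* Truncation is 5'-anchored by decision, not by evidence.
* The weak/strong enhancer distinction in the reference positive set
  (898 of 1798 elements show non-reproducible activity) is not
  modelled; a loader for real data should treat all validated elements
  as positive, as the reference training set's arithmetic implies.
* `rpart`'s internal split tie-breaking is accepted as-is; models are
  nonetheless exactly reproducible under a seed.
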