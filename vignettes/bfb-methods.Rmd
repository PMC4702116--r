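---
title: "Modelling the evolution space of breakage-fusion-bridge cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution space of breakage-fusion-bridge cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfbspace)
```

## The process and its discrete state space

A breakage-fusion-bridge (BFB) cycle breaks a chromosome arm, replicates it,
fuses the two broken sister ends into a palindrome, and breaks the resulting
dicentric bridge at the next anaphase.  Iterated over cell divisions this
produces the localized, highly amplified regions ("amplicons") seen in many
cancer genomes, bounded by fold-back inversion junctions.

`bfbspace` models the product of a cascade as a *folded structure*: the
linear BFB product laid against the reference so that identical reference
positions align vertically.  Walking the structure end to end and reporting
the label of each fold yields a palindromic *fold word*; recording, for each
cycle, the signed index of the segment the new break lands on (counted from
just after the structure midpoint) yields the *fold sequence*
`r = (r_1, ..., r_n)`.  The two encodings are interconvertible
(`word_from_sequence()`, `sequence_from_word()`), and a word is viable
exactly when the reversal algorithm (`reverse_word()`) unwinds it; the
chronological order of the surviving folds is then the order in which their
labels first appear in the word.

Three conventions pin the representation down, and everything else in the
package inherits them:

* **`r_1 = 1`.**  The first cycle always creates the single initial fold.
* **Duplicate-left.**  A palindromic product cannot distinguish "break at
  distance `l` from one end, keep the upper part" from the mirrored choice,
  so the algebra always duplicates the top end.  The one genuine binary
  choice — the direction of the *first* duplication, before any palindrome
  exists — is not part of the algebra; it enters the stochastic layer as a
  probability factor of 1/2 (see below).
* **Prefix length `b_i = s_i - 1`.**  The word recursion keeps the first
  `b_i` symbols of the previous word around the new label.  The structure
  after cycle `i` has `2 s_i` segments and hence `2 s_i - 1` folds, of which
  `2 b_i + 1` are accounted for by the recursion; `b_i = s_i - 1` is the
  unique consistent choice.

Cycles with `r_i <= 0` delete earlier folds; `reduce_sequence()` absorbs
them (rightmost first — the operation is confluent, which the test suite
checks by comparing against leftmost-first absorption) into the all-positive
*reduced* sequence describing the surviving structure.

## Orders, poset trees, and counting evolutions

A fold sequence fixes which segment each break lands on but not the relative
reference positions of the folds: those satisfy a partial order (each fold
lies strictly between the positions of the two folds bounding its segment).
Distinct linear extensions of that poset give distinct structures and, in
general, distinct copy-number profiles.  The package represents the poset as
a *2-d tree* (`build_poset_tree()`): node `i` attaches to the two bounding
folds by a *major* edge (larger label) and a *minor* edge (smaller label),
and carries a *plain*/*flipped* flag according to whether the kept word
prefix ends with the smaller or the larger bounding label.  This flag
convention is the one reading of the word patterns that reproduces both the
worked flag assignments and the chaining rule (a major child of a plain node
inherits its minor parent; of a flipped node, its major parent), which the
suite audits on every constructed tree.

Dropping minor edges leaves the *order tree*; the number of linear
extensions is the subtree-size product formula
`Phi(T) = n! / prod_b m_b` (`count_orders()`), which the tests verify
against brute-force filtering of all position permutations.
`enumerate_orders()` generates the extensions themselves by the standard
minimal-element recursion; eager enumeration (a plain rank matrix) is used
rather than a lazy generator because the largest enumerated census here
(32,768 extensions at six cycles) is small in memory terms.

The census (`count_sequences()`, `count_evolutions()`, `profile_census()`)
rests on two results: the cumulative-sum recursions for sequence counts, and
the closed forms `2^(n(n-1)/2)` (all evolutions) and
`prod_{i=1}^{n-1}(2^i - 1)` (evolutions that keep every fold; the fraction
tends to `prod(1 - 2^-i) ~ 0.2888`).  The closed forms are proved by the
*subtree switching* operation (`subtree_switch()`): introducing a new first
fold corresponds to choosing a root-containing subtree `s` of the order
tree, switching flipped edges inside `s` and plain edges adjacent to it, and
prepending a root; summed over all `s` the extension counts double `n`
times.  The suite checks `sum_s Phi(T_s) = 2^n Phi(T)` for every reduced
sequence with up to five cycles, including the binomial refinement by
top-branch size.

Counts are exact double-precision integers.  R ships no big-integer type in
the base distribution, so `count_orders()` refuses factorials beyond 18 and
the count functions guard the `2^53` exactness boundary; every census the
package enumerates is orders of magnitude below it.

## The stochastic layer

With breaks uniform along the structure, the unfolded length is the
multiplicative process `(L_n | L_{n-1}) ~ U(0, 2 L_{n-1}]`.  The n-cycle
marginal used by `length_pdf()` is
`log^(n-1)(2^n L / l) / (2^n (n-1)! L)` on `(0, 2^n L]`: with `2^n` inside
the logarithm the density integrates to one, reduces to the uniform law at
`n = 1`, has mean `L` and standard deviation `L sqrt((4/3)^n - 1)`, and
matches simulation; a variant with `2^(n+1)` in the logarithm is kept behind
the `printed` flag for comparison but is not a probability density.

A fold survives the cascade exactly when its length is below every later
length (`surviving_folds()`); the minimum length sets the amplicon size
(`L_amp = L_min / 2`).  The order statistics are built from the nested
logarithmic weights `W_k` (`wk()`), evaluated in closed form via the
coefficient recursion `a^k = B_k a^(k-1)` and validated against nested
adaptive quadrature.  The density that cycle `k` of `N` holds the minimum
with value `x` is implemented as

```
M_{k,N}(x, L) = W_{k-1}(x, L) * (1 - sum_{i=1}^{N-k} 2^{-i} W_{i-1}(x, x)) / (2^k L)
```

The index placement (`W_{k-1}`, `W_{i-1}`) is forced by three facts the
suite tests: at `k = N = 1` the minimum of a single cycle must be uniform on
`(0, 2L]`; the densities must sum and integrate to one; and the conditioned
argmin frequencies of simulated cascades must match.  The deleted-count
posterior uses the same weights with indices from zero, which is consistent
with this placement.  Derived quantities (`argmin_posterior()`,
`min_length_pdf()`, `bfb_count_posterior()`, `amplicon_size_pdf()`,
`deleted_count_posterior()`) follow directly; the posterior over the cycle
count takes an improper uniform prior over `N`.

Numerics: the infinite sums truncate at a relative tail below `1e-10`.  The
`a^k` recursion is an alternating sum whose cancellation exhausts double
precision near `k ~ 120-150`; both posterior loops detect the first
spurious increase in an otherwise decreasing tail and truncate there, which
costs mass far below the tail tolerance at any practically relevant input.
`min_length_pdf()` computes all `W_0..W_{N-1}` in one incremental pass, so
posterior evaluation is quadratic rather than quartic in `N`.

Fold-sequence likelihoods multiply conditional step probabilities: the
chance of the next element `r_n` is the expected ratio of the target segment
width to the structure length under the poset-uniform position density
(`step_probability()`).  Prefixes of up to two cycles use closed forms (the
two-cycle step distribution is `log(2)/2` for the outer segments and
`(1 - log 2)/2` for the inner ones); longer prefixes use vectorised
Monte-Carlo integration with the sample count and seed under caller control.
`path_probability()` multiplies the steps and, by default, the 1/2
first-cycle direction factor — the unique convention under which path
probabilities of full sequences sum to the per-step normalisation and match
the frequencies of simulated cascades (conditioned on the duplicate-left
first step, frequencies double, which the suite also checks).

## Inference from amplicon read depth

`rank_evolutions()` implements the likelihood ranking of candidate
evolutions for a segmented amplicon with all breakpoints known (segmentation
itself is out of scope; fold positions come from discordant read pairs).
The data model: mean depth `z_i` of region `i` is Gaussian with mean
`alpha + beta * c_i` and variance `sigma_i^2 / m_i`, with `sigma_i^2` the
observed bin-depth variance held fixed.  For each candidate (reduced
sequence, rank order) the profile `c` is computed by strand coverage, the
likelihood is maximised over `(alpha, beta)` by weighted least squares
(weights `m_i / sigma_i^2`, slope constrained non-negative; the closed form
is verified against a dense grid search), and the fold-position
log-likelihood (the poset-uniform product) is added.

Design choices that were genuinely open:

* **Orientation.**  The structure ends run through the flank with the higher
  signal toward the centromere; the opposite flank lies beyond the outermost
  fold and is excluded from the structure.  Equal flanks raise an error
  rather than guessing.
* **Baseline.**  By default the excluded flank is kept in the fit with BFB
  copy number 0, so the intercept absorbs non-BFB signal (the other allele,
  normal contamination).  `baseline = "exclude"` drops it entirely; on the
  packaged example both choices select the same top profile.
* **Position coordinates.**  Model positions are distances from the
  structure ends, rescaled so the outermost breakpoint is 1, with the chord
  length `L` set by the observed window.  Every candidate for a given
  amplicon has the same number of width factors, so rankings are invariant
  to the unit; absolute position log-likelihoods are therefore
  unit-dependent and only differences are meaningful.
* **Ties.**  Candidates are sorted by total log-likelihood, then
  lexicographically by fold sequence.  Candidates sharing a profile share
  the depth term exactly (the fit is cached per profile), so profile
  degeneracy is visible as exact ties — on the packaged PD4875 chr11 example
  the top two candidates share the profile `[16,12,14,6,2]` and are
  separated only by the much weaker position term.

The packaged PD4875 fixture carries the published per-region depth
summaries; its genomic coordinates are synthetic stand-ins (1 kb bins,
region width equal to the bin count in kb) because bin-resolution
coordinates are not available, and the fixture documentation says so.  All
acceptance-grade claims about the example (candidate count, top profile,
tie structure) are coordinate-free.

## What the synthetic generator emulates

`simulate_cascade()` draws each break uniformly along the current structure
and derives the fold-sequence element, fold position, and halved-length
bookkeeping from the hit segment, so every realization is internally
consistent by construction (the suite re-checks conservation, survivor
rules, and profile/coverage agreement on each draw).
`simulate_depth()` emulates the read-depth signal: constant-mean bins within
regions of constant copy number, mean `alpha + beta * c`, with variance
`dispersion * mean` via a negative-binomial draw — the simplest mean-variance
law matching the overdispersion (variance well above the mean) seen in the
real summaries.  A simple inflation was chosen over Poisson mixtures
deliberately: it has one interpretable parameter and is sufficient for
parameter-recovery testing.

The generator does *not* emulate mapability variation along the genome, GC
bias, subclonal mixtures, normal contamination beyond a constant intercept,
or uncertain/missing breakpoints.  Passing recovery tests therefore show
that the ranking recovers the generating profile under the stated model
(over 50 synthetic amplicons with 4-5 folds at fixture-like signal levels,
the true profile ranks first in at least 90% of runs and in the top three
always); they do not show robustness to the unmodelled effects, and real
amplicons with marginal signal or missing folds are outside the method's
stated scope.

## Problem sizes and runtime choices

Exhaustive enumeration is bounded at 8 cycles (reduced), 7 (full), and the
profile census at 6 — the largest sizes for which the package's own tests
can cross-check every count by enumeration in seconds; beyond that the
recursions and closed forms still provide counts.  Monte-Carlo defaults are
`10^5` samples per step in interactive use and `10^6` in the reproduction
script; standard errors are propagated and attached to the estimates.  The
test suite uses `2x10^4`-`2x10^5` draws per stochastic check, sized so each
check resolves its target at three standard errors.

## Known limitations

* Single dominant clone, uniform breakage, and exhaustive breakpoint
  detection are assumed throughout; the likelihood pieces degrade gracefully
  (the position term is explicitly weak) but are not robust to violations.
* Candidate enumeration is exponential: amplicons with more than six folds
  need external pre-filtering of sequences or a sampling strategy.
* Exact counting is limited by double precision; counts near or above
  `2^53` are refused rather than silently rounded.
* The position likelihood conditions only on the fold sequence, not on later
  survival of the folds; this matches the generative model used for the
  simulator but means deleted-then-reborn histories share position terms
  with their reduced forms.
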