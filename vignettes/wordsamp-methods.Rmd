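---
title: "Sampling schemes by the numbers: models and methods in wordsamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling schemes by the numbers: models and methods in wordsamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordsamp)
```

`wordsamp` computes exact sensitivity and specificity properties of
sequence-sampling schemes.  This vignette explains the underlying models,
the numerical choices, and what the package's tests do and do not establish.

## The random-sequence model

Everything exact in this package is computed under one model: a sequence of
independent, equally probable letters, and (for related pairs) evolution by
independent per-position substitutions — each position conserved with
probability `q`, otherwise replaced by a uniformly chosen different letter.
There are no indels in the model.

For word-based schemes we default to the two-letter purine/pyrimidine
alphabet, `a`/`g` → `r`, `c`/`t`/`u` → `y`.  Real DNA motivates this choice:
r/y frequencies are close to 50:50 even where base composition is skewed, the
elevated vertebrate CpG substitution rate respects r/y classes, and the 2ᵏ
lookup table lets `k` be twice as long for the same memory.  Characters that
do not encode (ambiguity codes, gaps) are masked, and any sampling window
overlapping a masked position is skipped — masking never errors and never
shifts coordinates.

## Run-hitting probabilities

A run of `x` overlapping matches between related sequences is hit exactly
when some word of the set occurs among `x` consecutive start positions,
i.e. in a window of `x + k − 1` letters.  `run_hit_profile()` computes this
by the standard automaton-style dynamic programming over all `|A|^k`
length-`k` suffix states, counting sequences that avoid the set and
subtracting.  Three numerical points:

* **Arithmetic.**  The DP carries integer counts in doubles and divides once
  at the end.  Counts are bounded by `|A|^(x+k−1)`, so every value with
  `x + k − 1 ≤ 53` (binary alphabet) is *exactly* representable: equalities
  like H(2) = 1/2 for `{ry}` and the strict dominance comparisons in the
  tests are exact, not approximate.  Beyond 53 the result degrades gracefully
  to double precision.
* **Guards.**  The suffix state space is `|A|^k` (capped at 2²⁴ entries) and
  the window length at `u + k − 1 ≤ 64` by default; both are arguments, not
  constants.
* **Oracle.**  `brute_force_hit_count()` enumerates all `|A|^L` sequences
  directly.  The test suite asserts bit-exact agreement with the DP for
  *every* nonempty binary word set with `k ≤ 3` and `x ≤ 6`, which is the
  strongest kind of check a dynamic programming can get.

The sparsity bound `H(x) ≤ min(x/s, 1)` (with `s = |A|^k/n`) is the yardstick
throughout; profiles carry an `upper_bound` and `deficit` column and plots
show the deficit by default, since well-designed schemes differ only there.

## Objectives and optimization

`objective(u, decay)` scores a profile by `Σ d^(1−x) H(x) / Σ d^(1−x)` for
`x = 1..u`.  The plain average (`d = 1`) treats all run sizes equally;
`d > 1` weights short runs (what matters for distant homology), `d < 1` long
runs (near-identical sequences).  Scores are normalized by default so they
are comparable across `u`; the argmax is unaffected.

`enumerate_exact_optima()` scores every `choose(|A|^k, n)` set and returns
*all* maximizers (lexicographically ordered, ties at 10⁻¹² resolution).
Optima are reported in the orientation found; `reverse_to_minimize_yr()` is
deliberately left to the caller, because reversal maps optima onto each other
and collapsing them would hide genuinely distinct solutions.

`simulated_annealing_search()` handles larger problems.  Design choices,
each of which was genuinely open:

* **Neighbourhood:** replace one uniformly chosen member with one uniformly
  chosen non-member — the smallest move that preserves `n` (and hence the
  structural density `H(1) = n/2^k`).
* **Schedule:** Metropolis acceptance `exp(Δ/T)` with geometric cooling
  (default `T₀ = 0.05`, factor 0.995, 2000 steps, 4 restarts).  Any schedule
  satisfying the contracts — determinism given the seed, final score never
  below the initial random set's — is acceptable; these defaults solve every
  small benchmark in the suite and are all overridable.
* **Caching:** objective values are memoised on the sorted word codes.  The
  DP dominates the cost, and on small state spaces most proposals are
  revisits, so caching changes the complexity class of a run.
* **Reproducibility:** the RNG is scoped with `withr::with_seed`, so a search
  neither consumes nor perturbs the caller's RNG state.

A weighted objective demonstrably shapes structure at desk scale: at
`k = 4, n = 2, u = 9`, the `d = 4` optimum has guaranteed minimum separation
3 (a polar set at the sparsity-8 optimum spacing) while the `d = 1/8`
optimum has minimum separation 2, and their profiles cross — the test suite
freezes exactly this configuration.  Larger showcases (128-word sets) are
search problems, not verification problems, and are out of scope for tests.

## Separations: polar and universal structure

`min_separation()` is a direct suffix/prefix overlap scan: the smallest
shift at which two words of the set can co-occur.  `max_separation()` works
on the order-(k−1) de Bruijn graph whose edges are the k-mers *not* in the
set: a surviving cycle means some bi-infinite sequence is never sampled
(`Inf`); otherwise the longest surviving path (computed by DP in topological
order, via igraph) bounds the longest unsampled stretch.  End effects are
excluded by construction — the definition is over bi-infinite sequences.

## Syncmers under the rank model

Syncmer hashes are modelled as iid continuous draws, so only the relative
ranks of the `w = k − j + 1` subwords matter and ties have probability zero
(`classify_rank_window()` refuses tied ranks rather than guessing).  The
exact profile `syncmer_hit_profile_exact()` conditions on the position of
the globally minimal rank in the `x + w − 1` subword positions: windows
containing it are syncmers only if it sits at a defining offset, and the
left and right remainders are independent subproblems of the same form.
This recursion is O(x²) and exact; the literal fraction-of-permutations
definition lives in the test suite as an independent oracle and agrees to
machine precision wherever it is feasible.

Down-sampling multiplies each syncmer window's retention by an independent
Bernoulli(1/ds) keep event, modelling the k-mer-hash filter.  Overlapping
k-mers differ in content, so treating their keep events as independent is
consistent with the hash model; how down-sampling interacts with *repeated*
k-mer content inside one run is not specified by the model and is assumed
independent here (the Monte Carlo sampler implements the same assumption, so
their agreement validates the implementation, not the assumption).

The recursion reproduces the expected structure exactly: closed syncmers of
sparsity `s = w/2` are universal with `H(x) = 1` from `x = 2s − 1`; open
syncmers with the central offset are polar with `H(x) = x/w` up to
`⌈w/2⌉`; and the central offset maximizes the run-size objective.

## Specificity, coverage and distances

**Sampled-match fraction.**  Maximal exact matches between unrelated random
sequences have length `y ≥ m` with frequency ∝ `p^y` (`p = 1/4` for DNA) and
are sampled with probability `H(y − m + 1)`, giving the series
`(1 − p) Σ H(x) p^(x−1)`.  Truncation is controlled by an analytic tail
bound (`H ≤ 1` gives tail ≤ `p^X`), default tolerance 10⁻¹²; for profile
inputs the tail freezes `H` at the last entry, which is exact once the
profile reaches 1 and otherwise errors if the frozen-tail uncertainty
exceeds the tolerance — the function never silently under-truncates.

**Coverage.**  `run_count_distribution(m, q)` enumerates all `2^(2m−1)`
conservation patterns of the letters covered by the `m` windows around a
focal letter (guard `m ≤ 12`).  The distribution is over `x = 0..m` and
sums to 1; the coverage sum `Σ_{x≥1} H(x) P_run(x)` starts at `x = 1`, which
reproduces the trivial `m = 1` case (`H(1)·q`) exactly.  Whether the source
formulation conditions on coverage at all is ambiguous; this normalization
is the one consistent with that base case.  A fully conserved set of windows
covering one letter is automatically a *consecutive* run, which is why the
run-hitting probability applies.

**Distances.**  `distance_distribution()` conditions on a word occurrence at
the origin (uniform over the set — each word is equally probable at a
sampled position in the iid model) and propagates mass through the suffix
states, harvesting and deleting mass that re-enters the set at each step: a
renewal-style definition chosen because it makes `mean(D) = s` hold exactly
in the limit and matches empirical gap distributions on simulated sequences.
Reported mean and variance are over the truncated support; the `tail_mass`
attribute quantifies the truncation, and tests only assert moments when it
is below 10⁻⁸.  Exhaustively over all binary sets with `k ≤ 3, n ≤ 4`,
ranking by average `H` at `u = 32` coincides with ranking by −Var(D)
(Spearman exactly 1 wherever the rankings are non-degenerate), supporting
the use of either criterion.

## Synthetic data: what it does and does not emulate

The generators produce (i) iid uniform sequences over any alphabet and
(ii) substitution-only related pairs with per-position conservation `q` —
precisely the model the theory assumes, which is the point: empirical
sparsity, gap bounds, run-hit frequencies and sampled-match fractions on
synthetic data must match the exact computations, and the suite checks that
they do (within binomial/replicate standard errors, using disjoint runs or
independent replicate pairs so the error bars are honest).

Real DNA is *not* iid: it has skewed composition, CpG depletion, and —
most importantly for specificity — simple repeats, which are exactly what
well-chosen word sets avoid and what makes them beat every-s-th sampling in
practice.  Passing tests on synthetic data therefore validate the
mathematics and the implementation, not the biological magnitude of the
specificity advantage; measuring that requires genome-scale data and an
aligner, both outside this package's scope (no indels, forward strand only,
exact-match seeds only).

## Problem sizes

The test and acceptance computations are sized for a laptop-class run:
exhaustive DP-vs-enumeration checks up to `k = 3, x = 6` (273 word sets);
200 random sets for the bound/monotonicity/reversal invariants; annealing
benchmarks on `choose(8, 2)` sets with 50 seeds; synthetic sequences of
10⁵–10⁶ letters with 4–8 replicate pairs for the empirical bridges.  These
sizes give standard errors comfortably below the effects being tested while
keeping the whole suite under a minute.

## Known limitations

* Substitution-only evolution; no indels, no strand symmetry, no
  composition bias in the exact theory.
* Word length is bounded by the lookup-table guard (`2^24` states); the
  published large sets (128 words, `k ≤ 12`) are findable by the annealer
  but not verifiable exactly.
* Syncmer analysis is rank-model only: no concrete hash function over
  nucleotide j-mers is provided, and tied hashes are rejected, not modelled.
* Two-hit and inexact-seed sensitivity are not computed.
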