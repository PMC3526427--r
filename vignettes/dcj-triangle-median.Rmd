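---
title: "Triangle score and exact DCJ medians of three circular genomes"
author: "dcjtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangle score and exact DCJ medians of three circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjtriad)
```

## The model and its assumptions

`dcjtriad` works with **circular genomes over a shared gene set `1..n`**:
every gene occurs exactly once in every genome, with an orientation, and all
chromosomes are circular. Under these assumptions a genome is fully captured
by a perfect matching on the `2n` gene extremities (tail `g^t`, head `g^h`):
each matching edge is one adjacency between neighbouring gene ends. The
internal encoding is `tail(g) = 2g − 1`, `head(g) = 2g`, which gives O(1)
indexing and a stable ordering for canonical output. Because a perfect
matching superposed on the implicit tail–head gene edges always decomposes
into cycles, *every* perfect matching is a valid circular genome — there are
`(2n−1)!!` of them.

Out of model scope (deliberately): linear chromosomes (the GRIMM reader
rejects the `$` terminator), unequal gene content, duplicated genes, and
indels. These would turn cycles into paths and break the closed-form
distance used throughout.

A **DCJ (2-break)** replaces two adjacencies by one of the two alternative
re-pairings of the same four extremities; it models reversals,
translocations, fusions and fissions in one operation. The distance is
computed from the breakpoint graph: `d(A,B) = n − c(A,B)`, with `c` the
number of alternating cycles. For three genomes the triangle score
`ts = d(A,B) + d(A,C) + d(B,C)` brackets the NP-hard median score by
`ts/2 ≤ ms ≤ 2·ts/3`; the package reports the integer-sharpened lower bound
`⌈ts/2⌉` (the median score is an integer while `ts/2` need not be) and the
additional upper bound `min` over the three sums of two pairwise distances
(each input genome is itself a median candidate).

## Sign and traversal conventions

Several equally valid conventions exist for turning a signed cycle such as
`(1, -2)` into adjacencies; all yield identical distances, but one must be
pinned for reproducible fixtures. `dcjtriad` uses: a positively signed gene
is traversed tail-to-head, so consecutive genes `x, y` contribute the
adjacency between the *outgoing* extremity of `x` (head if `x > 0`, tail if
`x < 0`) and the *incoming* extremity of `y` (tail if `y > 0`, head if
`y < 0`). Decoded chromosomes are canonicalised — start at the smallest gene
id, oriented positive, chromosomes sorted by smallest gene — so
`parseGenome(formatGenome(g)) == g` and rotations/reflections of a written
cycle compare equal.

Cycle decompositions are likewise deterministic: traversal starts at the
smallest unvisited extremity and follows the lexicographically smaller
colour first. This fixes cycle indices, which matters for the strong-pair
search below.

## Strong DCJs and triple construction

A DCJ changes `ts` by at most 2 (it touches two of the three distances, each
by at most 1). A **strong** DCJ raises `ts` by exactly 2. The package finds
one constructively: partition the moving genome's adjacencies by their cycle
id against each of the other two genomes; any two adjacencies differing in
*both* coordinates form a strong pair, and such a pair exists whenever both
of the mover's distances are below the maximum `n − 1`. `findStrongPair()`
scans pairs in lexicographic order of their smallest extremities and
`asDcjMove()` applies the "min-to-min" re-pairing — either re-pairing of a
strong pair merges the two cycles in both decompositions, so the choice is a
pure tie-break, pinned for reproducibility.

`constructTriple(p, q, r, n)` realises any prescribed distance triple from
`[0, n−1]` satisfying the triangle inequality. For an even sum it starts
from three copies of the identity genome `(1)(2)...(n)` and applies
`(p+q−r)/2`, `(p+r−q)/2`, `(q+r−p)/2` strong moves to `A`, `B`, `C`. For an
odd sum it first reaches the 2-gene unit configuration
`A = (1)(2)..., B = (1, 2)(3)..., C = (1, −2)(3)...` (one strong fusion in
`B`, then the alternative — non-strong — fusion in `C`), then proceeds as in
the even case on the reduced targets. One design point differs from the
obvious formulation: the targets are **not** sorted first. The even-case
coefficients are nonnegative under the triangle inequality in any order, and
in the odd case `(p+q−r−1)/2 ≥ 0` follows from the triangle inequality plus
parity (`p+q−r` is odd, hence ≥ 1), so label permutation bookkeeping is
unnecessary. An odd sum with a zero component is rejected during validation:
a zero distance forces the other two equal, hence an even sum — no such
triple exists. Before every strong move the implementation asserts the
submaximal-distance precondition, making the constructive argument
executable end to end; total strong moves always equal `⌊(p+q+r)/2⌋`.

## Exact median solvers

Since `d(X, M) = n − c(X, M)`, minimising the total distance of a candidate
median `M` is the same as maximising the total alternating-cycle count, and
the search space is the set of perfect matchings on the `2n` extremities.

**Brute force** (`medianBruteforce()`) scores all `(2n−1)!!` matchings; it is
the oracle implementation and is capped at `n = 6` (10,395 candidates, well
under a second) — the cap is a guard against accidental `(2n−1)!!` blow-up,
and can be raised explicitly.

**Branch-and-bound** (`medianBnb()`, compiled) builds the matching
depth-first, always branching on the smallest unmatched extremity paired
with each available partner in increasing order (deterministic node counts
and a deterministic "first median found"). For each of the three colours it
maintains the alternating paths induced by the median edges chosen so far
via endpoint maps: a new median edge either closes a cycle (+1) or splices
two paths, both O(1) with O(1) undo. Pruning uses the residual form of the
lower bound: with `m` genes unfixed, the cycles still obtainable are at most
`⌊(3m + c'_AB + c'_AC + c'_BC)/2⌋`, where the `c'` are the alternating-cycle
counts between the *contracted* colour matchings on the unmatched vertices
(each path contracted to a single edge). The incumbent starts at the best of
`A`, `B`, `C` as candidate median, i.e. at the min-pairwise-sum upper bound.
The solver is exact; the suite cross-checks it against brute force on random
triples and the two agree everywhere.

Ties: brute force with `allOptima = TRUE` returns *all* optimal medians, in
enumeration order; branch-and-bound returns the first optimum its
deterministic order encounters (the seeded candidate genome if nothing beats
it). Medians are genuinely non-unique in general, so downstream code should
treat the returned genome as *a* median, not *the* median.

The 11-gene examples solve in milliseconds (around a hundred search nodes);
the two-block chain on 8 genes likewise. No adequate-subgraph preprocessing
is used — the bound above is enough at these sizes, and keeping the solver
free of decomposition theory keeps its correctness argument elementary.

## What the generators emulate — and what they do not

`randomGenome(n, seed)` pairs a seeded shuffle of the `2n` extremities,
which samples exactly uniformly from all perfect matchings, i.e. from all
circular genomes; `randomTriple(n, "uniform")` draws three independently.
This is the natural null model for property tests (metric axioms, bound
checks, solver agreement), but uniform matchings are *not* realistic
evolutionary genomes: real genomes are correlated (few, long chromosomes;
bounded rearrangement divergence). The `"strong-walk"` mode covers part of
that gap by evolving three copies of one genome with `k` strong DCJs
(targets cycling `A`, `B`, `C` — any schedule of strong moves works, one is
pinned), producing triples that provably sit exactly at the median lower
bound. Passing tests therefore demonstrate correctness of the combinatorics
on these two families, not biological realism of any simulation.

Problem sizes used by the shipped tests were chosen to keep the whole suite
fast while still exercising every code path: exhaustive grids up to `n = 5`
for triple construction, random triples up to `n = 7` for distance/strong
properties, exact-median cross-checks at `n ≤ 5` (brute force versus
branch-and-bound, 100 triples), and the 11-gene worked examples solved by
branch-and-bound.

## Numerical and degenerate-input choices

* All quantities are small integers; no floating point enters any score.
* `n = 1` is legal everywhere it can be: the single matching on 2 vertices
  is `(1)`, distances are identically 0, and `enumerateDcjs()` returns an
  empty move list rather than erroring.
* A move's validity (4 distinct extremities, a genuine re-pairing, removed
  adjacencies present) is checked at application time; `applyStrongDcj()`
  re-derives the cycle memberships rather than trusting the pair object it
  is handed, and then asserts the +2 contract.
* `attainsLowerBound()` short-circuits to `FALSE` on an odd triangle score —
  `ts/2` is then not an integer, so the bound cannot be attained.
* The `seed` argument of `constructTriple()` is accepted for interface
  stability but unused: with the pinned tie-breaks the construction is fully
  deterministic.

## Known limitations

* Median solving beyond roughly 15–20 genes is not the goal here; the
  branch-and-bound bound is the triangle-score relaxation only, with no
  decomposition preprocessing, and worst-case instances will grow quickly.
* Whether the `2·ts/3` upper bound is ever tight is an open question; the
  package reports it but never assumes tightness anywhere.
* Only the first strong pair per tie-break order is returned;
  enumerating or sampling among all strong moves is not supported.
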