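# dcjtriad

Comparative genomics of **three circular genomes under the
Double-Cut-and-Join (DCJ) model**: breakpoint graphs, pairwise DCJ
distances, the triangle score, *strong* rearrangements, construction of
genome triples with prescribed pairwise distances, and **exact solvers for
the NP-hard DCJ median-of-three problem**.

The package is for researchers studying genome rearrangements and
small-phylogeny problems who need a desk-scale, fully exact toolkit: every
distance is computed from first principles (cycle counting in the breakpoint
graph) and every median score by provably exhaustive search, so the results
can serve as ground truth for heuristics.

## The model

A circular genome over genes `1..n` is a perfect matching on the `2n` gene
extremities (tail `g^t` and head `g^h` per gene); each matching edge is an
adjacency between neighbouring gene ends. The *breakpoint graph*
`BG(A, B, ..)` superposes the genomes' matchings, one colour each. Every
colour pair decomposes into alternating cycles, and the DCJ distance is

```
d_dcj(A, B) = n − c(A, B)
```

with `c(A, B)` the number of alternating cycles, so `0 ≤ d ≤ n − 1`.

For three genomes the *triangle score* is the sum of pairwise distances,
`ts(A,B,C) = d(A,B) + d(A,C) + d(B,C)`, and the *median score*

```
ms(A,B,C) = min over genomes M of  d(A,M) + d(B,M) + d(C,M)
```

is NP-hard to compute. The two are linked by

```
ts/2  ≤  ms  ≤  min(2·ts/3,  smallest sum of two pairwise distances).
```

A DCJ changes `ts` by at most 2 and `ms` by at most 1; a DCJ that raises
`ts` by 2 is called **strong**. The median score equals its lower bound
`ts/2` exactly on triples obtainable from a single genome by strong DCJs —
yet a strong DCJ need not raise the median score, and `ms − ts/2` can be
made arbitrarily large by chaining 4-gene blocks (see
`exampleRigidBlocks()`, `blockFamily()`, `exampleStrongFusion()`).

## Worked example

The 11-gene triple in which a strong DCJ fails to move the median score:

```r
library(dcjtriad)

g <- exampleStrongFusion()$genomes
triangleScore(g$A, g$B, g$C)
#> ScoreTriple: d(A,B) = 8 , d(A,C) = 8 , d(B,C) = 8 ; ts = 24

medianBnb(g$A, g$B, g$C)
#> MedianResult (bnb): ms = 15 [bounds: 12 .. min(16, 16)], 1 median(s), 106 nodes
#>   first median: (1)(2, 3, 4, 5)(6, 7)(8, 9, 10, 11)

# fuse B's two chromosomes into (1, 2, ..., 11): a strong DCJ (ts +2) ...
dcjDistance(g$B, g$Bprime)
#> [1] 1
tsSum(triangleScore(g$A, g$Bprime, g$C))
#> [1] 26

# ... that leaves the exact median score unchanged
medianScore(medianBnb(g$A, g$Bprime, g$C))
#> [1] 15
```

Triples with any feasible prescribed distances can be built constructively:

```r
tr <- constructTriple(2, 2, 2, n = 4)
tsDistances(triangleScore(tr$A, tr$B, tr$C))
#> AB AC BC
#>  2  2  2
sum(tr$log$strong)   # floor((2+2+2)/2) strong moves
#> [1] 3
```

Genomes parse from cycle notation (`parseGenome("(1, -2)(3, 4)")`) or
circular GRIMM files (`readGrimm()`); a thin command-line front end lives at
`inst/scripts/dcjtriad` (`distance`, `triangle`, `median`, `construct`).

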