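# Worked examples with known scores, used throughout the tests, plus the
# random-triple generator for property tests.  Each example returns its
# genomes together with the expected quantities so that callers can verify
# the core operations against them.

#' The minimal unit triangle: three 2-gene genomes at pairwise distance 1
#'
#' `A = (1)(2)`, `B = (1, 2)`, `C = (1, -2)`. The smallest triple with all
#' pairwise distances at the maximum `n - 1 = 1`; its breakpoint graph has a
#' single alternating cycle per colour pair. This configuration also seeds
#' the odd case of [constructTriple()].
#'
#' @return List with `label`, `genomes` (named list `A`, `B`, `C`) and
#'   `expected` (named numeric: the pairwise distances, `ts`, `ms`, and the
#'   `AB` cycle count).
#' @examples
#' ex <- exampleUnitTriangle()
#' tsSum(triangleScore(ex$genomes$A, ex$genomes$B, ex$genomes$C))
#' @export
exampleUnitTriangle <- function() {
    list(label = "unit-triangle",
         genomes = list(A = parseGenome("(1)(2)"),
                        B = parseGenome("(1, 2)"),
                        C = parseGenome("(1, -2)")),
         expected = list(dAB = 1L, dAC = 1L, dBC = 1L, ts = 3L, ms = 2L,
                         cyclesAB = 1L))
}

#' The rigid two-block triple: no DCJ can decrease its triangle score by 2
#'
#' `A = (1)(2)(3)(4)`, `B = (1, 2)(3, 4)`, `C = (1, -2)(3, -4)`: two
#' independent copies of the unit-triangle pattern. Although `ts = 6`, no
#' single DCJ decreases the triangle score by 2, and the exact median score
#' is 4 — one more than the lower bound `ts/2 = 3`. Chaining `n` such blocks
#' (see [blockFamily()]) pushes the median score `n` above the lower bound.
#'
#' @return List with `label`, `genomes` and `expected` (pairwise distances,
#'   `ts`, `ms`, `msMinusHalfTs`, and `tsDecreasable = FALSE`).
#' @examples
#' ex <- exampleRigidBlocks()
#' medianScore(medianBruteforce(ex$genomes$A, ex$genomes$B, ex$genomes$C))
#' @export
exampleRigidBlocks <- function() {
    list(label = "rigid-blocks",
         genomes = list(A = parseGenome("(1)(2)(3)(4)"),
                        B = parseGenome("(1, 2)(3, 4)"),
                        C = parseGenome("(1, -2)(3, -4)")),
         expected = list(dAB = 2L, dAC = 2L, dBC = 2L, ts = 6L, ms = 4L,
                         msMinusHalfTs = 1L, tsDecreasable = FALSE))
}

#' The strong-fusion counterexample: a strong DCJ that leaves the median
#' score unchanged
#'
#' Three 11-gene genomes `A`, `B`, `C` at pairwise distance 8 (`ts = 24`,
#' `ms = 15`), plus `Bprime` — obtained from `B` by a single fusion of its
#' two chromosomes into `(1, 2, ..., 11)`. That fusion is strong (`ts` rises
#' to 26, both `d(A, B')` and `d(C, B')` become 9) yet the median score stays
#' 15: the triangle-score lower bound rises while the median score does not,
#' showing the two measures can decouple. `M` and `Mprime` are optimal
#' medians of the two triples.
#'
#' @return List with `label`, `genomes` (named `A`, `B`, `C`, `Bprime`, `M`,
#'   `Mprime`) and `expected` (all distances and scores for both triples).
#' @examples
#' ex <- exampleStrongFusion()
#' dcjDistance(ex$genomes$A, ex$genomes$B)
#' @export
exampleStrongFusion <- function() {
    g <- list(
        A = parseGenome("(1, -6, -7, -8, -9, -10, -11)(2, 5, 4, 3)"),
        B = parseGenome("(1, 8, 9, 10, 11)(2, 3, 4, 5, 6, 7)"),
        C = parseGenome("(1, -3, 4, 10, -8, 11, 9, 5, -7, 6, 2)"),
        Bprime = parseGenome("(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)"),
        M = parseGenome("(1, -6, -5, -2, -3, -4, -7, -10, -11, 8, 9)"),
        Mprime = parseGenome("(1, -3, -4, -5, -2, -6, 7, -10, -11, 8, 9)"))
    list(label = "strong-fusion",
         genomes = g,
         expected = list(
             dAB = 8L, dAC = 8L, dBC = 8L, ts = 24L, ms = 15L,
             dAM = 3L, dBM = 5L, dCM = 7L,
             dABprime = 9L, dCBprime = 9L, tsPrime = 26L, msPrime = 15L,
             dAMprime = 4L, dBprimeMprime = 6L, dCMprime = 5L))
}

#' Chain of rigid blocks on 4n genes
#'
#' `n` disjoint copies of the [exampleRigidBlocks()] pattern, copy `i` on
#' genes `4(i-1)+1 .. 4(i-1)+4`: `A` all singletons, `B` fuses consecutive
#' pairs head-to-tail, `C` fuses them head-to-head. Each block contributes 6
#' to the triangle score and 4 to the median score, so
#' `ms - ts/2 = 4n - 3n = n` grows without bound.
#'
#' @param n Number of blocks (gene count is `4 * n`).
#' @return Named list of [Genome-class] objects `A`, `B`, `C`.
#' @examples
#' tr <- blockFamily(2)
#' formatGenome(tr$B)  # "(1, 2)(3, 4)(5, 6)(7, 8)"
#' @export
blockFamily <- function(n) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be at least 1")
    chromA <- as.list(seq_len(4L * n))
    odd <- seq(1L, 4L * n, by = 2L)
    chromB <- lapply(odd, function(g) c(g, g + 1L))
    chromC <- lapply(odd, function(g) c(g, -(g + 1L)))
    list(A = .chromosomesToGenome(chromA),
         B = .chromosomesToGenome(chromB),
         C = .chromosomesToGenome(chromC))
}

#' Generate a random genome triple
#'
#' Two modes: `"uniform"` draws three independent uniformly random genomes;
#' `"strong-walk"` starts from three copies of a single genome (the identity)
#' and applies `k` strong DCJs with targets cycling `A`, `B`, `C`, which by
#' construction yields a triple whose median score equals the triangle-score
#' lower bound (`ms = ts/2 = k`, with `ts = 2k`).
#'
#' @param n Gene count.
#' @param mode `"uniform"` or `"strong-walk"`.
#' @param k Number of strong moves for the walk (ignored for uniform draws).
#' @param seed Optional seed for the uniform draws; the walk itself is
#'   deterministic.
#' @return Named list of [Genome-class] objects `A`, `B`, `C`; for the walk,
#'   the applied moves are attached as `attr(., "moves")`.
#' @examples
#' tr <- randomTriple(4, "strong-walk", k = 3)
#' tsSum(triangleScore(tr$A, tr$B, tr$C))  # 6
#' @export
randomTriple <- function(n, mode = c("uniform", "strong-walk"), k = 0L,
                         seed = NULL) {
    mode <- match.arg(mode)
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be at least 1")
    if (mode == "uniform") {
        return(.withSeed(seed, list(A = randomGenome(n), B = randomGenome(n),
                                    C = randomGenome(n))))
    }
    k <- as.integer(k)
    if (is.na(k) || k < 0L) stop("'k' must be nonnegative")
    g <- list(A = identityGenome(n), B = identityGenome(n),
              C = identityGenome(n))
    moves <- list()
    targets <- rep_len(c("A", "B", "C"), k)
    for (i in seq_len(k)) {
        lab <- targets[i]
        others <- setdiff(names(g), lab)
        ds <- vapply(others, function(o) dcjDistance(g[[lab]], g[[o]]),
                     integer(1L))
        pair <- if (all(ds < n - 1L)) findStrongPair(lab, g$A, g$B, g$C)
                else NULL
        if (is.null(pair))
            stop("strong walk infeasible at move ", i, " of ", k, ": ",
                 "genome ", lab, " is already at maximal distance; ",
                 i - 1L, " move(s) completed")
        g[[lab]] <- applyStrongDcj(lab, g$A, g$B, g$C, pair)
        moves[[i]] <- asDcjMove(pair)
    }
    attr(g, "moves") <- moves
    g
}
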