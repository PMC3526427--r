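# Exact DCJ median of three genomes.  ms(A,B,C) = min over genomes M of
# d(A,M) + d(B,M) + d(C,M).  Since d(X,M) = n - c(X,M), minimising the total
# distance is the same as maximising the total number of alternating cycles
# the candidate forms with the three given genomes: total = 3n - sum(c).
# The problem is NP-hard; exact solvers here are exhaustive enumeration of
# all (2n-1)!! matchings (small n) and branch-and-bound (moderate n).

#' Bounds on the DCJ median score from the triangle score
#'
#' The median score always satisfies
#' \eqn{\lceil ts/2 \rceil \le ms \le \lfloor 2\,ts/3 \rfloor} and, slightly
#' better on the upper side, \eqn{ms \le} the smallest sum of two pairwise
#' distances (each given genome is itself a candidate median).
#'
#' @param a,b,c [Genome-class] objects on the same gene set.
#' @return Named integer vector `c(lower, upperTwoThirds, upperMinPair)`.
#' @examples
#' medianBounds(parseGenome("(1)(2)(3)(4)"), parseGenome("(1, 2)(3, 4)"),
#'              parseGenome("(1, -2)(3, -4)"))
#' @export
medianBounds <- function(a, b, c) {
    d <- tsDistances(triangleScore(a, b, c))
    ts <- sum(d)
    c(lower = as.integer(ceiling(ts / 2)),
      upperTwoThirds = as.integer(floor(2 * ts / 3)),
      upperMinPair = as.integer(min(d[["AB"]] + d[["AC"]],
                                    d[["AB"]] + d[["BC"]],
                                    d[["AC"]] + d[["BC"]])))
}

.medianResult <- function(a, b, c, score, mates, nodes, method) {
    bounds <- medianBounds(a, b, c)
    medians <- lapply(mates, Genome)
    dist <- t(vapply(medians, function(m)
        c(A = dcjDistance(a, m), B = dcjDistance(b, m),
          C = dcjDistance(c, m)), integer(3L)))
    new("MedianResult", score = as.integer(score), medians = medians,
        distances = dist, lowerBound = bounds[["lower"]],
        upperTwoThirds = bounds[["upperTwoThirds"]],
        upperMinPair = bounds[["upperMinPair"]],
        nodesExplored = as.numeric(nodes), method = method)
}

#' @describeIn medianScore The exact median score.
#' @param x A [MedianResult-class].
#' @export
setMethod("medianScore", "MedianResult", function(x) x@score)

#' @describeIn medianGenomes The optimal median genome(s).
#' @param x A [MedianResult-class].
#' @export
setMethod("medianGenomes", "MedianResult", function(x) x@medians)

setMethod("show", "MedianResult", function(object) {
    cat("MedianResult (", object@method, "): ms = ", object@score,
        " [bounds: ", object@lowerBound, " .. min(",
        object@upperTwoThirds, ", ", object@upperMinPair, ")], ",
        length(object@medians), " median(s), ",
        format(object@nodesExplored, big.mark = ","),
        " nodes\n", sep = "")
    cat("  first median:", formatGenome(object@medians[[1L]]), "\n")
})

#' Exact DCJ median by exhaustive enumeration
#'
#' Scores every one of the \eqn{(2n-1)!!} perfect matchings on the \eqn{2n}
#' extremities as a candidate median and returns the global minimum. Feasible
#' for small `n` only (10,395 candidates at `n = 6`); the cap exists because
#' the count grows superexponentially — use [medianBnb()] beyond it.
#'
#' @param a,b,c [Genome-class] objects on the same gene set.
#' @param allOptima If `TRUE`, return every optimal median (canonically
#'   ordered by mate vector); otherwise only the first found.
#' @param cap Refuse `n` above this (default 6).
#' @return A [MedianResult-class].
#' @examples
#' ms <- medianBruteforce(parseGenome("(1)(2)"), parseGenome("(1, 2)"),
#'                        parseGenome("(1, -2)"))
#' medianScore(ms)  # 2
#' @export
medianBruteforce <- function(a, b, c, allOptima = FALSE, cap = 6L) {
    n <- .checkSameN(a, b, c)
    if (n > cap)
        stop("brute force enumerates (2n-1)!! matchings and is capped at ",
             "n = ", cap, "; use medianBnb() for larger gene counts ",
             "(or raise 'cap' explicitly)")
    ma <- a@mate; mb <- b@mate; mc <- c@mate
    best <- -1L
    bestMates <- list()
    cands <- allPerfectMatchings(n)
    for (m in cands) {
        tot <- .cycleCountMates(ma, m) + .cycleCountMates(mb, m) +
            .cycleCountMates(mc, m)
        if (tot > best) {
            best <- tot
            bestMates <- list(m)
        } else if (allOptima && tot == best) {
            bestMates[[length(bestMates) + 1L]] <- m
        }
    }
    .medianResult(a, b, c, score = 3L * n - best, mates = bestMates,
                  nodes = length(cands), method = "bruteforce")
}

#' Exact DCJ median by branch-and-bound
#'
#' Depth-first search over partial matchings: the smallest unmatched
#' extremity is paired with every available partner (in increasing order),
#' alternating paths with the three given genomes are maintained by endpoint
#' contraction, and a branch is pruned when
#' (cycles closed so far) + \eqn{\lfloor (3m + c'_{AB} + c'_{AC} + c'_{BC})/2
#' \rfloor} cannot beat the incumbent, where `m` counts the genes not yet
#' fixed and the `c'` are alternating-cycle counts of the contracted residual
#' instance (the residual form of the triangle-score lower bound). The
#' incumbent starts from the best of `A`, `B`, `C` as candidate median, i.e.
#' at the min-pairwise-sum upper bound. The result is exact and agrees with
#' [medianBruteforce()] wherever both run.
#'
#' @param a,b,c [Genome-class] objects on the same gene set.
#' @return A [MedianResult-class] with the first optimal median found (the
#'   seeded candidate when nothing beats it) and the node count.
#' @examples
#' ms <- medianBnb(parseGenome("(1)(2)(3)(4)"), parseGenome("(1, 2)(3, 4)"),
#'                 parseGenome("(1, -2)(3, -4)"))
#' medianScore(ms)  # 4
#' @export
medianBnb <- function(a, b, c) {
    n <- .checkSameN(a, b, c)
    res <- median_bnb_cpp(n, a@mate, b@mate, c@mate)
    .medianResult(a, b, c, score = res$score, mates = list(res$mate),
                  nodes = res$nodes, method = "bnb")
}

# exact median score by the cheapest applicable exact solver
.exactMs <- function(a, b, c) {
    medianScore(medianBnb(a, b, c))
}

#' Does the median score attain its lower bound?
#'
#' True iff \eqn{ms(A,B,C) = ts(A,B,C)/2} (which requires an even triangle
#' score). This holds exactly for triples obtainable from a single genome by
#' strong DCJs.
#'
#' @param a,b,c [Genome-class] objects.
#' @return Logical scalar.
#' @examples
#' g <- parseGenome("(1)(2)(3)")
#' attainsLowerBound(g, g, g)  # TRUE: ms = ts = 0
#' @export
attainsLowerBound <- function(a, b, c) {
    ts <- .ts(a, b, c)
    if (ts %% 2L != 0L) return(FALSE)
    .exactMs(a, b, c) == ts %/% 2L
}

#' Change in median score under one DCJ move
#'
#' Solves the median exactly before and after the move; the difference is
#' provably in \eqn{\{-1, 0, +1\}} (a single DCJ moves one genome by at most
#' one step relative to any fixed median candidate), and that range is
#' asserted.
#'
#' @param a,b,c [Genome-class] objects labelled `A`, `B`, `C`.
#' @param move A [DcjMove-class] with `target` one of `"A"`, `"B"`, `"C"`.
#' @return Integer delta `ms(after) - ms(before)`.
#' @export
msDeltaUnderMove <- function(a, b, c, move) {
    stopifnot(is(move, "DcjMove"))
    g <- list(A = a, B = b, C = c)
    lab <- move@target
    if (is.na(lab) || !(lab %in% names(g)))
        stop("move target must be one of 'A', 'B', 'C'")
    before <- .exactMs(g$A, g$B, g$C)
    g[[lab]] <- applyDcj(g[[lab]], move)
    after <- .exactMs(g$A, g$B, g$C)
    delta <- after - before
    if (abs(delta) > 1L)
        stop("internal error: a single DCJ changed the median score by ",
             delta)
    delta
}
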