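#' @import methods
NULL

#' Genome: a circular genome as a perfect matching on gene extremities
#'
#' A circular genome over genes \eqn{1..n} is stored as a perfect matching on
#' the \eqn{2n} gene extremities. Gene \eqn{g} contributes its tail
#' (vertex \eqn{2g-1}, written \eqn{g^t}) and its head (vertex \eqn{2g},
#' written \eqn{g^h}); every adjacency between two neighbouring gene ends on a
#' (circular) chromosome is one matching edge. Because the matching is
#' superposed on the implicit tail--head gene edges, any perfect matching
#' decodes to a set of circular chromosomes, so validity only requires a
#' fixed-point-free involution on \eqn{1..2n}.
#'
#' @slot n Integer, the number of genes.
#' @slot mate Integer vector of length \eqn{2n}; \code{mate[v]} is the
#'   extremity adjacent to extremity \code{v}.
#'
#' @seealso [parseGenome()], [decodeChromosomes()], [randomGenome()]
#' @export
setClass("Genome", representation(n = "integer", mate = "integer"))

setValidity("Genome", function(object) {
    n <- object@n
    mate <- object@mate
    if (length(n) != 1L || is.na(n) || n < 1L)
        return("'n' must be a single positive integer")
    if (length(mate) != 2L * n)
        return("'mate' must have length 2n")
    if (anyNA(mate) || any(mate < 1L) || any(mate > 2L * n))
        return("'mate' entries must lie in 1..2n")
    if (any(mate == seq_along(mate)))
        return("an extremity cannot be adjacent to itself")
    if (!identical(mate[mate], seq_along(mate)))
        return("'mate' must be an involution (a perfect matching)")
    TRUE
})

#' Breakpoint graph of two or more genomes
#'
#' The superposition of \eqn{k \ge 2} genome matchings (one colour per genome)
#' on the shared vertex set of \eqn{2n} gene extremities. Every unordered
#' colour pair decomposes into vertex-disjoint alternating cycles; the number
#' of such cycles drives the DCJ distance.
#'
#' @slot n Integer gene count shared by all genomes.
#' @slot matchings Named list of integer mate vectors, one per colour.
#'
#' @seealso [buildBreakpointGraph()], [alternatingCycles()]
#' @export
setClass("BreakpointGraph",
         representation(n = "integer", matchings = "list"))

setValidity("BreakpointGraph", function(object) {
    if (length(object@matchings) < 2L)
        return("a breakpoint graph needs at least 2 genomes")
    if (is.null(names(object@matchings)) ||
        anyDuplicated(names(object@matchings)))
        return("matchings must be uniquely named (colour labels)")
    for (m in object@matchings) {
        if (length(m) != 2L * object@n)
            return("all matchings must live on the same 2n vertices")
        if (!identical(m[m], seq_along(m)) || any(m == seq_along(m)))
            return("each colour must be a perfect matching")
    }
    TRUE
})

#' Alternating-cycle decomposition of one colour pair
#'
#' The vertex-disjoint cycles with edges alternating between the two colours.
#' Cycles are listed by their smallest contained vertex; a length-2 cycle is a
#' trivial cycle (the two colours share that adjacency).
#'
#' @slot colors Character vector of length 2, the colour pair.
#' @slot cycles List of integer vectors, each a cyclic vertex sequence in
#'   traversal order (first colour edge first).
#' @slot cycleId Integer vector of length \eqn{2n} mapping each extremity to
#'   the index of its cycle.
#' @export
setClass("CycleDecomposition",
         representation(colors = "character", cycles = "list",
                        cycleId = "integer"))

#' A DCJ (2-break) rearrangement
#'
#' Replaces two adjacencies of one genome by one of the two alternative
#' re-pairings of the same four extremities.
#'
#' @slot target Character label of the genome the move acts on (may be
#'   \code{NA} for a free-standing move).
#' @slot removed 2x2 integer matrix; each row is one removed adjacency.
#' @slot added 2x2 integer matrix; each row is one added adjacency.
#'
#' @seealso [applyDcj()], [enumerateDcjs()]
#' @export
setClass("DcjMove",
         representation(target = "character", removed = "matrix",
                        added = "matrix"))

setValidity("DcjMove", function(object) {
    r <- object@removed
    a <- object@added
    if (!is.numeric(r) || !identical(dim(r), c(2L, 2L)) ||
        !is.numeric(a) || !identical(dim(a), c(2L, 2L)))
        return("'removed' and 'added' must be 2x2 integer matrices")
    ext <- sort(as.vector(r))
    if (anyDuplicated(ext))
        return("the two removed adjacencies must cover 4 distinct extremities")
    if (!identical(sort(as.vector(a)), ext))
        return("'added' must re-pair the same four extremities")
    if (setequal(.adjKeys(r), .adjKeys(a)))
        return("'added' must differ from 'removed'")
    TRUE
})

# canonical "u-v" keys (u < v) for the rows of an adjacency matrix
.adjKeys <- function(m) {
    paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]), sep = "-")
}

#' A strong pair of adjacencies
#'
#' Two adjacencies of the moving genome that lie in two distinct alternating
#' cycles with respect to each of the two other genomes. Any DCJ on such a
#' pair merges cycles in both decompositions and therefore increases the
#' triangle score by 2 (a strong DCJ).
#'
#' @slot mover Character label of the moving genome.
#' @slot edges 2x2 integer matrix; each row one adjacency of the mover.
#' @slot cyclesFirst Integer vector of length 2: cycle indices of the two
#'   edges in the decomposition against the first other genome.
#' @slot cyclesSecond Same against the second other genome.
#'
#' @seealso [findStrongPair()], [applyStrongDcj()]
#' @export
setClass("StrongPair",
         representation(mover = "character", edges = "matrix",
                        cyclesFirst = "integer", cyclesSecond = "integer"))

setValidity("StrongPair", function(object) {
    if (object@cyclesFirst[1L] == object@cyclesFirst[2L])
        return("edges must lie in distinct cycles of the first decomposition")
    if (object@cyclesSecond[1L] == object@cyclesSecond[2L])
        return("edges must lie in distinct cycles of the second decomposition")
    if (anyDuplicated(as.vector(object@edges)))
        return("the two adjacencies must cover 4 distinct extremities")
    TRUE
})

#' Triangle score of three genomes
#'
#' The three pairwise DCJ distances and their sum, the triangle score
#' \eqn{ts(A,B,C) = d(A,B) + d(A,C) + d(B,C)}.
#'
#' @slot distances Named integer vector with elements \code{AB}, \code{AC},
#'   \code{BC}.
#' @slot total Integer, the triangle score.
#' @seealso [triangleScore()]
#' @export
setClass("ScoreTriple",
         representation(distances = "integer", total = "integer"))

setValidity("ScoreTriple", function(object) {
    d <- object@distances
    if (length(d) != 3L || !identical(names(d), c("AB", "AC", "BC")))
        return("'distances' must be named c(AB=, AC=, BC=)")
    if (any(d < 0L))
        return("distances must be nonnegative")
    if (object@total != sum(d))
        return("'total' must equal the sum of the three distances")
    if (d[1L] + d[2L] < d[3L] || d[1L] + d[3L] < d[2L] ||
        d[2L] + d[3L] < d[1L])
        return("distances must satisfy the triangle inequality")
    TRUE
})

#' Result of an exact DCJ median computation
#'
#' @slot score Integer, the exact median score \eqn{ms(A,B,C)}.
#' @slot medians List of [Genome] objects attaining the score (brute force
#'   with \code{allOptima = TRUE} returns all of them; branch-and-bound the
#'   first one found).
#' @slot distances Integer matrix, one row per returned median, columns
#'   \code{A}, \code{B}, \code{C}: the distances from that median.
#' @slot lowerBound Integer, \eqn{\lceil ts/2 \rceil}.
#' @slot upperTwoThirds Integer, \eqn{\lfloor 2\,ts/3 \rfloor}.
#' @slot upperMinPair Integer, the smallest pairwise distance sum.
#' @slot nodesExplored Numeric search statistic (candidate matchings for brute
#'   force; search-tree nodes for branch-and-bound).
#' @slot method Character, \code{"bruteforce"} or \code{"bnb"}.
#' @seealso [medianBruteforce()], [medianBnb()], [medianBounds()]
#' @export
setClass("MedianResult",
         representation(score = "integer", medians = "list",
                        distances = "matrix", lowerBound = "integer",
                        upperTwoThirds = "integer", upperMinPair = "integer",
                        nodesExplored = "numeric", method = "character"))

setValidity("MedianResult", function(object) {
    if (length(object@medians) < 1L)
        return("at least one median genome must be returned")
    if (object@score > min(object@upperTwoThirds, object@upperMinPair) ||
        object@score < object@lowerBound)
        return("score must lie between the lower and upper bounds")
    TRUE
})
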