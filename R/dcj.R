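#' DCJ distance between two circular genomes
#'
#' The minimal number of DCJ (2-break) rearrangements transforming one genome
#' into the other, computed by cycle counting in their breakpoint graph:
#' \eqn{d_{dcj}(A,B) = n - c(A,B)}, where \eqn{c(A,B)} is the number of
#' alternating cycles. Ranges over \eqn{0..n-1}.
#'
#' @param a,b [Genome-class] objects on the same gene set.
#' @return Integer distance.
#' @examples
#' dcjDistance(parseGenome("(1)(2)"), parseGenome("(1, 2)"))  # 1
#' @export
dcjDistance <- function(a, b) {
    .checkSameN(a, b)
    a@n - .cycleCountMates(a@mate, b@mate)
}

.checkSameN <- function(...) {
    ns <- vapply(list(...), geneCount, integer(1L))
    if (length(unique(ns)) != 1L)
        stop("genomes are on different gene sets: n = ",
             paste(ns, collapse = ", "))
    ns[[1L]]
}

# plain numeric triangle score, used internally where the class is overkill
.ts <- function(a, b, c) {
    dcjDistance(a, b) + dcjDistance(a, c) + dcjDistance(b, c)
}

#' Triangle score of three genomes
#'
#' The sum of the three pairwise DCJ distances,
#' \eqn{ts(A,B,C) = d(A,B) + d(A,C) + d(B,C)}. Halved, it is a lower bound
#' for the median score; with factor 2/3 an upper bound.
#'
#' @param a,b,c [Genome-class] objects on the same gene set.
#' @return A [ScoreTriple-class] holding the three distances and their sum.
#' @examples
#' ts <- triangleScore(parseGenome("(1)(2)"), parseGenome("(1, 2)"),
#'                     parseGenome("(1, -2)"))
#' tsSum(ts)        # 3
#' tsDistances(ts)  # AB, AC, BC
#' @export
triangleScore <- function(a, b, c) {
    .checkSameN(a, b, c)
    d <- c(AB = dcjDistance(a, b), AC = dcjDistance(a, c),
           BC = dcjDistance(b, c))
    new("ScoreTriple", distances = d, total = sum(d))
}

#' @describeIn tsDistances The named pairwise distances of a score triple.
#' @param x A [ScoreTriple-class].
#' @export
setMethod("tsDistances", "ScoreTriple", function(x) x@distances)

#' @describeIn tsSum The triangle score (sum of the three distances).
#' @param x A [ScoreTriple-class].
#' @export
setMethod("tsSum", "ScoreTriple", function(x) x@total)

setMethod("show", "ScoreTriple", function(object) {
    d <- object@distances
    cat("ScoreTriple: d(A,B) =", d[["AB"]], ", d(A,C) =", d[["AC"]],
        ", d(B,C) =", d[["BC"]], "; ts =", object@total, "\n")
})

#' Construct a DCJ move
#'
#' A 2-break: two adjacencies are removed and the same four extremities are
#' re-paired in one of the two alternative ways.
#'
#' @param removed 2x2 integer matrix (rows = adjacencies to remove).
#' @param added 2x2 integer matrix (rows = adjacencies to add).
#' @param target Optional label of the genome the move acts on.
#' @return A [DcjMove-class].
#' @examples
#' # fuse (1)(2) into (1, 2): remove the two self-adjacencies
#' DcjMove(rbind(c(1, 2), c(3, 4)), rbind(c(2, 3), c(4, 1)))
#' @export
DcjMove <- function(removed, added, target = NA_character_) {
    storage.mode(removed) <- "integer"
    storage.mode(added) <- "integer"
    new("DcjMove", target = as.character(target), removed = removed,
        added = added)
}

setMethod("show", "DcjMove", function(object) {
    fmt <- function(m) paste(apply(m, 1L, function(r)
        paste0("{", extremityLabel(r[1L]), ",", extremityLabel(r[2L]), "}")),
        collapse = " ")
    cat("DcjMove", if (!is.na(object@target)) paste0("on ", object@target),
        ": remove", fmt(object@removed), "add", fmt(object@added), "\n")
})

#' Apply a DCJ move to a genome
#'
#' @param g A [Genome-class].
#' @param move A [DcjMove-class] whose removed adjacencies are present in `g`.
#' @return The rearranged [Genome-class]; `g` itself is unchanged.
#' @examples
#' g <- parseGenome("(1)(2)")
#' m <- DcjMove(rbind(c(1, 2), c(3, 4)), rbind(c(2, 3), c(4, 1)))
#' formatGenome(applyDcj(g, m))  # "(1, 2)"
#' @export
applyDcj <- function(g, move) {
    stopifnot(is(g, "Genome"), is(move, "DcjMove"))
    validObject(move)
    mate <- g@mate
    r <- move@removed
    for (i in 1:2) {
        if (mate[r[i, 1L]] != r[i, 2L])
            stop("adjacency {", extremityLabel(r[i, 1L]), ",",
                 extremityLabel(r[i, 2L]), "} is not present in the genome")
    }
    a <- move@added
    for (i in 1:2) {
        mate[a[i, 1L]] <- a[i, 2L]
        mate[a[i, 2L]] <- a[i, 1L]
    }
    Genome(mate)
}

#' Invert a DCJ move
#'
#' @param move A [DcjMove-class].
#' @return The [DcjMove-class] that undoes `move`.
#' @export
invertDcj <- function(move) {
    DcjMove(move@added, move@removed, move@target)
}

# the two re-pairings of two disjoint adjacencies; variant 1 joins the two
# smaller extremities ("min-to-min"), variant 2 is the alternative
.repairings <- function(e1, e2) {
    e1 <- sort(e1)
    e2 <- sort(e2)
    list(rbind(c(e1[1L], e2[1L]), c(e1[2L], e2[2L])),
         rbind(c(e1[1L], e2[2L]), c(e1[2L], e2[1L])))
}

#' Enumerate all DCJ moves available in a genome
#'
#' All \eqn{\binom{n}{2}} unordered pairs of adjacencies, each with its two
#' re-pairings: \eqn{n(n-1)} moves, in a deterministic order (pairs ordered
#' by their smallest extremities, the "min-to-min" re-pairing first).
#'
#' @param g A [Genome-class].
#' @param target Optional label stamped on the moves.
#' @return List of [DcjMove-class] objects (empty for `n < 2`).
#' @examples
#' length(enumerateDcjs(parseGenome("(1)(2)(3)(4)")))  # 12
#' @export
enumerateDcjs <- function(g, target = NA_character_) {
    adj <- adjacencies(g)
    n <- nrow(adj)
    if (n < 2L) return(list())
    moves <- vector("list", n * (n - 1L))
    k <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            removed <- adj[c(i, j), , drop = FALSE]
            for (add in .repairings(adj[i, ], adj[j, ])) {
                k <- k + 1L
                moves[[k]] <- DcjMove(removed, add, target)
            }
        }
    }
    moves
}

#' Change in triangle score under one DCJ move
#'
#' Recomputes only the two distances that involve the moved genome (the third
#' pair's matchings are untouched). The result always lies in
#' \eqn{\{-2, ..., +2\}}: one DCJ changes each affected distance by at most 1.
#'
#' @param a,b,c [Genome-class] objects labelled `A`, `B`, `C`.
#' @param move A [DcjMove-class] with `target` one of `"A"`, `"B"`, `"C"`.
#' @return Integer delta `ts(after) - ts(before)`.
#' @examples
#' a <- parseGenome("(1)(2)"); b <- parseGenome("(1, 2)")
#' m <- DcjMove(rbind(c(1, 2), c(3, 4)), rbind(c(2, 3), c(4, 1)),
#'              target = "A")
#' tsDelta(a, b, parseGenome("(1, -2)"), m)
#' @export
tsDelta <- function(a, b, c, move) {
    stopifnot(is(move, "DcjMove"))
    g <- list(A = a, B = b, C = c)
    lab <- move@target
    if (is.na(lab) || !(lab %in% names(g)))
        stop("move target must be one of 'A', 'B', 'C'")
    others <- g[setdiff(names(g), lab)]
    before <- dcjDistance(g[[lab]], others[[1L]]) +
        dcjDistance(g[[lab]], others[[2L]])
    moved <- applyDcj(g[[lab]], move)
    after <- dcjDistance(moved, others[[1L]]) +
        dcjDistance(moved, others[[2L]])
    after - before
}
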