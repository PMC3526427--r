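# Strong DCJs: rearrangements in one genome that increase the triangle score
# by 2, i.e. move that genome one step farther from each of the other two.
# A DCJ on two adjacencies lying in distinct alternating cycles with respect
# to BOTH other genomes merges cycles in both decompositions (either
# re-pairing does), dropping both cycle counts by 1 while the third pair is
# untouched.

.tripleList <- function(a, b, c) {
    .checkSameN(a, b, c)
    list(A = a, B = b, C = c)
}

#' Find a strong pair of adjacencies
#'
#' Searches the moving genome's adjacencies for a pair that lies in two
#' distinct alternating cycles against each of the two other genomes. Such a
#' pair exists whenever both of the mover's distances to the other genomes
#' are below the maximum \eqn{n - 1}; any DCJ on it is strong. Adjacencies
#' are scanned in order of their smallest extremity and the lexicographically
#' first qualifying pair is returned, so the result is deterministic.
#'
#' @param mover `"A"`, `"B"` or `"C"`: the genome to rearrange.
#' @param a,b,c [Genome-class] objects on the same gene set.
#' @return A [StrongPair-class], or `NULL` when no pair exists (only possible
#'   when the mover has a distance of `n - 1` to at least one other genome;
#'   `NULL` is returned only after exhausting all pairs).
#' @examples
#' a <- parseGenome("(1)(2)(3)(4)")
#' b <- parseGenome("(1, 2)(3, 4)")
#' c <- parseGenome("(1, -2)(3, -4)")
#' findStrongPair("A", a, b, c)
#' @export
findStrongPair <- function(mover, a, b, c) {
    g <- .tripleList(a, b, c)
    if (!(mover %in% names(g)))
        stop("'mover' must be one of 'A', 'B', 'C'")
    others <- setdiff(names(g), mover)
    bg <- buildBreakpointGraph(g)
    dec1 <- alternatingCycles(bg, mover, others[1L])
    dec2 <- alternatingCycles(bg, mover, others[2L])
    adj <- adjacencies(g[[mover]])
    id1 <- dec1@cycleId[adj[, 1L]]   # both endpoints share the cycle
    id2 <- dec2@cycleId[adj[, 1L]]
    m <- nrow(adj)
    for (i in seq_len(m - 1L)) {
        for (j in seq.int(i + 1L, m)) {
            if (id1[i] != id1[j] && id2[i] != id2[j]) {
                return(new("StrongPair", mover = mover,
                           edges = adj[c(i, j), , drop = FALSE],
                           cyclesFirst = c(id1[i], id1[j]),
                           cyclesSecond = c(id2[i], id2[j])))
            }
        }
    }
    NULL
}

setMethod("show", "StrongPair", function(object) {
    e <- object@edges
    cat("StrongPair in ", object@mover, ": {",
        extremityLabel(e[1L, 1L]), ",", extremityLabel(e[1L, 2L]), "} and {",
        extremityLabel(e[2L, 1L]), ",", extremityLabel(e[2L, 2L]),
        "} (cycles ", paste(object@cyclesFirst, collapse = "/"), " and ",
        paste(object@cyclesSecond, collapse = "/"), ")\n", sep = "")
})

#' @describeIn asDcjMove Turn a strong pair into a concrete move using the
#'   "min-to-min" re-pairing (the pinned deterministic variant; either
#'   re-pairing of a strong pair is a strong DCJ).
#' @param x Object to convert.
#' @param ... Unused.
#' @export
setMethod("asDcjMove", "StrongPair", function(x, ...) {
    DcjMove(x@edges, .repairings(x@edges[1L, ], x@edges[2L, ])[[1L]],
            target = x@mover)
})

#' Apply a strong DCJ
#'
#' Applies the pinned re-pairing of a strong pair to the moving genome and
#' verifies the contract: the triangle score rises by exactly 2 (both of the
#' mover's distances by 1, the third untouched).
#'
#' @param mover `"A"`, `"B"` or `"C"`.
#' @param a,b,c [Genome-class] objects.
#' @param pair A [StrongPair-class] for `mover`, e.g. from
#'   [findStrongPair()]. Passing a non-strong pair is an error.
#' @return The rearranged mover [Genome-class].
#' @examples
#' a <- parseGenome("(1)(2)(3)(4)")
#' b <- parseGenome("(1, 2)(3, 4)")
#' c <- parseGenome("(1, -2)(3, -4)")
#' p <- findStrongPair("A", a, b, c)
#' a2 <- applyStrongDcj("A", a, b, c, p)
#' tsSum(triangleScore(a2, b, c))   # was 6, now 8
#' @export
applyStrongDcj <- function(mover, a, b, c, pair) {
    g <- .tripleList(a, b, c)
    stopifnot(is(pair, "StrongPair"))
    if (pair@mover != mover)
        stop("pair was found for mover '", pair@mover, "', not '", mover, "'")
    # guard: re-derive the cycle memberships instead of trusting the slots
    others <- setdiff(names(g), mover)
    bg <- buildBreakpointGraph(g)
    id1 <- alternatingCycles(bg, mover, others[1L])@cycleId
    id2 <- alternatingCycles(bg, mover, others[2L])@cycleId
    e <- pair@edges
    if (id1[e[1L, 1L]] == id1[e[2L, 1L]] ||
        id2[e[1L, 1L]] == id2[e[2L, 1L]])
        stop("not a strong pair: the two adjacencies share an alternating ",
             "cycle with respect to at least one other genome")
    move <- asDcjMove(pair)
    moved <- applyDcj(g[[mover]], move)
    g2 <- g
    g2[[mover]] <- moved
    if (.ts(g2$A, g2$B, g2$C) - .ts(g$A, g$B, g$C) != 2L)
        stop("internal error: strong DCJ did not raise the triangle score by 2")
    moved
}

#' Is a DCJ move strong?
#'
#' A move is strong iff it increases the triangle score by exactly 2.
#'
#' @param move A [DcjMove-class] targeting one of the genomes.
#' @param a,b,c [Genome-class] objects labelled `A`, `B`, `C`.
#' @return Logical scalar.
#' @export
isStrong <- function(move, a, b, c) {
    tsDelta(a, b, c, move) == 2L
}

#' Does any DCJ decrease the triangle score by 2?
#'
#' Exhaustively applies all \eqn{3 n(n-1)} moves over the three genomes and
#' checks whether any has `tsDelta == -2`. Some triples admit none: their
#' breakpoint graph cannot be built from an identity breakpoint graph with
#' \eqn{ts/2} DCJs.
#'
#' @param a,b,c [Genome-class] objects.
#' @return Logical scalar.
#' @examples
#' existsTsDecreasingDcj(parseGenome("(1)(2)(3)(4)"),
#'                       parseGenome("(1, 2)(3, 4)"),
#'                       parseGenome("(1, -2)(3, -4)"))  # FALSE
#' @export
existsTsDecreasingDcj <- function(a, b, c) {
    g <- .tripleList(a, b, c)
    for (lab in names(g)) {
        for (move in enumerateDcjs(g[[lab]], target = lab)) {
            if (tsDelta(g$A, g$B, g$C, move) == -2L) return(TRUE)
        }
    }
    FALSE
}

#' Validate a prescribed-distance triple
#'
#' @param p,q,r Target pairwise distances `d(A,B)`, `d(A,C)`, `d(B,C)`.
#' @param n Gene count.
#' @return (Invisibly) the integer vector `c(p, q, r, n)`.
#' @keywords internal
.checkTripleSpec <- function(p, q, r, n) {
    v <- as.integer(c(p, q, r, n))
    if (anyNA(v)) stop("p, q, r, n must be integers")
    p <- v[1L]; q <- v[2L]; r <- v[3L]; n <- v[4L]
    if (n < 1L) stop("'n' must be at least 1")
    if (min(p, q, r) < 0L || max(p, q, r) > n - 1L)
        stop("p, q, r must lie in [0, n - 1] = [0, ", n - 1L, "]")
    if (p + q < r || p + r < q || q + r < p)
        stop("(p, q, r) must satisfy the triangle inequality")
    if ((p + q + r) %% 2L == 1L && min(p, q, r) == 0L)
        stop("impossible spec: an odd distance sum with a zero distance ",
             "contradicts the triangle inequality (a zero distance forces ",
             "the other two equal, hence an even sum)")
    invisible(v)
}

#' Construct three genomes with prescribed pairwise DCJ distances
#'
#' Builds genomes `A`, `B`, `C` on `n` genes with exact pairwise distances
#' `(p, q, r) = (d(A,B), d(A,C), d(B,C))` for any triple of integers in
#' `[0, n - 1]` satisfying the triangle inequality, using
#' \eqn{\lfloor (p+q+r)/2 \rfloor} strong DCJs plus, when `p + q + r` is odd,
#' one non-strong DCJ.
#'
#' For an even sum the construction starts from three copies of the identity
#' genome and applies `(p+q-r)/2` strong DCJs to `A`, `(p+r-q)/2` to `B` and
#' `(q+r-p)/2` to `C` (each found with [findStrongPair()]); the triangle
#' inequality makes all three counts nonnegative. For an odd sum all of
#' `p, q, r` are positive; the construction first reaches the unit triple
#' `A = (1)(2)...`, `B = (1, 2)(3)...`, `C = (1, -2)(3)...` with distances
#' `(1, 1, 1)` (one strong move in `B`, then one non-strong move in `C`) and
#' then applies `(p+q-r-1)/2`, `(p+r-q-1)/2`, `(q+r-p-1)/2` further strong
#' moves, again all nonnegative by the triangle inequality and parity.
#'
#' @param p,q,r Target distances `d(A,B)`, `d(A,C)`, `d(B,C)`.
#' @param n Gene count (at least 2 whenever any target is positive).
#' @param seed Reserved for future randomised pair selection; with the
#'   deterministic tie-breaking of [findStrongPair()] it does not alter the
#'   output.
#' @return A list with elements `A`, `B`, `C` (the genomes) and `log`, a
#'   `data.frame` with one row per move: `step`, `target`, the removed and
#'   added adjacencies (as `"u-v"` extremity index pairs), and `strong`.
#'   The move objects themselves are attached as `attr(log, "moves")`.
#' @examples
#' tr <- constructTriple(2, 2, 2, n = 4)
#' tsDistances(triangleScore(tr$A, tr$B, tr$C))
#' sum(tr$log$strong)  # 3 strong moves
#' @export
constructTriple <- function(p, q, r, n, seed = NULL) {
    v <- .checkTripleSpec(p, q, r, n)
    p <- v[1L]; q <- v[2L]; r <- v[3L]; n <- v[4L]
    g <- list(A = identityGenome(n), B = identityGenome(n),
              C = identityGenome(n))
    log <- data.frame(step = integer(0L), target = character(0L),
                      removed = character(0L), added = character(0L),
                      strong = logical(0L))
    moves <- list()
    record <- function(move) {
        strong <- tsDelta(g$A, g$B, g$C, move) == 2L
        moved <- applyDcj(g[[move@target]], move)
        g[[move@target]] <<- moved
        moves[[length(moves) + 1L]] <<- move
        log[nrow(log) + 1L, ] <<- list(nrow(log) + 1L, move@target,
                                       paste(.adjKeys(move@removed),
                                             collapse = " "),
                                       paste(.adjKeys(move@added),
                                             collapse = " "),
                                       strong)
    }
    strongCounts <- c(A = (p + q - r) %/% 2L, B = (p + r - q) %/% 2L,
                      C = (q + r - p) %/% 2L)
    if ((p + q + r) %% 2L == 1L) {
        # seed the unit triple on genes 1, 2: strong fusion in B, then the
        # alternative (non-strong) fusion in C
        selfAdj <- rbind(c(1L, 2L), c(3L, 4L))
        record(DcjMove(selfAdj, rbind(c(2L, 3L), c(4L, 1L)), target = "B"))
        record(DcjMove(selfAdj, rbind(c(1L, 3L), c(2L, 4L)), target = "C"))
        strongCounts <- c(A = (p + q - r - 1L) %/% 2L,
                          B = (p + r - q - 1L) %/% 2L,
                          C = (q + r - p - 1L) %/% 2L)
    }
    for (lab in names(strongCounts)) {
        for (i in seq_len(strongCounts[[lab]])) {
            others <- setdiff(names(g), lab)
            ds <- vapply(others, function(o) dcjDistance(g[[lab]], g[[o]]),
                         integer(1L))
            stopifnot(all(ds < n - 1L))  # strong-pair existence precondition
            pair <- findStrongPair(lab, g$A, g$B, g$C)
            if (is.null(pair))
                stop("internal error: no strong pair although both of ",
                     lab, "'s distances are below n - 1")
            record(asDcjMove(pair))
        }
    }
    got <- c(dcjDistance(g$A, g$B), dcjDistance(g$A, g$C),
             dcjDistance(g$B, g$C))
    if (!identical(got, c(p, q, r)))
        stop("internal error: constructed distances (",
             paste(got, collapse = ", "), ") differ from the target (",
             paste(c(p, q, r), collapse = ", "), ")")
    attr(log, "moves") <- moves
    list(A = g$A, B = g$B, C = g$C, log = log)
}
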