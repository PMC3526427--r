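#' Build the breakpoint graph of two or more genomes
#'
#' Superposes the genomes' adjacency matchings, one colour each, on the
#' shared vertex set of \eqn{2n} gene extremities.
#'
#' @param genomes List of [Genome-class] objects (at least 2) with identical
#'   gene count; names become the colour labels (defaults to `A`, `B`, ...).
#' @return A [BreakpointGraph-class].
#' @examples
#' bg <- buildBreakpointGraph(list(A = parseGenome("(1)(2)"),
#'                                 B = parseGenome("(1, 2)")))
#' bg
#' @export
buildBreakpointGraph <- function(genomes) {
    if (!is.list(genomes) || length(genomes) < 2L)
        stop("a breakpoint graph needs at least 2 genomes")
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
        names(genomes) <- LETTERS[seq_along(genomes)]
    ns <- vapply(genomes, geneCount, integer(1L))
    if (length(unique(ns)) != 1L)
        stop("all genomes must share the same gene set 1..n; got n = ",
             paste(ns, collapse = ", "))
    new("BreakpointGraph", n = ns[[1L]],
        matchings = lapply(genomes, function(g) g@mate))
}

#' @describeIn geneCount Gene count of a breakpoint graph.
#' @export
setMethod("geneCount", "BreakpointGraph", function(x) x@n)

#' Colour labels of a breakpoint graph
#'
#' @param x A [BreakpointGraph-class].
#' @return Character vector of genome labels.
#' @export
graphColors <- function(x) names(x@matchings)

setMethod("show", "BreakpointGraph", function(object) {
    cat("BreakpointGraph on", 2L * object@n, "extremities (",
        object@n, "genes ), colours:",
        paste(graphColors(object), collapse = ", "), "\n")
})

# count alternating cycles of two mate vectors (the union of two perfect
# matchings on the same vertex set always decomposes into such cycles)
.cycleCountMates <- function(m1, m2) {
    N <- length(m1)
    visited <- logical(N)
    k <- 0L
    for (s in seq_len(N)) {
        if (visited[s]) next
        k <- k + 1L
        v <- s
        repeat {
            visited[v] <- TRUE
            w <- m1[v]
            visited[w] <- TRUE
            v <- m2[w]
            if (v == s) break
        }
    }
    k
}

#' Decompose one colour pair into alternating cycles
#'
#' Traverses the union of the two matchings. Each traversal starts at the
#' smallest unvisited extremity and first follows the edge of the
#' lexicographically smaller colour, which makes cycle indices and vertex
#' orders deterministic. A length-2 cycle is trivial (shared adjacency).
#'
#' @param x A [BreakpointGraph-class].
#' @param color1,color2 Two distinct colour labels present in `x`.
#' @return A [CycleDecomposition-class].
#' @name alternatingCycles
#' @examples
#' bg <- buildBreakpointGraph(list(A = parseGenome("(1)(2)"),
#'                                 B = parseGenome("(1, 2)")))
#' alternatingCycles(bg, "A", "B")
#' @export
setMethod("alternatingCycles", "BreakpointGraph",
          function(x, color1, color2) {
    cols <- graphColors(x)
    if (!(color1 %in% cols)) stop("unknown colour label: ", color1)
    if (!(color2 %in% cols)) stop("unknown colour label: ", color2)
    if (color1 == color2) stop("the two colours must differ")
    ord <- sort(c(color1, color2))
    m1 <- x@matchings[[ord[1L]]]
    m2 <- x@matchings[[ord[2L]]]
    N <- 2L * x@n
    cycleId <- integer(N)
    cycles <- list()
    for (s in seq_len(N)) {
        if (cycleId[s] > 0L) next
        id <- length(cycles) + 1L
        seqv <- integer(0L)
        v <- s
        repeat {
            cycleId[v] <- id
            seqv <- c(seqv, v)
            w <- m1[v]
            cycleId[w] <- id
            seqv <- c(seqv, w)
            v <- m2[w]
            if (v == s) break
        }
        cycles[[id]] <- seqv
    }
    new("CycleDecomposition", colors = ord, cycles = cycles,
        cycleId = cycleId)
})

#' Number of alternating cycles of a colour pair
#'
#' `c(A, B)` in the distance formula \eqn{d_{dcj}(A,B) = n - c(A,B)}.
#'
#' @param x A [BreakpointGraph-class] or a [CycleDecomposition-class].
#' @param ... Colour pair, passed to [alternatingCycles()] when `x` is a
#'   breakpoint graph.
#' @return Integer cycle count.
#' @examples
#' bg <- buildBreakpointGraph(list(parseGenome("(1)(2)"),
#'                                 parseGenome("(1, 2)")))
#' cycleCount(bg, "A", "B")
#' @export
cycleCount <- function(x, ...) {
    if (is(x, "CycleDecomposition")) return(length(x@cycles))
    length(alternatingCycles(x, ...)@cycles)
}

setMethod("show", "CycleDecomposition", function(object) {
    lens <- lengths(object@cycles)
    cat("CycleDecomposition ", object@colors[1L], "/", object@colors[2L],
        ": ", length(object@cycles), " cycle(s), lengths ",
        paste(lens, collapse = ", "), "\n", sep = "")
    for (i in seq_along(object@cycles)) {
        cat("  [", i, "] ",
            paste(extremityLabel(object@cycles[[i]]), collapse = " - "),
            "\n", sep = "")
    }
})

#' Is a breakpoint graph the identity breakpoint graph?
#'
#' True iff all colour matchings coincide, i.e. the graph consists of trivial
#' multicycles of parallel edges (all genomes identical).
#'
#' @param x A [BreakpointGraph-class].
#' @return Logical scalar.
#' @name isIdentityGraph
#' @examples
#' g <- parseGenome("(1, 2, 3)")
#' isIdentityGraph(buildBreakpointGraph(list(g, g)))
#' @export
setMethod("isIdentityGraph", "BreakpointGraph", function(x) {
    first <- x@matchings[[1L]]
    all(vapply(x@matchings[-1L], identical, logical(1L), y = first))
})

#' Export a breakpoint graph in DOT format
#'
#' Writes the coloured multigraph for inspection with Graphviz; the first
#' three colours are drawn red, blue, green. Layout is left to the renderer.
#'
#' @param x A [BreakpointGraph-class].
#' @param file Optional path; if omitted the DOT lines are returned.
#' @return (Invisibly) the character vector of DOT lines.
#' @export
writeBreakpointGraphDot <- function(x, file = NULL) {
    palette <- c("red", "blue", "green", "orange", "purple", "brown")
    cols <- graphColors(x)
    lines <- c("graph breakpointgraph {", "  node [shape=circle];")
    for (i in seq_along(cols)) {
        m <- x@matchings[[i]]
        v <- which(m > seq_along(m))
        lines <- c(lines, sprintf('  "%s" -- "%s" [color=%s, label="%s"];',
                                  extremityLabel(v), extremityLabel(m[v]),
                                  palette[(i - 1L) %% length(palette) + 1L],
                                  cols[i]))
    }
    lines <- c(lines, "}")
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}
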