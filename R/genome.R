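# Extremity encoding: tail(g) = 2g - 1, head(g) = 2g.  The implicit gene edge
# joins 2g-1 and 2g; genome adjacencies are a perfect matching superposed on
# these gene edges, so decoding always yields circular chromosomes.

#' Extremity helpers
#'
#' Map between gene identifiers and extremity vertex indices. Gene \eqn{g}
#' has tail \eqn{2g-1} and head \eqn{2g}.
#'
#' @param g Integer vector of gene identifiers (1-based).
#' @param v Integer vector of extremity vertices.
#' @return `tailOf`/`headOf` return vertex indices; `geneOf` the gene a vertex
#'   belongs to; `extremityLabel` the conventional label, e.g. `"3t"`, `"3h"`.
#' @examples
#' tailOf(3); headOf(3); geneOf(5:6); extremityLabel(1:4)
#' @export
tailOf <- function(g) 2L * as.integer(g) - 1L

#' @rdname tailOf
#' @export
headOf <- function(g) 2L * as.integer(g)

#' @rdname tailOf
#' @export
geneOf <- function(v) (as.integer(v) + 1L) %/% 2L

#' @rdname tailOf
#' @export
extremityLabel <- function(v) {
    v <- as.integer(v)
    paste0(geneOf(v), ifelse(v %% 2L == 1L, "t", "h"))
}

#' Construct a Genome from a mate vector
#'
#' Low-level constructor; most users will call [parseGenome()] instead.
#'
#' @param mate Integer vector of length \eqn{2n}: a fixed-point-free
#'   involution pairing the extremities.
#' @return A [Genome-class] object.
#' @examples
#' Genome(c(2L, 1L, 4L, 3L))   # the genome (1)(2)
#' @export
Genome <- function(mate) {
    mate <- as.integer(mate)
    new("Genome", n = length(mate) %/% 2L, mate = mate)
}

#' @describeIn geneCount Number of genes of a genome.
#' @param x Object to query.
#' @export
setMethod("geneCount", "Genome", function(x) x@n)

#' Adjacencies of a genome
#'
#' @param x A [Genome-class].
#' @return Integer matrix with one row per adjacency, columns the two
#'   extremities (smaller first), rows ordered by the first column.
#' @name adjacencies
#' @examples
#' adjacencies(parseGenome("(1, 2)"))
#' @export
setMethod("adjacencies", "Genome", function(x) {
    v <- which(x@mate > seq_along(x@mate))
    cbind(v, x@mate[v], deparse.level = 0L)
})

setMethod("show", "Genome", function(object) {
    cat("Genome on", object@n, "genes:",
        formatGenome(object), "\n")
})

#' @export
setMethod("==", signature("Genome", "Genome"), function(e1, e2) {
    e1@n == e2@n && identical(e1@mate, e2@mate)
})

#' @export
setMethod("!=", signature("Genome", "Genome"), function(e1, e2) !(e1 == e2))

# outgoing/incoming extremity of a signed gene when traversed left-to-right:
# +g is entered at its tail and left at its head, -g the other way round.
.outgoing <- function(s) ifelse(s > 0L, headOf(s), tailOf(-s))
.incoming <- function(s) ifelse(s > 0L, tailOf(s), headOf(-s))

# turn a list of signed-gene chromosome vectors into a Genome
.chromosomesToGenome <- function(chroms, n = NULL, what = "genome") {
    genes <- unlist(lapply(chroms, abs))
    if (length(genes) == 0L)
        stop(what, " contains no genes")
    if (any(genes == 0L))
        stop("gene id 0 is not allowed")
    if (anyDuplicated(genes))
        stop("duplicate gene id: ", genes[duplicated(genes)][1L])
    if (is.null(n)) {
        n <- max(genes)
    } else {
        n <- as.integer(n)
        if (any(genes > n))
            stop("gene id out of range 1..", n, ": ", max(genes))
    }
    if (length(genes) != n) {
        missing <- setdiff(seq_len(n), genes)
        stop("missing gene id: ", missing[1L])
    }
    mate <- integer(2L * n)
    for (ch in chroms) {
        from <- .outgoing(ch)
        to <- .incoming(c(ch[-1L], ch[1L]))
        mate[from] <- to
        mate[to] <- from
    }
    Genome(mate)
}

#' Parse a genome written in signed-cycle notation
#'
#' Reads strings such as `"(1, -6, -7)(2, 5, 4, 3)"`: each parenthesised group
#' is one circular chromosome given as signed gene identifiers; a positive
#' gene is traversed tail-to-head, a negative one head-to-tail. Consecutive
#' genes `x, y` (cyclically) contribute the adjacency between the outgoing
#' extremity of `x` and the incoming extremity of `y`.
#'
#' @param text Character scalar in cycle notation. Whitespace is ignored.
#' @param n Optional gene count; defaults to the largest absolute gene id.
#'   Every gene `1..n` must appear exactly once.
#' @return A [Genome-class].
#' @examples
#' parseGenome("(1, -2)")
#' parseGenome("(1)(2)(3)")
#' @export
parseGenome <- function(text, n = NULL) {
    stopifnot(is.character(text), length(text) == 1L)
    s <- gsub("[[:space:]]", "", text)
    if (!nzchar(s))
        stop("empty genome string")
    m <- gregexpr("\\(([^()]*)\\)", s)[[1L]]
    if (m[1L] == -1L)
        stop("no parenthesised chromosome found in: ", text)
    groups <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1L]]
    if (sum(nchar(groups)) != nchar(s))
        stop("malformed cycle notation: ", text)
    chroms <- lapply(groups, function(gr) {
        inner <- substr(gr, 2L, nchar(gr) - 1L)
        if (!nzchar(inner))
            stop("empty chromosome '()' in: ", text)
        toks <- strsplit(inner, ",", fixed = TRUE)[[1L]]
        vals <- suppressWarnings(as.integer(toks))
        if (anyNA(vals) || any(toks == ""))
            stop("invalid gene token '", toks[is.na(vals) | toks == ""][1L],
                 "' in: ", text)
        vals
    })
    .chromosomesToGenome(chroms, n, what = text)
}

#' Decode a genome into canonical circular chromosomes
#'
#' Traverses the alternation of implicit gene edges and adjacencies. Each
#' chromosome is reported starting at its smallest gene id with positive sign
#' (the canonical representative of its rotation/reflection class) and
#' chromosomes are ordered by their smallest gene.
#'
#' @param x A [Genome-class].
#' @return List of integer vectors of signed gene ids, one per chromosome.
#' @name decodeChromosomes
#' @examples
#' decodeChromosomes(parseGenome("(-2, -1)"))  # canonicalises to (1, 2)
#' @export
setMethod("decodeChromosomes", "Genome", function(x) {
    mate <- x@mate
    seen <- logical(x@n)
    chroms <- list()
    for (g in seq_len(x@n)) {
        if (seen[g]) next
        ch <- integer(0L)
        cur <- g          # enter gene 'cur' with positive orientation
        exit <- headOf(g)
        repeat {
            seen[abs(cur)] <- TRUE
            ch <- c(ch, cur)
            nxt <- mate[exit]
            gn <- geneOf(nxt)
            if (gn == g) break
            if (nxt %% 2L == 1L) {     # entered at tail: positive
                cur <- gn
                exit <- headOf(gn)
            } else {                   # entered at head: negative
                cur <- -gn
                exit <- tailOf(gn)
            }
        }
        chroms[[length(chroms) + 1L]] <- ch
    }
    chroms
})

#' Format a genome in cycle notation
#'
#' @param x A [Genome-class].
#' @return Character scalar such as `"(1, -2)(3, 4)"` in the canonical form
#'   produced by [decodeChromosomes()].
#' @examples
#' formatGenome(parseGenome("(2,1)(4,3)"))
#' @export
formatGenome <- function(x) {
    paste(vapply(decodeChromosomes(x),
                 function(ch) paste0("(", paste(ch, collapse = ", "), ")"),
                 character(1L)),
          collapse = "")
}

#' Read and write GRIMM multi-genome files (circular dialect)
#'
#' The circular GRIMM dialect: genomes start with a header line `>name`;
#' each following non-empty line is one circular chromosome written as
#' whitespace-separated signed gene ids terminated by `@`. The linear
#' terminator `$` is rejected (only circular genomes are modelled). All
#' genomes in one file must use the same gene set `1..n`.
#'
#' @param con File path, connection, or character vector of lines.
#' @return `readGrimm`: named list of [Genome-class] objects.
#' @examples
#' g <- readGrimm(c(">A", "1 @", "2 @", ">B", "1 2 @"))
#' writeGrimm(g)
#' @export
readGrimm <- function(con) {
    lines <- if (is.character(con) && length(con) > 1L) con
             else if (is.character(con) && !file.exists(con) &&
                      grepl("\n", con)) strsplit(con, "\n")[[1L]]
             else readLines(con)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines) || !startsWith(lines[1L], ">"))
        stop("GRIMM input must start with a '>name' header")
    name <- NULL
    chroms <- list()
    out <- list()
    flush <- function() {
        if (!is.null(name)) {
            if (!length(chroms))
                stop("genome '", name, "' has no chromosomes")
            out[[name]] <<- .chromosomesToGenome(chroms, what = name)
        }
    }
    for (ln in lines) {
        if (startsWith(ln, ">")) {
            flush()
            name <- trimws(substring(ln, 2L))
            if (!nzchar(name)) stop("empty genome name in GRIMM header")
            chroms <- list()
        } else {
            toks <- strsplit(ln, "[[:space:]]+")[[1L]]
            if (any(toks == "$"))
                stop("linear chromosome terminator '$' is not supported; ",
                     "only circular chromosomes ('@') are modelled")
            term <- which(toks == "@")
            if (length(term) != 1L || term != length(toks))
                stop("chromosome line must end with '@': ", ln)
            vals <- suppressWarnings(as.integer(toks[-term]))
            if (anyNA(vals) || !length(vals))
                stop("invalid chromosome line: ", ln)
            chroms[[length(chroms) + 1L]] <- vals
        }
    }
    flush()
    ns <- vapply(out, geneCount, integer(1L))
    if (length(unique(ns)) > 1L)
        stop("genomes use different gene sets: n = ",
             paste(unique(ns), collapse = ", "))
    out
}

#' @rdname readGrimm
#' @param genomes Named list of [Genome-class] objects.
#' @param file Optional path or connection; if omitted the lines are returned.
#' @return `writeGrimm`: (invisibly) the character vector of lines written.
#' @export
writeGrimm <- function(genomes, file = NULL) {
    stopifnot(is.list(genomes), !is.null(names(genomes)),
              all(nzchar(names(genomes))))
    lines <- unlist(lapply(names(genomes), function(nm) {
        g <- genomes[[nm]]
        c(paste0(">", nm),
          vapply(decodeChromosomes(g),
                 function(ch) paste(c(ch, "@"), collapse = " "),
                 character(1L)))
    }))
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}

# run expr with a temporarily seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
}

#' Draw a uniformly random circular genome
#'
#' Pairs a seeded random shuffle of the \eqn{2n} extremities sequentially,
#' which samples uniformly from the \eqn{(2n-1)!!} perfect matchings (and
#' hence uniformly from all circular genomes on `n` genes).
#'
#' @param n Gene count, at least 1.
#' @param seed Optional integer seed; when given, the draw is deterministic
#'   and the caller's RNG state is left untouched.
#' @return A [Genome-class].
#' @examples
#' randomGenome(5, seed = 1)
#' @export
randomGenome <- function(n, seed = NULL) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be at least 1")
    .withSeed(seed, {
        ord <- sample.int(2L * n)
        mate <- integer(2L * n)
        odd <- ord[seq(1L, 2L * n, by = 2L)]
        even <- ord[seq(2L, 2L * n, by = 2L)]
        mate[odd] <- even
        mate[even] <- odd
        Genome(mate)
    })
}

#' Identity genome (1)(2)...(n)
#'
#' Each gene forms its own single-gene circular chromosome; this is the
#' starting genome for triple construction.
#'
#' @param n Gene count.
#' @return A [Genome-class].
#' @examples
#' identityGenome(4)
#' @export
identityGenome <- function(n) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be at least 1")
    v <- seq_len(2L * n)
    mate <- ifelse(v %% 2L == 1L, v + 1L, v - 1L)
    Genome(as.integer(mate))
}

#' Enumerate all perfect matchings on 2n extremities
#'
#' There are \eqn{(2n-1)!!} of them, i.e. all circular genomes on `n` genes.
#' Used by the brute-force median solver and by counting tests; intended for
#' small `n` only.
#'
#' @param n Gene count.
#' @return List of mate vectors (each convertible with [Genome()]).
#' @examples
#' length(allPerfectMatchings(3))  # 15
#' @export
allPerfectMatchings <- function(n) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("'n' must be at least 1")
    N <- 2L * n
    res <- vector("list", prod(seq(1L, N - 1L, by = 2L)))
    k <- 0L
    rec <- function(mate, free) {
        if (!length(free)) {
            k <<- k + 1L
            res[[k]] <<- mate
            return(invisible())
        }
        u <- free[1L]
        rest <- free[-1L]
        for (v in rest) {
            mate[u] <- v
            mate[v] <- u
            rec(mate, rest[rest != v])
        }
    }
    rec(integer(N), seq_len(N))
    res
}
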