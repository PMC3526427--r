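#' Number of genes
#'
#' @param x Object to query (a genome or breakpoint graph).
#' @return Integer gene count `n`.
#' @examples
#' geneCount(parseGenome("(1, 2, 3)"))
#' @export
setGeneric("geneCount", function(x) standardGeneric("geneCount"))

#' @rdname adjacencies
#' @export
setGeneric("adjacencies", function(x) standardGeneric("adjacencies"))

#' @rdname decodeChromosomes
#' @export
setGeneric("decodeChromosomes", function(x) standardGeneric("decodeChromosomes"))

#' @rdname alternatingCycles
#' @export
setGeneric("alternatingCycles",
           function(x, color1, color2) standardGeneric("alternatingCycles"))

#' @rdname isIdentityGraph
#' @export
setGeneric("isIdentityGraph", function(x) standardGeneric("isIdentityGraph"))

#' Convert to a concrete DCJ move
#'
#' @param x Object to convert (e.g. a [StrongPair-class]).
#' @param ... Further arguments for methods.
#' @return A [DcjMove-class].
#' @export
setGeneric("asDcjMove", function(x, ...) standardGeneric("asDcjMove"))

#' Median score of a median result
#'
#' @param x A [MedianResult-class].
#' @return Integer exact median score.
#' @export
setGeneric("medianScore", function(x) standardGeneric("medianScore"))

#' Median genome(s) of a median result
#'
#' @param x A [MedianResult-class].
#' @return List of [Genome-class] objects attaining the median score.
#' @export
setGeneric("medianGenomes", function(x) standardGeneric("medianGenomes"))

#' Pairwise distances of a score triple
#'
#' @param x A [ScoreTriple-class].
#' @return Named integer vector `c(AB =, AC =, BC =)`.
#' @export
setGeneric("tsDistances", function(x) standardGeneric("tsDistances"))

#' Triangle score of a score triple
#'
#' @param x A [ScoreTriple-class].
#' @return Integer sum of the three pairwise distances.
#' @export
setGeneric("tsSum", function(x) standardGeneric("tsSum"))
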