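Package: dcjtriad
Title: Pairwise Distances and Exact Medians of Three Circular Genomes
    Under the Double-Cut-and-Join Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing three circular genomes under the
    Double-Cut-and-Join (DCJ, 2-break) rearrangement model. Genomes over a
    shared gene set are represented as perfect matchings on gene
    extremities; the package builds breakpoint graphs, decomposes colour
    pairs into alternating cycles, computes DCJ distances and the triangle
    score (sum of pairwise distances), finds and applies strong DCJs
    (rearrangements that increase the triangle score by 2), constructs
    genome triples with prescribed pairwise distances, and solves the
    NP-hard DCJ median-of-three problem exactly by exhaustive enumeration
    (small gene counts) or branch-and-bound over perfect matchings
    (moderate gene counts), together with lower and upper bounds on the
    median score in terms of the triangle score. Genomes are read and
    written in signed-cycle notation and in the circular dialect of the
    GRIMM multi-genome format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
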