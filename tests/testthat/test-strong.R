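test_that("a strong pair is found in the two-block triple and applies", {
    rb <- exampleRigidBlocks()$genomes
    p <- findStrongPair("A", rb$A, rb$B, rb$C)
    expect_s4_class(p, "StrongPair")
    # the first pair in scan order: the self-adjacencies of genes 1 and 3,
    # which sit in different cycles of both decompositions
    expect_setequal(geneOf(as.vector(p@edges)), c(1L, 3L))
    a2 <- applyStrongDcj("A", rb$A, rb$B, rb$C, p)
    expect_identical(tsSum(triangleScore(a2, rb$B, rb$C)), 8L)
})

test_that("no strong pair exists at maximal pairwise distances", {
    ut <- exampleUnitTriangle()$genomes   # n = 2, all distances = n - 1
    for (mover in c("A", "B", "C"))
        expect_null(findStrongPair(mover, ut$A, ut$B, ut$C))
})

test_that("identical genomes always admit a strong pair (trivial cycles)", {
    g <- identityGenome(3)
    p <- findStrongPair("A", g, g, g)
    expect_s4_class(p, "StrongPair")
    a2 <- applyStrongDcj("A", g, g, g, p)
    expect_identical(tsSum(triangleScore(a2, g, g)), 2L)
    expect_identical(dcjDistance(a2, g), 1L)
})

test_that("strong pairs exist and raise ts by 2 whenever both mover
           distances are submaximal", {
    set.seed(108)
    found <- 0L
    i <- 0L
    while (found < 300L) {
        i <- i + 1L
        n <- sample(3:7, 1L)
        tr <- rTriple(n, seed = 40000 + i)
        movers <- Filter(function(lab) {
            others <- setdiff(c("A", "B", "C"), lab)
            all(vapply(others, function(o)
                dcjDistance(tr[[lab]], tr[[o]]), integer(1L)) < n - 1L)
        }, c("A", "B", "C"))
        if (!length(movers)) next
        lab <- movers[[1L]]
        found <- found + 1L
        p <- findStrongPair(lab, tr$A, tr$B, tr$C)
        expect_s4_class(p, "StrongPair")
        before <- tsSum(triangleScore(tr$A, tr$B, tr$C))
        tr[[lab]] <- applyStrongDcj(lab, tr$A, tr$B, tr$C, p)
        expect_identical(tsSum(triangleScore(tr$A, tr$B, tr$C)),
                         before + 2L)
    }
})

test_that("applying a non-strong pair is rejected", {
    rb <- exampleRigidBlocks()$genomes
    adj <- adjacencies(rb$A)
    # the self-adjacencies of genes 1 and 2 share their AB-cycle
    fake <- new("StrongPair", mover = "A", edges = adj[1:2, ],
                cyclesFirst = c(1L, 2L), cyclesSecond = c(1L, 2L))
    expect_error(applyStrongDcj("A", rb$A, rb$B, rb$C, fake),
                 "not a strong pair")
    expect_error(applyStrongDcj("B", rb$B, rb$A, rb$C,
                                findStrongPair("A", rb$A, rb$B, rb$C)),
                 "found for mover")
})

test_that("isStrong classifies moves by their ts delta", {
    sf <- exampleStrongFusion()$genomes
    expect_true(isStrong(strongFusionMove(), sf$A, sf$B, sf$C))
    # at all-maximal distances no move can push ts beyond 3(n-1)
    ut <- exampleUnitTriangle()$genomes
    for (lab in c("A", "B", "C"))
        for (m in enumerateDcjs(ut[[lab]], target = lab))
            expect_false(isStrong(m, ut$A, ut$B, ut$C))
    # the inverse of a strong move decreases ts by 2
    g <- identityGenome(3)
    p <- findStrongPair("A", g, g, g)
    a2 <- applyStrongDcj("A", g, g, g, p)
    inv <- invertDcj(asDcjMove(p))
    expect_identical(tsDelta(a2, g, g, inv), -2L)
    expect_false(isStrong(inv, a2, g, g))
})

test_that("ts-decreasing moves exist after a strong move but not for the
           rigid blocks", {
    rb <- exampleRigidBlocks()$genomes
    expect_false(existsTsDecreasingDcj(rb$A, rb$B, rb$C))
    # the largest achievable decrease there is 1
    deltas <- unlist(lapply(c("A", "B", "C"), function(lab)
        vapply(enumerateDcjs(rb[[lab]], target = lab),
               function(m) tsDelta(rb$A, rb$B, rb$C, m), integer(1L))))
    expect_identical(min(deltas), -1L)
    g <- identityGenome(3)
    expect_false(existsTsDecreasingDcj(g, g, g))
    a2 <- applyStrongDcj("A", g, g, g, findStrongPair("A", g, g, g))
    expect_true(existsTsDecreasingDcj(a2, g, g))
})

test_that("triple construction hits exact distances with the promised
           number of strong moves", {
    # exhaustive (p, q, r) grid for n up to 5
    for (n in 2:5) {
        grid <- expand.grid(p = 0:(n - 1L), q = 0:(n - 1L), r = 0:(n - 1L))
        for (row in seq_len(nrow(grid))) {
            p <- grid$p[row]; q <- grid$q[row]; r <- grid$r[row]
            valid <- (p + q >= r && p + r >= q && q + r >= p) &&
                !((p + q + r) %% 2L == 1L && min(p, q, r) == 0L)
            if (!valid) {
                expect_error(constructTriple(p, q, r, n))
                next
            }
            tr <- constructTriple(p, q, r, n)
            expect_identical(c(dcjDistance(tr$A, tr$B),
                               dcjDistance(tr$A, tr$C),
                               dcjDistance(tr$B, tr$C)),
                             c(p, q, r))
            expect_identical(sum(tr$log$strong), (p + q + r) %/% 2L)
            expect_identical(nrow(tr$log) - sum(tr$log$strong),
                             (p + q + r) %% 2L)
        }
    }
})

test_that("the construction log tracks the triangle score move by move", {
    tr <- constructTriple(2, 3, 3, n = 5)
    g <- list(A = identityGenome(5), B = identityGenome(5),
              C = identityGenome(5))
    ts <- 0L
    for (k in seq_along(attr(tr$log, "moves"))) {
        m <- attr(tr$log, "moves")[[k]]
        g[[m@target]] <- applyDcj(g[[m@target]], m)
        ts <- ts + (if (tr$log$strong[k]) 2L else 1L)
        expect_identical(tsSum(triangleScore(g$A, g$B, g$C)), ts)
    }
    expect_true(g$A == tr$A && g$B == tr$B && g$C == tr$C)
})

test_that("degenerate and invalid specs are handled", {
    tr0 <- constructTriple(0, 0, 0, n = 3)
    expect_true(tr0$A == tr0$B && tr0$B == tr0$C)
    expect_identical(nrow(tr0$log), 0L)
    # (1,1,1) on 2 genes reproduces the unit-triangle breakpoint graph
    tr1 <- constructTriple(1, 1, 1, n = 2)
    ut <- exampleUnitTriangle()$genomes
    expect_true(tr1$A == ut$A && tr1$B == ut$B && tr1$C == ut$C)
    expect_error(constructTriple(1, 1, 3, n = 4), "triangle inequality")
    expect_error(constructTriple(0, 1, 2, n = 5), "triangle inequality")
    expect_error(constructTriple(2, 2, 2, n = 2), "0, 1")
    expect_error(constructTriple(0, 1, 1, n = 5), NA)
    # an odd sum with a zero distance always violates the triangle
    # inequality outright (zero distance forces the other two equal)
    expect_error(constructTriple(0, 2, 3, n = 6), "triangle inequality")
})
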