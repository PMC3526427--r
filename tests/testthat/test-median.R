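test_that("median bounds follow from the triangle score", {
    rb <- exampleRigidBlocks()$genomes
    expect_identical(medianBounds(rb$A, rb$B, rb$C),
                     c(lower = 3L, upperTwoThirds = 4L, upperMinPair = 4L))
    sf <- exampleStrongFusion()$genomes
    expect_identical(medianBounds(sf$A, sf$B, sf$C),
                     c(lower = 12L, upperTwoThirds = 16L, upperMinPair = 16L))
    g <- randomGenome(4, seed = 11)
    expect_identical(medianBounds(g, g, g),
                     c(lower = 0L, upperTwoThirds = 0L, upperMinPair = 0L))
})

test_that("brute force finds the exact median of the small examples", {
    rb <- exampleRigidBlocks()$genomes
    res <- medianBruteforce(rb$A, rb$B, rb$C)
    expect_identical(medianScore(res), 4L)
    expect_identical(res@nodesExplored, 105)
    ut <- exampleUnitTriangle()$genomes
    res1 <- medianBruteforce(ut$A, ut$B, ut$C)
    expect_identical(medianScore(res1), 2L)
    # an identical triple has itself as unique median
    m <- randomGenome(4, seed = 12)
    resm <- medianBruteforce(m, m, m, allOptima = TRUE)
    expect_identical(medianScore(resm), 0L)
    expect_length(medianGenomes(resm), 1L)
    expect_true(medianGenomes(resm)[[1L]] == m)
    expect_error(medianBruteforce(randomGenome(8, seed = 1),
                                  randomGenome(8, seed = 2),
                                  randomGenome(8, seed = 3)),
                 "medianBnb")
})

test_that("every reported median attains the reported score", {
    rb <- exampleRigidBlocks()$genomes
    res <- medianBruteforce(rb$A, rb$B, rb$C, allOptima = TRUE)
    for (k in seq_along(medianGenomes(res))) {
        m <- medianGenomes(res)[[k]]
        tot <- dcjDistance(rb$A, m) + dcjDistance(rb$B, m) +
            dcjDistance(rb$C, m)
        expect_identical(tot, medianScore(res))
        expect_identical(unname(res@distances[k, ]),
                         c(dcjDistance(rb$A, m), dcjDistance(rb$B, m),
                           dcjDistance(rb$C, m)))
    }
})

test_that("branch-and-bound equals brute force on random triples", {
    set.seed(109)
    for (i in 1:100) {
        n <- sample(2:5, 1L)
        tr <- rTriple(n, seed = 50000 + i)
        bf <- medianBruteforce(tr$A, tr$B, tr$C)
        bb <- medianBnb(tr$A, tr$B, tr$C)
        expect_identical(medianScore(bb), medianScore(bf))
    }
})

test_that("the exact median respects the triangle-score bounds", {
    set.seed(110)
    for (i in 1:100) {
        n <- sample(2:5, 1L)
        tr <- rTriple(n, seed = 60000 + i)
        ms <- medianScore(medianBnb(tr$A, tr$B, tr$C))
        b <- medianBounds(tr$A, tr$B, tr$C)
        expect_gte(ms, b[["lower"]])
        expect_lte(ms, b[["upperTwoThirds"]])
        expect_lte(ms, b[["upperMinPair"]])
    }
})

test_that("one DCJ changes the median score by at most 1", {
    set.seed(111)
    for (i in 1:100) {
        n <- sample(2:4, 1L)
        tr <- rTriple(n, seed = 70000 + i)
        lab <- sample(c("A", "B", "C"), 1L)
        moves <- enumerateDcjs(tr[[lab]], target = lab)
        if (!length(moves)) next
        m <- moves[[sample.int(length(moves), 1L)]]
        expect_true(msDeltaUnderMove(tr$A, tr$B, tr$C, m) %in% (-1L:1L))
    }
})

test_that("strong walks attain the lower bound and one strong move from
           identity raises ms by 1", {
    for (n in 3:5) {
        for (k in c(2L, 3L)) {
            tr <- randomTriple(n, "strong-walk", k = k)
            expect_identical(tsSum(triangleScore(tr$A, tr$B, tr$C)), 2L * k)
            expect_identical(medianScore(medianBnb(tr$A, tr$B, tr$C)), k)
            expect_true(attainsLowerBound(tr$A, tr$B, tr$C))
        }
    }
    g <- identityGenome(3)
    p <- findStrongPair("A", g, g, g)
    expect_identical(msDeltaUnderMove(g, g, g, asDcjMove(p)), 1L)
    expect_true(attainsLowerBound(g, g, g))
    # the rigid-block triple misses the bound by one
    rb <- exampleRigidBlocks()$genomes
    expect_false(attainsLowerBound(rb$A, rb$B, rb$C))
})

test_that("triples at the lower bound unwind to one genome by halving ts", {
    # reverse of the strong-walk characterisation: when ms = ts/2, a greedy
    # sequence of ts-decreasing-by-2 moves reaches a single genome in
    # exactly ms steps
    set.seed(112)
    checked <- 0L
    i <- 0L
    while (checked < 60L) {
        i <- i + 1L
        tr <- rTriple(3L, seed = 80000 + i)
        ts <- tsSum(triangleScore(tr$A, tr$B, tr$C))
        if (ts %% 2L == 1L ||
            medianScore(medianBruteforce(tr$A, tr$B, tr$C)) != ts %/% 2L)
            next
        checked <- checked + 1L
        steps <- 0L
        while (tsSum(triangleScore(tr$A, tr$B, tr$C)) > 0L) {
            advanced <- FALSE
            for (lab in c("A", "B", "C")) {
                for (m in enumerateDcjs(tr[[lab]], target = lab)) {
                    if (tsDelta(tr$A, tr$B, tr$C, m) == -2L) {
                        tr[[lab]] <- applyDcj(tr[[lab]], m)
                        steps <- steps + 1L
                        advanced <- TRUE
                        break
                    }
                }
                if (advanced) break
            }
            expect_true(advanced)   # a -2 move must exist at the bound
            if (!advanced) break
        }
        expect_identical(steps, ts %/% 2L)
        expect_true(tr$A == tr$B && tr$B == tr$C)
    }
})

test_that("chained rigid blocks push ms above the lower bound by n", {
    tr1 <- blockFamily(1)
    expect_identical(medianScore(medianBruteforce(tr1$A, tr1$B, tr1$C)), 4L)
    expect_identical(tsSum(triangleScore(tr1$A, tr1$B, tr1$C)), 6L)
    tr2 <- blockFamily(2)
    res2 <- medianBnb(tr2$A, tr2$B, tr2$C)
    expect_identical(medianScore(res2), 8L)
    expect_identical(tsSum(triangleScore(tr2$A, tr2$B, tr2$C)), 12L)
    # ms - ts/2 = number of blocks
    expect_identical(8L - 12L %/% 2L, 2L)
})

test_that("a greedy -2 unwind gets stuck on the rigid blocks", {
    # ts = 6 yet no sequence of three DCJs reaches a single genome: the
    # first -2 move does not even exist
    rb <- exampleRigidBlocks()$genomes
    expect_false(existsTsDecreasingDcj(rb$A, rb$B, rb$C))
    expect_identical(medianScore(medianBruteforce(rb$A, rb$B, rb$C)) -
                         tsSum(triangleScore(rb$A, rb$B, rb$C)) %/% 2L, 1L)
})
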