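# Independent oracles used to cross-check the package's formula-based code.
# They work on raw mate vectors and deliberately avoid the package's
# distance/cycle routines.

# Greedy constructive sorting: transform matching 'ma' into 'mb' by repeatedly
# picking a target adjacency (x, y) of 'mb' not yet present in 'ma' and
# installing it with one 2-break.  Each such step is a valid DCJ and the
# number of steps taken is an upper bound on the DCJ distance that in fact
# equals it (each step raises the shared-adjacency... cycle count by one).
greedySortSteps <- function(ma, mb) {
    steps <- 0L
    repeat {
        diff <- which(ma != mb)
        if (!length(diff)) return(steps)
        x <- diff[1L]
        y <- mb[x]
        u <- ma[x]
        v <- ma[y]
        # 2-break: remove {x,u} and {y,v}, add {x,y} and {u,v}
        ma[x] <- y; ma[y] <- x
        ma[u] <- v; ma[v] <- u
        steps <- steps + 1L
    }
}

# uniform random triple drawn with plain base R, for property loops
rTriple <- function(n, seed) {
    randomTriple(n, "uniform", seed = seed)
}

# the single fusion turning the two-chromosome 11-gene genome B of the
# strong-fusion example into the single cycle (1, 2, ..., 11):
# B has {1h,8t} and {7h,2t}; B' replaces them by {1h,2t} and {7h,8t}
strongFusionMove <- function() {
    DcjMove(rbind(c(headOf(1), tailOf(8)), c(headOf(7), tailOf(2))),
            rbind(c(headOf(1), tailOf(2)), c(headOf(7), tailOf(8))),
            target = "B")
}

expect_valid_genome <- function(g) {
    expect_s4_class(g, "Genome")
    expect_true(validObject(g))
}
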