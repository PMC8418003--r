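test_that("initial scores follow the seed-emphasis formula and sum to 1", {
    net <- mkNetwork(c(A = 1, B = 1, C = 1),
        data.frame(from = c("A", "B"), to = c("B", "C"),
            weight = c(1, 1)))
    expect_equal(unname(initialScores(net, "A", h = 1)), rep(1 / 3, 3))
    s2 <- initialScores(net, "A", h = 2)           # Z = 2 + 1 + 1 = 4
    expect_equal(unname(s2), c(0.5, 0.25, 0.25))
    expect_equal(sum(s2), 1, tolerance = 1e-12)

    # global rescaling of vertex weights cancels in the normalization
    net2 <- mkNetwork(c(A = 2, B = 2, C = 2), edgeWeights(net))
    expect_equal(initialScores(net2, "A", h = 2), s2)

    expect_error(initialScores(net, c("X", "Y")),
        class = "netprop_disjoint_seed_error")
    expect_message(initialScores(net, c("A", "X"), h = 1),
        "absent from network")
})

test_that("transition matrix is column-normalized with zero columns for isolates", {
    # U's neighbors: A (w=1), B (w=3); C isolated
    net <- mkNetwork(c(A = 1, B = 1, C = 1, U = 1),
        data.frame(from = c("A", "B"), to = c("U", "U"),
            weight = c(1, 3) / 3))  # weights in [0,1]
    TM <- transitionMatrix(net)
    expect_equal(TM["A", "U"], 0.25)
    expect_equal(TM["B", "U"], 0.75)
    expect_equal(sum(TM[, "C"]), 0)
    expect_equal(unname(Matrix::colSums(TM)[c("A", "B", "U")]),
        c(1, 1, 1), tolerance = 1e-14)

    pair <- mkNetwork(c(A = 1, B = 1),
        data.frame(from = "A", to = "B", weight = 0.5))
    TMp <- transitionMatrix(pair)
    expect_equal(TMp["B", "A"], 1)
    expect_equal(TMp["A", "B"], 1)

    # neighbors but all-zero incident weights -> zero column + warning
    zer <- mkNetwork(c(A = 1, B = 1),
        data.frame(from = "A", to = "B", weight = 0))
    expect_warning(TMz <- transitionMatrix(zer), "all-zero")
    expect_equal(sum(abs(TMz)), 0)
})

test_that("recurrence fixed points match hand-solved cases", {
    pair <- mkNetwork(c(A = 1, B = 1),
        data.frame(from = "A", to = "B", weight = 1))
    TM <- transitionMatrix(pair)
    s0 <- c(A = 1, B = 0)

    # k = 1: propagation disabled, S = S0 after one step
    r1 <- propagate(TM, s0, propagationConfig(k = 1))
    expect_equal(unname(r1$scores), c(1, 0))

    # k = 0.5: solve S1 = 0.5 S2 + 0.5, S2 = 0.5 S1 -> (2/3, 1/3)
    r <- propagate(TM, s0, propagationConfig(k = 0.5))
    expect_equal(unname(r$scores), c(2 / 3, 1 / 3), tolerance = 1e-7)
    expect_equal(unname(solveDirect(TM, s0, 0.5)), c(2 / 3, 1 / 3),
        tolerance = 1e-12)

    # two isolated vertices: T = 0, fixed point k * S0 (mass loss)
    iso <- mkNetwork(c(A = 1, B = 1),
        data.frame(from = character(), to = character(),
            weight = numeric()))
    TMi <- transitionMatrix(iso)
    ri <- propagate(TMi, c(A = 0.5, B = 0.5), propagationConfig(k = 0.5))
    expect_equal(unname(ri$scores), c(0.25, 0.25), tolerance = 1e-7)
})

test_that("iterative propagation agrees with the direct solve", {
    for (i in 1:10) {
        net <- randomNetwork(50, 120, seed = 100 + i)
        TM <- transitionMatrix(net)
        s0 <- initialScores(net, vertexNames(net)[1:3], h = 2)
        k <- c(0.1, 0.3, 0.5, 0.7, 0.9)[(i %% 5) + 1]
        it <- propagate(TM, s0, propagationConfig(k = k))$scores
        dir <- solveDirect(TM, s0, k)
        expect_lt(sum(abs(it - dir)), 1e-6)
    }
})

test_that("L1 residual contracts by at least (1 - k) per iteration", {
    for (i in 1:5) {
        net <- randomNetwork(80, 200, seed = 200 + i)
        TM <- transitionMatrix(net)
        s0 <- initialScores(net, vertexNames(net)[1:4], h = 3)
        k <- 0.2 + 0.15 * i
        res <- propagate(TM, s0, propagationConfig(k = k))$residuals
        ratios <- res[-1] / res[-length(res)]
        expect_true(all(ratios <= (1 - k) + 1e-10))
    }
})

test_that("score mass is conserved without zero columns, bounded with them", {
    # connected network: every column stochastic, sum S stays 1
    net <- randomNetwork(40, 200, seed = 42)  # dense enough: no isolates
    TM <- transitionMatrix(net)
    expect_true(all(abs(Matrix::colSums(TM) - 1) < 1e-12))
    s0 <- initialScores(net, vertexNames(net)[1:2], h = 2)
    k <- 0.5
    s <- as.numeric(s0)
    for (j in 1:50) {
        s <- (1 - k) * as.numeric(TM %*% s) + k * as.numeric(s0)
        expect_equal(sum(s), 1, tolerance = 1e-10)
    }

    # with isolated vertices, total mass decreases monotonically to >= k
    iso <- mkNetwork(c(A = 1, B = 1, C = 1),
        data.frame(from = "A", to = "B", weight = 1))
    TMi <- transitionMatrix(iso)
    s0i <- initialScores(iso, "C", h = 5)
    si <- as.numeric(s0i); sums <- numeric(60)
    for (j in 1:60) {
        si <- (1 - k) * as.numeric(TMi %*% si) + k * as.numeric(s0i)
        sums[j] <- sum(si)
    }
    expect_true(all(diff(sums) <= 1e-12))
    expect_gte(sums[60], k)
    expect_lte(sums[60], 1)
})

test_that("k = 0 non-convergence raises a convergence error", {
    # bipartite single edge oscillates under pure power iteration
    pair <- mkNetwork(c(A = 1, B = 1),
        data.frame(from = "A", to = "B", weight = 1))
    TM <- transitionMatrix(pair)
    expect_error(
        propagate(TM, c(A = 1, B = 0),
            propagationConfig(k = 0, maxIterations = 50L)),
        class = "netprop_convergence_error")
    expect_error(solveDirect(TM, c(A = 1, B = 0), 0),
        class = "netprop_solver_error")
})

test_that("increasing h raises the seeds' share of propagated mass", {
    # Note the aggregate form: an individual seed-to-candidate score
    # ratio can drop with h when a candidate borders several seeds, so
    # monotonicity is asserted for the seed set's total mass share.
    for (i in 1:5) {
        net <- randomNetwork(60, 150, seed = 300 + i)
        seeds <- vertexNames(net)[seq(1, 60, by = 12)]
        cand <- setdiff(vertexNames(net), seeds)
        TM <- transitionMatrix(net)
        shares <- vapply(c(1L, 2L, 5L, 10L), function(h) {
            s <- propagate(TM, initialScores(net, seeds, h = h),
                propagationConfig(h = h, k = 0.6))$scores
            sum(s[seeds]) / sum(s[cand])
        }, numeric(1))
        expect_true(all(diff(shares) > 0))
    }
})

test_that("propagation is equivariant under vertex relabeling", {
    net <- randomNetwork(30, 70, seed = 9)
    v <- vertexNames(net)
    seeds <- v[1:3]
    map <- stats::setNames(sprintf("Z%04d", sample(seq_along(v))), v)
    e <- edgeWeights(net)
    netP <- mkNetwork(
        stats::setNames(vertexWeights(net), unname(map[v]))[
            order(unname(map[v]))],
        data.frame(from = unname(map[e$from]), to = unname(map[e$to]),
            weight = e$weight))
    cfg <- propagationConfig(h = 2, k = 0.4)
    s <- propagate(transitionMatrix(net),
        initialScores(net, seeds, h = 2), cfg)$scores
    sP <- propagate(transitionMatrix(netP),
        initialScores(netP, unname(map[seeds]), h = 2), cfg)$scores
    expect_equal(unname(sP[unname(map[v])]), unname(s[v]),
        tolerance = 1e-12)
})

test_that("gene ranking respects seeds flag and the shared tiebreak", {
    s <- c(A = 0.4, B = 0.35, C = 0.25)
    rk <- rankGenes(s, seeds = "A", includeSeeds = FALSE)
    expect_identical(rk$gene, c("B", "C"))
    expect_identical(rk$rank, 1:2)
    rkAll <- rankGenes(s, seeds = "A", includeSeeds = TRUE)
    expect_identical(rkAll$gene, c("A", "B", "C"))
    expect_identical(rkAll$is_seed, c(TRUE, FALSE, FALSE))
    tie <- rankGenes(c(B = 0.5, A = 0.5, C = 0.1))
    expect_identical(tie$gene, c("A", "B", "C"))
})
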