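test_that("rank-sum AUC matches closed single-fold cases", {
    expect_equal(rocAndAuc(data.frame(rank = 1, n_ranked = 101))$auc, 1.0)
    expect_equal(rocAndAuc(data.frame(rank = 101, n_ranked = 101))$auc, 0.0)
    # rank 26 of 101: beats 75 of 100 candidates
    expect_equal(rocAndAuc(data.frame(rank = 26, n_ranked = 101))$auc, 0.75)
    expect_error(rocAndAuc(data.frame(rank = numeric(),
        n_ranked = numeric())), class = "netprop_empty_input_error")
})

test_that("rank-sum AUC equals exhaustive pair counting on fuzzed folds", {
    set.seed(11)
    for (i in 1:50) {
        nf <- sample(1:8, 1)
        ns <- sample(3:50, nf, replace = TRUE)
        ranks <- vapply(ns, function(n) sample.int(n, 1), integer(1))
        folds <- data.frame(rank = ranks, n_ranked = ns)
        expect_equal(rocAndAuc(folds)$auc, bruteForceAuc(ranks, ns))
    }
})

test_that("ROC endpoints and monotonicity are sound", {
    folds <- data.frame(rank = c(2, 5, 1), n_ranked = c(10, 20, 15))
    roc <- rocAndAuc(folds)$roc
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$sensitivity[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$sensitivity[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$sensitivity) >= 0))
})

test_that("LOOCV demotes the held-out seed and excludes training seeds", {
    # seeds A, B share an edge; candidates C, D sit apart with low weight
    net <- mkNetwork(c(A = 2, B = 2, C = 1, D = 1),
        data.frame(from = c("A", "C"), to = c("B", "D"),
            weight = c(1, 1)))
    res <- loocv(net, c("A", "B"), propagationConfig(h = 5, k = 0.7))
    f <- loocvFolds(res)
    expect_identical(f$gene, c("A", "B"))
    # ranked list: all vertices minus the single training seed
    expect_identical(unique(f$n_ranked), 3L)
    # held-out gene keeps w = 2 and receives propagation from the
    # emphasized training seed, so it outranks both w = 1 candidates
    expect_identical(f$rank, c(1, 1))
    expect_equal(aucValue(res), 1.0)

    expect_error(loocv(net, "A"), class = "netprop_cardinality_error")
})

test_that("LOOCV AUC equals the hand-enumerated pair count on a tiny case", {
    # 2 seeds, 3 candidates; engineer fold ranks {1, 3} of 4 via weights
    # by checking rocAndAuc directly against brute enumeration
    folds <- data.frame(rank = c(1, 3), n_ranked = c(4, 4))
    expect_equal(rocAndAuc(folds)$auc, bruteForceAuc(c(1, 3), c(4, 4)))
    expect_equal(rocAndAuc(folds)$auc, (3 / 3 + 1 / 3) / 2)
})

test_that("perfect and random prioritizations hit their AUC anchors", {
    # every fold ranked first -> AUC 1
    expect_equal(rocAndAuc(data.frame(rank = rep(1, 20),
        n_ranked = rep(50, 20)))$auc, 1.0)
    # uniformly random ranks -> AUC ~ 0.5 within Monte-Carlo error
    set.seed(5)
    ranks <- sample.int(200, 400, replace = TRUE)
    auc <- rocAndAuc(data.frame(rank = ranks, n_ranked = 200))$auc
    expect_lt(abs(auc - 0.5), 0.05)
})

test_that("AUC is invariant to strictly monotone score transforms", {
    net <- randomNetwork(40, 100, seed = 77)
    seeds <- vertexNames(net)[1:5]
    cfg <- propagationConfig(h = 3, k = 0.5)
    base <- loocv(net, seeds, cfg)
    # monotone transform of the scores leaves every rank unchanged
    TM <- transitionMatrix(net)
    for (g in seeds) {
        train <- setdiff(sort(seeds), g)
        s <- propagate(TM, initialScores(net, train, h = 3), cfg)$scores
        ranked <- setdiff(vertexNames(net), train)
        r1 <- rank(-s[ranked], ties.method = "average")[[g]]
        r2 <- rank(-(log1p(s[ranked]) * 7 + 2),
            ties.method = "average")[[g]]
        expect_equal(r1, r2)
    }
    expect_s4_class(base, "LoocvResult")
})

test_that("grid search tabulates all points, is order-invariant", {
    net <- randomNetwork(30, 80, seed = 13)
    seeds <- vertexNames(net)[1:4]
    g1 <- gridSearch(net, seeds, hGrid = c(1, 5), kGrid = c(0.3, 0.7, 1))
    expect_identical(nrow(gridTable(g1)), 6L)
    expect_equal(bestParams(g1)$auc, max(gridTable(g1)$auc))
    g2 <- gridSearch(net, seeds, hGrid = c(5, 1), kGrid = c(1, 0.7, 0.3))
    expect_equal(gridTable(g1), gridTable(g2))

    single <- gridSearch(net, seeds, hGrid = 2, kGrid = 0.5)
    expect_identical(nrow(gridTable(single)), 1L)
    expect_equal(bestParams(single), gridTable(single))
})

test_that("subsampling is reproducible and validates sizes", {
    spec <- simulationSpec(nGenes = 60L, nEdgesTarget = 150L,
        moduleSize = 6L, nDiseaseSamples = 8L, nNormalSamples = 8L,
        rngSeed = 21L)
    ge <- generateExpression(spec)
    et <- generateNetwork(spec)
    r1 <- subsampleRobustness(ge$data, et, ge$seeds, sizes = c(4L, 8L),
        repeats = 2L, rngSeed = 99L)
    r2 <- subsampleRobustness(ge$data, et, ge$seeds, sizes = c(4L, 8L),
        repeats = 2L, rngSeed = 99L)
    expect_identical(r1$aucs, r2$aucs)
    expect_identical(nrow(r1$aucs), 4L)
    expect_identical(colnames(r1$summary),
        c("size", "min", "q1", "median", "q3", "max"))

    expect_error(subsampleRobustness(ge$data, et, ge$seeds,
        sizes = 18L, repeats = 1L), class = "netprop_cardinality_error")
    expect_error(subsampleRobustness(ge$data, et, ge$seeds,
        sizes = 5L, repeats = 1L), class = "netprop_cardinality_error")
})
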