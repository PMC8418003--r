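# Leave-one-out cross-validation over seed genes, rank-based ROC/AUC,
# (h, k) grid search and balanced subsampling robustness.

#' ROC points and AUC from held-out ranks
#'
#' Each fold contributes the rank of one held-out seed gene within its
#' ranked list of `n_ranked` genes (the candidates plus the test gene).
#' The AUC is the rank-sum (Mann-Whitney) estimator: the probability that
#' a held-out seed outranks a random candidate, `(n - rank) / (n - 1)`
#' averaged over folds; score ties enter as midranks and so receive half
#' credit. The ROC curve sweeps a rank cutoff `c`: sensitivity is the
#' fraction of test genes with rank <= c, and the false positive rate is
#' the fraction of non-test ranked genes with rank <= c (specificity is
#' taken over the candidate genes of each fold, the standard
#' prioritization convention).
#'
#' @param folds data.frame with columns `rank` and `n_ranked` (one row per
#'   fold); ranks may be fractional midranks.
#' @return list with `roc` (data.frame `fpr`, `sensitivity`) and `auc`.
#' @export
rocAndAuc <- function(folds) {
    folds <- as.data.frame(folds)
    if (!nrow(folds))
        npStop("netprop_empty_input_error", "no folds to evaluate")
    stopifnot(all(c("rank", "n_ranked") %in% colnames(folds)),
        all(folds$rank >= 1), all(folds$rank <= folds$n_ranked),
        all(folds$n_ranked >= 2))
    r <- folds$rank; n <- folds$n_ranked
    auc <- mean((n - r) / (n - 1))
    cutoffs <- 0:max(n)
    sens <- vapply(cutoffs, function(cc) mean(r <= cc), numeric(1))
    fpr <- vapply(cutoffs, function(cc)
        mean((pmin(cc, n) - (r <= cc)) / (n - 1)), numeric(1))
    list(roc = data.frame(fpr = fpr, sensitivity = sens), auc = auc)
}

#' Leave-one-out cross-validation of the prioritization
#'
#' Each seed gene present in the network is held out in turn: the initial
#' scores are rebuilt from the remaining (training) seeds, so the test
#' gene is demoted to candidate status and receives the plain `w(v)`
#' initial weight; propagation is rerun; and the test gene's rank is
#' recorded among the candidates plus itself (training seeds are excluded
#' from the ranked list). The per-fold ranks yield the ROC and the
#' rank-sum AUC via [rocAndAuc()].
#'
#' The network (and hence the transition matrix) is fixed across folds;
#' only the initial scores change.
#'
#' @param network a [WeightedNetwork-class].
#' @param seeds character vector of seed symbols; at least 2 must be
#'   network vertices.
#' @param config a [PropagationConfig-class].
#' @param quiet suppress progress messages.
#' @return a [LoocvResult-class].
#' @export
loocv <- function(network, seeds, config = propagationConfig(),
                  quiet = TRUE) {
    stopifnot(methods::is(network, "WeightedNetwork"),
        methods::is(config, "PropagationConfig"))
    seeds <- unique(normalizeSymbols(seeds))
    v <- vertexNames(network)
    seedsIn <- sort(seeds[seeds %in% v])
    if (length(seedsIn) < 2L)
        npStop("netprop_cardinality_error",
            "LOOCV needs >= 2 seed genes in the network, found %d",
            length(seedsIn))
    TM <- transitionMatrix(network)
    folds <- data.frame(gene = seedsIn, rank = NA_real_,
        n_ranked = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_along(seedsIn)) {
        g <- seedsIn[i]
        train <- setdiff(seedsIn, g)
        s0 <- initialScores(network, train, h = config@h, quiet = TRUE)
        s <- propagate(TM, s0, config)$scores
        rankedSet <- setdiff(v, train)
        sc <- s[rankedSet]
        folds$rank[i] <- rank(-sc, ties.method = "average")[[g]]
        folds$n_ranked[i] <- length(rankedSet)
        if (!quiet)
            message(sprintf("fold %d/%d: %s ranked %.1f of %d",
                i, length(seedsIn), g, folds$rank[i], folds$n_ranked[i]))
    }
    ra <- rocAndAuc(folds)
    methods::new("LoocvResult", folds = folds, roc = ra$roc,
        auc = ra$auc, config = config)
}

#' Grid search over seed emphasis h and restart weight k
#'
#' Runs [loocv()] at every `(h, k)` grid point and tabulates the AUCs.
#' Deterministic given its inputs, and invariant to the order in which
#' the grids are supplied (rows are sorted by `h`, then `k`). A grid
#' point whose propagation fails to converge (possible only at `k = 0`)
#' is recorded with `NA` AUC and skipped for the argmax.
#'
#' @param network a [WeightedNetwork-class].
#' @param seeds seed gene symbols.
#' @param hGrid integer vector of seed-emphasis values (default
#'   `c(1, 10, 15, 30)`).
#' @param kGrid numeric vector of restart weights (default
#'   `seq(0, 1, by = 0.1)`).
#' @param tolerance,maxIterations,norm passed to [propagationConfig()].
#' @return a [GridResult-class].
#' @export
gridSearch <- function(network, seeds, hGrid = c(1L, 10L, 15L, 30L),
                       kGrid = seq(0, 1, by = 0.1),
                       tolerance = 1e-8, maxIterations = 10000L,
                       norm = "L1") {
    if (!length(hGrid) || !length(kGrid))
        npStop("netprop_empty_input_error", "grids must be non-empty")
    grid <- expand.grid(k = as.numeric(kGrid), h = as.integer(hGrid))
    auc <- vapply(seq_len(nrow(grid)), function(i) {
        cfg <- propagationConfig(h = grid$h[i], k = grid$k[i],
            tolerance = tolerance, maxIterations = maxIterations,
            norm = norm)
        tryCatch(aucValue(loocv(network, seeds, cfg)),
            netprop_convergence_error = function(e) {
                warning(sprintf("grid point (h=%d, k=%g): %s",
                    grid$h[i], grid$k[i], conditionMessage(e)))
                NA_real_
            })
    }, numeric(1))
    tab <- data.frame(h = grid$h, k = grid$k, auc = auc)
    tab <- tab[order(tab$h, tab$k), , drop = FALSE]
    rownames(tab) <- NULL
    ok <- which(!is.na(tab$auc))
    if (!length(ok))
        npStop("netprop_convergence_error",
            "no grid point converged")
    best <- tab[ok[which.max(tab$auc[ok])], , drop = FALSE]
    methods::new("GridResult", table = tab, best = best)
}

#' Robustness of the AUC under balanced subsampling
#'
#' Draws `repeats` balanced subsamples (equal numbers of disease and
#' normal samples) at each requested size, rebuilds the weighted network
#' from each subsample, reruns [loocv()], and collects the AUCs together
#' with per-size quartile summaries. Fully reproducible from `rngSeed`:
#' a single RNG stream is used, iterating sizes in the given order and
#' replicates within each size, drawing disease then normal sample IDs.
#'
#' @param data an [ExpressionDataset-class] (the full sample set).
#' @param edges an [EdgeTable-class].
#' @param seeds seed gene symbols.
#' @param sizes even integers >= 4; each must not exceed twice the
#'   smaller class size.
#' @param repeats subsamples per size (the reference design uses 100).
#' @param rngSeed integer RNG seed.
#' @param config a [PropagationConfig-class].
#' @param transform,epsilon,missingPolicy network-construction options,
#'   see [buildWeightedNetwork()].
#' @return list with `aucs` (data.frame `size`, `replicate`, `auc`) and
#'   `summary` (per-size `min`, `q1`, `median`, `q3`, `max`).
#' @export
subsampleRobustness <- function(data, edges, seeds, sizes, repeats,
                                rngSeed = 1L,
                                config = propagationConfig(),
                                transform = "abs", epsilon = 1e-6,
                                missingPolicy = "drop") {
    stopifnot(methods::is(data, "ExpressionDataset"),
        methods::is(edges, "EdgeTable"), repeats >= 1L)
    lab <- sampleLabels(data)
    dIDs <- names(lab)[lab == "disease"]
    nIDs <- names(lab)[lab == "normal"]
    maxSize <- 2L * min(length(dIDs), length(nIDs))
    sizes <- as.integer(sizes)
    if (any(sizes %% 2L != 0L) || any(sizes < 4L))
        npStop("netprop_cardinality_error",
            "sizes must be even integers >= 4 (balanced classes)")
    if (any(sizes > maxSize))
        npStop("netprop_cardinality_error",
            "size %d exceeds available balanced samples (max %d)",
            max(sizes), maxSize)

    set.seed(rngSeed)
    rows <- vector("list", length(sizes) * repeats)
    ri <- 0L
    for (sz in sizes) {
        half <- sz %/% 2L
        for (rep_i in seq_len(repeats)) {
            keep <- c(sample(dIDs, half), sample(nIDs, half))
            sub <- data[, keep]
            net <- buildWeightedNetwork(edges, sub, transform = transform,
                epsilon = epsilon, missingPolicy = missingPolicy,
                quiet = TRUE)
            res <- loocv(net, seeds, config)
            ri <- ri + 1L
            rows[[ri]] <- data.frame(size = sz, replicate = rep_i,
                auc = aucValue(res))
        }
    }
    aucs <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(aucs$auc, aucs$size), function(x) {
        q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
            max = q[5])
    }))
    summ <- cbind(size = as.integer(rownames(summ)), summ)
    rownames(summ) <- NULL
    list(aucs = aucs, summary = summ)
}

#' @describeIn loocv per-fold ranks of the held-out seed genes.
#' @param x a `LoocvResult`.
#' @rdname loocvFolds
#' @export
setMethod("loocvFolds", "LoocvResult", function(x) x@folds)

#' ROC points of a cross-validation result
#' @param x a [LoocvResult-class].
#' @rdname rocPoints
#' @export
setMethod("rocPoints", "LoocvResult", function(x) x@roc)

#' AUC of a cross-validation result
#' @param x a [LoocvResult-class].
#' @rdname aucValue
#' @export
setMethod("aucValue", "LoocvResult", function(x) x@auc)

setMethod("show", "LoocvResult", function(object) {
    cat(sprintf("LoocvResult: %d folds, AUC = %.4f\n",
        nrow(object@folds), object@auc))
    cat(sprintf("  median held-out rank: %.1f of %d\n",
        stats::median(object@folds$rank), object@folds$n_ranked[1]))
})

#' Full (h, k, auc) table of a grid search
#' @param x a [GridResult-class].
#' @rdname gridTable
#' @export
setMethod("gridTable", "GridResult", function(x) x@table)

#' Best grid point of a grid search
#' @param x a [GridResult-class].
#' @rdname bestParams
#' @export
setMethod("bestParams", "GridResult", function(x) x@best)

setMethod("show", "GridResult", function(object) {
    b <- object@best
    cat(sprintf("GridResult: %d grid points; best AUC = %.4f at h = %d, k = %g\n",
        nrow(object@table), b$auc, b$h, b$k))
})
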