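# Disease-risk propagation: initial scores, the column-normalized
# transition matrix and the restart recurrence
#   S(i+1) = (1 - k) * T %*% S(i) + k * S(0)
# iterated until the residual between successive score vectors drops
# below the tolerance (default 1e-8).

#' Construct a PropagationConfig
#'
#' @param h integer >= 1; seed emphasis. `h = 1` treats seed and candidate
#'   genes as equally important in the initial scores.
#' @param k restart weight in `[0, 1]`: weight of the initial (vertex)
#'   scores against the propagated (edge) scores. `k = 1` disables
#'   propagation; `k = 0` is pure power iteration on the transition matrix
#'   and carries no contraction guarantee.
#' @param tolerance convergence threshold on the residual (default `1e-8`).
#' @param maxIterations iteration cap (default 10000).
#' @param norm `"L1"` (default) or `"Linf"`; norm used in the convergence
#'   test.
#' @return a [PropagationConfig-class].
#' @export
propagationConfig <- function(h = 1L, k = 0.7, tolerance = 1e-8,
                              maxIterations = 10000L,
                              norm = c("L1", "Linf")) {
    methods::new("PropagationConfig", h = as.integer(h), k = as.numeric(k),
        tolerance = as.numeric(tolerance),
        maxIterations = as.integer(maxIterations),
        norm = match.arg(norm))
}

setMethod("show", "PropagationConfig", function(object) {
    cat(sprintf(
        "PropagationConfig: h = %d, k = %g, tolerance = %g (%s), maxIterations = %d\n",
        object@h, object@k, object@tolerance, object@norm,
        object@maxIterations))
})

#' Initial disease-risk scores
#'
#' Builds the normalized initial score vector: seeds receive `h * w(v)`,
#' candidates `w(v)`, all divided by the common normalizer
#' `sum_{a in seeds} h * w(a) + sum_{a not in seeds} w(a)` so the vector
#' sums to one. Doubling every vertex weight leaves the result unchanged.
#'
#' @param network a [WeightedNetwork-class].
#' @param seeds character vector of seed gene symbols; seeds absent from
#'   the network are reported via a message, not silently dropped.
#' @param h integer seed emphasis, >= 1.
#' @param quiet suppress the absent-seed message.
#' @return named numeric score vector over all vertices, summing to 1.
#' @export
initialScores <- function(network, seeds, h = 1L, quiet = FALSE) {
    stopifnot(methods::is(network, "WeightedNetwork"), h >= 1)
    seeds <- unique(normalizeSymbols(seeds))
    vw <- vertexWeights(network)
    inNet <- seeds[seeds %in% names(vw)]
    if (!length(inNet))
        npStop("netprop_disjoint_seed_error",
            "none of the %d seed gene(s) are network vertices",
            length(seeds))
    if (!quiet && length(inNet) < length(seeds))
        message(sprintf("initialScores: %d of %d seeds absent from network",
            length(seeds) - length(inNet), length(seeds)))
    raw <- vw
    raw[inNet] <- h * raw[inNet]
    raw / sum(raw)
}

#' Disease-risk transition matrix
#'
#' Column-normalized sparse transition matrix in `(to, from)` orientation:
#' `T[v, u] = w(u, v) / sum_{r in neighbor(u)} w(u, r)`, so the recurrence
#' is the left-multiplication `T %*% S`. A vertex with no neighbors gets an
#' all-zero column; so does a vertex whose incident edge weights are all
#' zero (a warning is issued for the latter). Every other column sums to
#' one.
#'
#' @param network a [WeightedNetwork-class] (edge weights must be
#'   non-negative, which the class guarantees).
#' @return a sparse [Matrix::Matrix] (dgCMatrix) with vertex dimnames.
#' @export
transitionMatrix <- function(network) {
    stopifnot(methods::is(network, "WeightedNetwork"))
    v <- vertexNames(network)
    n <- length(v)
    e <- edgeWeights(network)
    idx <- stats::setNames(seq_len(n), v)
    iF <- idx[e$from]; iT <- idx[e$to]
    strength <- numeric(n)
    agg <- rowsum(c(e$weight, e$weight), c(iF, iT))
    strength[as.integer(rownames(agg))] <- agg[, 1L]

    hasNb <- logical(n)
    hasNb[c(iF, iT)] <- TRUE
    if (any(hasNb & strength == 0))
        warning(sprintf(
            "%d vertex(es) have neighbors but all-zero incident edge weights; their columns are zero",
            sum(hasNb & strength == 0)))

    keep <- e$weight > 0
    i <- c(iT[keep], iF[keep])          # to
    j <- c(iF[keep], iT[keep])          # from
    x <- c(e$weight[keep], e$weight[keep]) / strength[j]
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
        dimnames = list(v, v))
}

#' Iterate the propagation recurrence to its fixed point
#'
#' Runs `S(i+1) = (1 - k) * T %*% S(i) + k * S0` from `S(0) = S0` until
#' the residual `||S(i+1) - S(i)||` falls below the tolerance or the
#' iteration cap is reached. For `k > 0` the map is a contraction with
#' factor at most `1 - k` in the L1 norm, so convergence is guaranteed;
#' for `k = 0` there is no such guarantee and hitting the cap is an error.
#'
#' @param T transition matrix from [transitionMatrix()].
#' @param s0 initial score vector (must sum to 1, within `1e-6`).
#' @param config a [PropagationConfig-class]; its `h` slot is not used
#'   here (it only shapes `s0`).
#' @return list with `scores` (named numeric), `residuals` (per-iteration
#'   residual trace), `iterations`, `converged`.
#' @export
propagate <- function(T, s0, config = propagationConfig()) {
    stopifnot(methods::is(config, "PropagationConfig"),
        nrow(T) == length(s0))
    if (abs(sum(s0) - 1) > 1e-6)
        npStop("netprop_input_error",
            "initial scores must sum to 1 (got %.6g)", sum(s0))
    k <- config@k
    normFun <- if (config@norm == "L1") function(d) sum(abs(d))
               else function(d) max(abs(d))
    s <- as.numeric(s0)
    residuals <- numeric(0)
    converged <- FALSE
    for (it in seq_len(config@maxIterations)) {
        sNew <- (1 - k) * as.numeric(T %*% s) + k * as.numeric(s0)
        res <- normFun(sNew - s)
        residuals[it] <- res
        s <- sNew
        if (res < config@tolerance) { converged <- TRUE; break }
    }
    if (!converged) {
        if (k == 0)
            npStop("netprop_convergence_error",
                "no convergence after %d iterations with k = 0 (no contraction guarantee)",
                config@maxIterations)
        warning(sprintf("propagation stopped at maxIterations = %d, residual %.3g",
            config@maxIterations, residuals[length(residuals)]))
    }
    list(scores = stats::setNames(s, rownames(T)),
         residuals = residuals,
         iterations = length(residuals),
         converged = converged)
}

#' Exact fixed point of the recurrence by a direct linear solve
#'
#' Solves `(I - (1 - k) * T) S = k * S0`, the closed form of the
#' recurrence's fixed point, with a sparse LU factorization. Serves as the
#' oracle for [propagate()]; the two agree within tight numerical
#' tolerance for `k > 0`.
#'
#' @param T transition matrix from [transitionMatrix()].
#' @param s0 initial score vector.
#' @param k restart weight in `(0, 1]`.
#' @return named numeric score vector.
#' @export
solveDirect <- function(T, s0, k) {
    stopifnot(nrow(T) == length(s0))
    if (k <= 0)
        npStop("netprop_solver_error",
            "direct solve requires k > 0 (system may be singular at k = 0)")
    A <- Matrix::Diagonal(nrow(T)) - (1 - k) * T
    s <- as.numeric(Matrix::solve(A, k * as.numeric(s0)))
    stats::setNames(s, rownames(T))
}

#' Rank genes by disease-risk score
#'
#' Orders genes by score descending, ties broken by gene symbol ascending
#' (the package-wide stable rule). With `includeSeeds = FALSE` the seed
#' genes are removed before ranks are assigned, so ranks refer to the
#' candidate list only.
#'
#' @param scores named numeric score vector (finite).
#' @param seeds character vector of seed symbols (may be empty).
#' @param includeSeeds keep seeds in the ranking (flagged in `is_seed`)?
#' @return data.frame with columns `rank`, `gene`, `score`, `is_seed`.
#' @export
rankGenes <- function(scores, seeds = character(), includeSeeds = FALSE) {
    if (any(!is.finite(scores)))
        npStop("netprop_numeric_error", "scores must all be finite")
    seeds <- normalizeSymbols(seeds)
    isSeed <- names(scores) %in% seeds
    if (!includeSeeds) {
        scores <- scores[!isSeed]
        isSeed <- isSeed[!isSeed]
    }
    o <- order(-scores, names(scores))
    data.frame(rank = seq_along(o),
        gene = names(scores)[o],
        score = unname(scores[o]),
        is_seed = isSeed[o],
        stringsAsFactors = FALSE)
}
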