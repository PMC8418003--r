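#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionDataset: a labelled gene-by-sample expression matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"expr"` (non-negative expression values, genes in rows) and a mandatory
#' two-level sample annotation `condition` in `colData` with levels
#' `disease` and `normal`. Gene symbols (rownames) are unique and
#' uppercase-normalized; gene order is lexicographic.
#'
#' @slot .data inherited `SummarizedExperiment` slots.
#' @seealso [ExpressionDataset()] for construction from a matrix and labels,
#'   [readExpression()] for construction from files.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else {
        x <- SummarizedExperiment::assay(object, "expr")
        if (anyNA(x))
            msg <- c(msg, "expression matrix contains missing values")
        else if (any(x < 0))
            msg <- c(msg, "expression values must be non-negative")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "gene symbols must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'condition' column")
    else {
        cond <- cd$condition
        if (!all(levels(cond) == c("disease", "normal")))
            msg <- c(msg, "condition levels must be c('disease','normal')")
        else if (any(table(cond) < 2L))
            msg <- c(msg, "each condition class needs at least 2 samples")
    }
    if (length(msg)) msg else TRUE
})

#' EdgeTable: a deduplicated undirected edge list
#'
#' Holds the edges of an undirected gene network. Construction canonicalizes
#' orientation (`from < to` lexicographically), removes self-loops and
#' collapses duplicates, so validity guarantees a simple graph.
#'
#' @slot from,to character vectors of equal length; `from[i] < to[i]`.
#' @seealso [EdgeTable()], [readEdgeList()]
#' @export
setClass("EdgeTable",
    representation(from = "character", to = "character"))

setValidity("EdgeTable", function(object) {
    msg <- character()
    if (length(object@from) != length(object@to))
        msg <- c(msg, "'from' and 'to' must have equal length")
    else if (length(object@from)) {
        if (any(object@from == object@to))
            msg <- c(msg, "self-loops are not allowed")
        if (any(object@from > object@to))
            msg <- c(msg, "edges must be canonically oriented (from < to)")
        if (anyDuplicated(paste(object@from, object@to, sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' WeightedNetwork: an expression-weighted interaction network
#'
#' An undirected gene network carrying a positive differential-expression
#' weight per vertex and a co-expression weight in `[0, 1]` per edge.
#'
#' @slot vertexWeights named numeric; names are the vertices (sorted),
#'   values are the disease/normal mean-expression ratios, strictly positive.
#' @slot edges data.frame with columns `from`, `to`, `weight`; canonical
#'   orientation, `weight` in `[0, 1]`.
#' @seealso [buildWeightedNetwork()]
#' @export
setClass("WeightedNetwork",
    representation(vertexWeights = "numeric", edges = "data.frame"))

setValidity("WeightedNetwork", function(object) {
    msg <- character()
    vw <- object@vertexWeights
    if (is.null(names(vw)) || anyDuplicated(names(vw)))
        msg <- c(msg, "vertexWeights must be uniquely named")
    if (any(!is.finite(vw)) || any(vw <= 0))
        msg <- c(msg, "vertex weights must be finite and strictly positive")
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        msg <- c(msg, "edges needs columns from, to, weight")
    else if (nrow(e)) {
        if (!all(e$from %in% names(vw)) || !all(e$to %in% names(vw)))
            msg <- c(msg, "edge endpoints must be network vertices")
        if (any(!is.finite(e$weight)) || any(e$weight < 0) ||
            any(e$weight > 1))
            msg <- c(msg, "edge weights must be finite, in [0, 1]")
        if (any(e$from >= e$to))
            msg <- c(msg, "edges must be canonically oriented (from < to)")
    }
    if (length(msg)) msg else TRUE
})

#' PropagationConfig: parameters of the propagation recurrence
#'
#' @slot h integer >= 1, seed emphasis: multiplier on seed genes' initial
#'   scores relative to candidates.
#' @slot k numeric in `[0, 1]`, restart weight mixing the propagated scores
#'   (edge information) with the initial scores (vertex information).
#' @slot tolerance positive numeric, convergence threshold on the residual
#'   between successive score vectors (default `1e-8`).
#' @slot maxIterations integer cap on iterations (default 10000).
#' @slot norm `"L1"` or `"Linf"`, the norm used in the convergence test.
#' @seealso [propagationConfig()]
#' @export
setClass("PropagationConfig",
    representation(h = "integer", k = "numeric", tolerance = "numeric",
        maxIterations = "integer", norm = "character"))

setValidity("PropagationConfig", function(object) {
    msg <- character()
    if (length(object@h) != 1L || is.na(object@h) || object@h < 1L)
        msg <- c(msg, "h must be a single integer >= 1")
    if (length(object@k) != 1L || is.na(object@k) ||
        object@k < 0 || object@k > 1)
        msg <- c(msg, "k must be a single value in [0, 1]")
    if (length(object@tolerance) != 1L || !is.finite(object@tolerance) ||
        object@tolerance <= 0)
        msg <- c(msg, "tolerance must be a single positive value")
    if (length(object@maxIterations) != 1L || is.na(object@maxIterations) ||
        object@maxIterations < 1L)
        msg <- c(msg, "maxIterations must be a single integer >= 1")
    if (length(object@norm) != 1L || !object@norm %in% c("L1", "Linf"))
        msg <- c(msg, "norm must be 'L1' or 'Linf'")
    if (length(msg)) msg else TRUE
})

#' LoocvResult: leave-one-out cross-validation outcome
#'
#' @slot folds data.frame with one row per held-out seed gene: `gene`,
#'   `rank` (midrank among candidates plus the test gene; ties share rank),
#'   `n_ranked` (size of that ranked list).
#' @slot roc data.frame of ROC points: `fpr`, `sensitivity`.
#' @slot auc numeric in `[0, 1]`; probability a held-out seed outranks a
#'   random candidate (rank-sum estimator, ties counted 1/2).
#' @slot config the [PropagationConfig-class] used.
#' @seealso [loocv()]
#' @export
setClass("LoocvResult",
    representation(folds = "data.frame", roc = "data.frame",
        auc = "numeric", config = "PropagationConfig"))

setValidity("LoocvResult", function(object) {
    msg <- character()
    f <- object@folds
    if (!all(c("gene", "rank", "n_ranked") %in% colnames(f)))
        msg <- c(msg, "folds needs columns gene, rank, n_ranked")
    else if (nrow(f) && (any(f$rank < 1) || any(f$rank > f$n_ranked)))
        msg <- c(msg, "fold ranks must lie in [1, n_ranked]")
    if (length(object@auc) != 1L || is.na(object@auc) ||
        object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' GridResult: (h, k) parameter grid search outcome
#'
#' @slot table data.frame with columns `h`, `k`, `auc`, one row per grid
#'   point.
#' @slot best single-row data.frame: the grid point with maximal AUC (ties
#'   broken by smaller h, then smaller k).
#' @seealso [gridSearch()]
#' @export
setClass("GridResult",
    representation(table = "data.frame", best = "data.frame"))

setValidity("GridResult", function(object) {
    msg <- character()
    if (!all(c("h", "k", "auc") %in% colnames(object@table)))
        msg <- c(msg, "table needs columns h, k, auc")
    if (nrow(object@best) != 1L)
        msg <- c(msg, "best must be a single row")
    else if (nrow(object@table) &&
             object@best$auc < max(object@table$auc))
        msg <- c(msg, "best must attain the maximal AUC")
    if (length(msg)) msg else TRUE
})

#' SimulationSpec: parameters of the synthetic planted-module benchmark
#'
#' Describes a benchmark instance at reduced scale: a sparse undirected
#' network with a planted disease module, and an expression matrix in which
#' module genes are differentially expressed between disease and normal
#' samples and co-expressed within disease samples through a shared latent
#' factor.
#'
#' @slot nGenes number of genes (default 300).
#' @slot nEdgesTarget target number of background edges (default 900).
#' @slot moduleSize number of planted seed genes (default 15).
#' @slot attachment `"preferential"` (scale-free-like) or `"erdos_renyi"`.
#' @slot nDiseaseSamples,nNormalSamples sample counts (defaults 30 + 30).
#' @slot foldChange disease/normal mean-expression ratio of module genes
#'   (default 2).
#' @slot moduleCorrelation target pairwise Pearson correlation of module
#'   genes across disease samples, in `[0, 1)` (default 0.6).
#' @slot noiseSd standard deviation of expression noise (default 1).
#' @slot baselineMean baseline expression level, FPKM-like scale (default 5).
#' @slot rngSeed integer seed; all generator randomness derives from it.
#' @seealso [simulationSpec()], [generateBenchmark()]
#' @export
setClass("SimulationSpec",
    representation(nGenes = "integer", nEdgesTarget = "integer",
        moduleSize = "integer", attachment = "character",
        nDiseaseSamples = "integer", nNormalSamples = "integer",
        foldChange = "numeric", moduleCorrelation = "numeric",
        noiseSd = "numeric", baselineMean = "numeric", rngSeed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    n <- object@nGenes
    if (n < 2L) msg <- c(msg, "nGenes must be >= 2")
    if (object@moduleSize < 1L || object@moduleSize >= n)
        msg <- c(msg, "moduleSize must be in [1, nGenes)")
    if (object@nEdgesTarget < 1L ||
        object@nEdgesTarget > n * (n - 1L) / 2)
        msg <- c(msg, "nEdgesTarget must be in [1, nGenes*(nGenes-1)/2]")
    if (!object@attachment %in% c("preferential", "erdos_renyi"))
        msg <- c(msg, "attachment must be 'preferential' or 'erdos_renyi'")
    if (object@nDiseaseSamples < 2L || object@nNormalSamples < 2L)
        msg <- c(msg, "need >= 2 samples per class")
    if (object@foldChange <= 0)
        msg <- c(msg, "foldChange must be positive")
    if (object@moduleCorrelation < 0 || object@moduleCorrelation >= 1)
        msg <- c(msg, "moduleCorrelation must be in [0, 1)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (object@baselineMean <= 0)
        msg <- c(msg, "baselineMean must be positive")
    if (length(msg)) msg else TRUE
})
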